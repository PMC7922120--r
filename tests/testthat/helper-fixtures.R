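# Small in-code fixtures and independent oracles shared across tests.

# one-product-per-ingredient reference tables --------------------------------

tiny_ingredients <- function() {
  data.frame(
    name = c("alpha", "beta", "gamma", "khco3", "no_ld50", "no_hl",
             "mystery"),
    ld50_contact_ug_per_bee = c(100, 10, 1, 100, NA, 50, 25),
    half_life_days = c(log(2), 14, 30, NA, 5, NA, 10),
    harm_class = c("harmless", "slightly_harmful", "harmful", "harmless",
                   "harmless", "harmless", "unknown"),
    stringsAsFactors = FALSE
  )
}

tiny_products <- function() {
  ing <- tiny_ingredients()$name
  data.frame(product = paste0("p_", ing), ingredient = ing,
             concentration_pct = 100, stringsAsFactors = FALSE)
}

# a spray row for one product at one date
app <- function(vineyard = "v1", date = "2019-05-01", product = "p_alpha",
                dose = 1000, category = "other") {
  data.frame(vineyard_id = vineyard, date = date, product = product,
             dose_g_per_ha = dose, category = category,
             stringsAsFactors = FALSE)
}

empty_spray <- function() {
  data.frame(vineyard_id = character(), date = character(),
             product = character(), dose_g_per_ha = numeric(),
             category = character(), stringsAsFactors = FALSE)
}

# brute-force aAPTLc oracle: explicit per-term loop, independent of the
# vectorised implementation
oracle_aaptlc <- function(spray, ingredients, products, scaling = 1e-4,
                          khco3_halflife = NULL) {
  total <- 0
  for (i in seq_len(nrow(spray))) {
    comps <- products[products$product == spray$product[i], , drop = FALSE]
    for (j in seq_len(nrow(comps))) {
      amount <- spray$dose_g_per_ha[i] * comps$concentration_pct[j] / 100
      row <- ingredients[ingredients$name == comps$ingredient[j], ]
      ld50 <- row$ld50_contact_ug_per_bee
      hl <- row$half_life_days
      if (is.na(hl) && !is.null(khco3_halflife) &&
          row$name == "potassium_bicarbonate") hl <- khco3_halflife
      if (is.na(ld50) || is.na(hl)) next
      total <- total + amount / ld50 * hl / log(2)
    }
  }
  scaling * total
}

# enumeration oracle for the categorical rating
oracle_rating <- function(classes) {
  scale <- c(harmless = 0.4, slightly_harmful = 0.8, harmful = 1.0)
  sum(scale[classes])
}

# random ingredient table + regime for fuzzing
random_regime <- function(n_apps, n_ingredients = 4) {
  ing <- data.frame(
    name = paste0("ing", seq_len(n_ingredients)),
    ld50_contact_ug_per_bee = stats::runif(n_ingredients, 0.1, 500),
    half_life_days = stats::runif(n_ingredients, 0.5, 2000),
    harm_class = sample(c("harmless", "slightly_harmful", "harmful"),
                        n_ingredients, replace = TRUE),
    stringsAsFactors = FALSE)
  prods <- data.frame(product = paste0("prod", seq_len(n_ingredients)),
                      ingredient = ing$name,
                      concentration_pct = stats::runif(n_ingredients, 1, 100),
                      stringsAsFactors = FALSE)
  spray <- data.frame(
    vineyard_id = "v1",
    date = sprintf("2019-05-%02d", seq_len(n_apps)),
    product = sample(prods$product, n_apps, replace = TRUE),
    dose_g_per_ha = stats::runif(n_apps, 10, 5000),
    category = "other",
    stringsAsFactors = FALSE)
  list(spray = spray, ingredients = ing, products = prods)
}

# minimal stand-in fit for rank_models tests
fake_fit <- function(label, aicc, k = 3, adj_r2 = 0.5) {
  structure(list(response = "y", terms = if (label == "null") character(0)
                 else strsplit(label, " \\+ ")[[1]],
                 label = label, n = 100, k = k, loglik = 0, aic = aicc,
                 aicc = aicc, r2 = adj_r2, adj_r2 = adj_r2,
                 coefficients = data.frame()), class = "vm_fit")
}

# zero-effect configuration (same noise, no structure)
zero_effect_config <- function() {
  eff <- lapply(synthetic_config()$effects, function(e) {
    e$date <- c(0, 0, 0, 0)
    for (nm in setdiff(names(e), c("intercept", "date", "residual_sd"))) {
      if (length(e[[nm]]) > 1) e[[nm]][] <- 0 else e[[nm]] <- 0
    }
    e
  })
  synthetic_config(effects = eff)
}
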