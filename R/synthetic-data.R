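## Synthetic paired-vineyard studies with known ground truth.

#' Default synthetic-study configuration
#'
#' Encodes the study conditions the generator emulates: 16 circles each
#' holding one organic and one integrated vineyard (32 in total), three
#' inter-row cover-crop types, five sampling dates with seasonally declining
#' mite densities and an early-June pollen peak, spray regimes following the
#' per-category application-count structure of the field survey, landscape
#' circles whose semi-natural-habitat share spans 10--55%, near-zero
#' zero-inflated eriophyoid counts and absent spider mites. Effects are
#' injected on the log10(y + 1) scale (the modelling scale), so the ground
#' truth is exact for the Gaussian GLMs.
#'
#' @param n_pairs Number of circles (vineyard pairs).
#' @param effects Named list of per-response effect lists; see the returned
#'   defaults for the structure (`intercept`, `date` deviations for dates
#'   2--5, `management_organic`, `cover_crop` deviations for species-rich and
#'   spontaneous, slopes per unit of the landscape / cover predictors, and
#'   `residual_sd`). Pass modified copies to change the ground truth.
#' @return A list of class `vm_config`.
#' @export
synthetic_config <- function(n_pairs = 16, effects = NULL) {
  stopifnot(n_pairs >= 1)
  default_effects <- list(
    phytoseiid = list(
      intercept = 0.91,
      date = c(-0.35, -0.40, -0.42, -0.46),
      management_organic = -0.20,
      cover_crop = c(species_rich = 0.08, spontaneous = 0.22),
      pct_vineyards = 0.008, pct_total_snh = -0.008,
      residual_sd = 0.15),
    tydeoid = list(
      intercept = 0.65,
      date = c(-0.30, -0.42, -0.50, -0.40),
      management_organic = -0.10,
      cover_crop = c(species_rich = 0.05, spontaneous = 0.25),
      residual_sd = 0.18),
    eriophyoid = list(
      intercept = 0.26,
      date = c(-0.10, -0.15, -0.20, -0.18),
      pct_vineyards = -0.004, vegetation_cover_summer = 0.002,
      residual_sd = 0.10),
    pollen = list(
      intercept = 1.79,
      date = c(0.35, -0.10, -0.15, -0.22),
      management_organic = -0.15,
      cover_crop = c(species_rich = 0.03, spontaneous = 0.15),
      min_dist_woody = 0.0008, pct_vineyards = -0.001,
      residual_sd = 0.18)
  )
  if (!is.null(effects)) {
    default_effects[names(effects)] <- effects
  }
  structure(list(
    n_pairs = n_pairs,
    n_dates = 5L,
    circle_radius_m = 500,
    # per-category application-count means/sds by management
    spray_profile = data.frame(
      category = rep(c("insecticide", "acaricide", "synthetic_fungicide",
                       "sulfur", "copper", "potassium_bicarbonate"), each = 2),
      management = rep(c("organic", "integrated"), times = 6),
      mean = c(0, 0.25, 0.25, 0.38, 0, 5.79, 9.19, 4.13, 8.88, 1.25, 4.44, 0),
      sd   = c(0, 0.45, 0.45, 0.50, 0, 2.58, 1.60, 1.84, 1.84, 0.83, 2.76, 0)),
    # product dose (g/ha) by category, log-normal jitter sd on log scale
    dose_g_per_ha = c(insecticide = 300, acaricide = 500,
                      synthetic_fungicide = 1000, sulfur = 3000,
                      copper = 2000, potassium_bicarbonate = 3000),
    dose_jitter_sdlog = 0.1,
    vegetation_cover = list(
      spring = list(organic = c(mean = 82.4, sd = 18.9),
                    integrated = c(mean = 80.8, sd = 19.5)),
      summer = list(organic = c(mean = 61.7, sd = 22.3),
                    integrated = c(mean = 40.4, sd = 24.8))),
    landscape = list(snh_share = c(0.10, 0.55),
                     vineyard_share = c(0.15, 0.40),
                     woody_fraction = c(0.30, 0.70),
                     excluded_share = 0.05),
    min_dist_woody_range = c(0, 300),
    n_leaves = 25L,
    leaf_area_range_cm2 = c(100, 200),
    square_side_mm = 19,
    counted_fraction = 0.21,
    pollen_composition = c(
      Poaceae = 0.56, Plantaginaceae = 0.083, Pinaceae = 0.073,
      Betulaceae = 0.04, Juglandaceae = 0.03, Amaranthaceae = 0.03,
      Caryophyllaceae = 0.02, Urticaceae = 0.02, Moraceae = 0.01,
      AP = 0.06, NAP = 0.05, "NA" = 0.024),
    # per-vineyard Dirichlet concentration around the base composition and
    # multiplicative structure: spontaneous inter-rows enrich herb pollen,
    # arboreal types are over-represented in spring
    pollen_heterogeneity = 25,
    pollen_spontaneous_herb_boost = 1.5,
    pollen_spring_arboreal_boost = 1.4,
    eriophyoid_zero_inflation = 0.3,
    eriophyoid_species_split = c(eriophyoid_colomerus = 0.7,
                                 eriophyoid_calepitrimerus = 0.3),
    effects = default_effects
  ), class = "vm_config")
}

#' Synthetic toxicological reference table
#'
#' A small synthetic active-ingredient table with PPDB-magnitude honeybee
#' contact LD50s, soil half-lives and T. pyri harm classes: one ingredient
#' per application category, potassium bicarbonate with a deliberately blank
#' half-life (to exercise the shipped 7-day default) and a plant-oil extract
#' with a missing LD50 (to exercise the exclusion path). Values are
#' plausible but synthetic; they are not a toxicology database extract.
#'
#' @return Data frame with columns `name`, `ld50_contact_ug_per_bee`,
#'   `half_life_days`, `harm_class`.
#' @export
default_ingredients <- function() {
  data.frame(
    name = c("sulfur", "copper_hydroxide", "potassium_bicarbonate",
             "triazol_a", "pyrethroid_a", "tetrazine_a", "plant_oil_extract"),
    ld50_contact_ug_per_bee = c(400, 50, 100, 25, 0.1, 10, NA),
    half_life_days = c(4, 1000, NA, 60, 30, 20, 10),
    harm_class = c("slightly_harmful", "harmless", "harmless",
                   "slightly_harmful", "harmful", "harmful", "harmless"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic product composition table
#'
#' One commercial-style product per application category (plus an organic
#' oil spray), in long format. Synthetic counterpart to a product register.
#'
#' @return Data frame with columns `product`, `ingredient`,
#'   `concentration_pct`.
#' @export
default_products <- function() {
  data.frame(
    product = c("wettable_sulfur", "copper_hydroxide_35", "k_bicarb_85",
                "syn_fungicide_a", "insecticide_a", "acaricide_a",
                "oil_spray"),
    ingredient = c("sulfur", "copper_hydroxide", "potassium_bicarbonate",
                   "triazol_a", "pyrethroid_a", "tetrazine_a",
                   "plant_oil_extract"),
    concentration_pct = c(80, 35, 85, 25, 20, 20, 90),
    stringsAsFactors = FALSE
  )
}

rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  pmax(lower, pmin(upper, stats::rnorm(n, mean, sd)))
}

#' Generate the paired-vineyard design
#'
#' Each circle gets exactly one organic and one integrated vineyard;
#' cover-crop types are assigned near-balanced across vineyards; vegetation
#' cover percentages are drawn per season and management; the minimum
#' distance to the nearest woody SNH is drawn per vineyard.
#'
#' @param config A `vm_config` from [synthetic_config()].
#' @return Data frame with one row per vineyard: `vineyard_id`, `circle_id`,
#'   `management`, `cover_crop`, `vegetation_cover_spring`,
#'   `vegetation_cover_summer`, `min_dist_woody`.
#' @export
generate_design <- function(config) {
  n <- 2L * config$n_pairs
  circle_id <- sprintf("c%02d", rep(seq_len(config$n_pairs), each = 2))
  management <- rep(c("organic", "integrated"), times = config$n_pairs)
  levels3 <- c("species_poor", "species_rich", "spontaneous")
  cover_crop <- sample(rep(levels3, length.out = n))
  veg <- function(season) {
    prof <- config$vegetation_cover[[season]]
    vapply(management, function(m) {
      rtrunc_norm(1, prof[[m]][["mean"]], prof[[m]][["sd"]], 0, 100)
    }, numeric(1))
  }
  data.frame(
    vineyard_id = sprintf("v%02d", seq_len(n)),
    circle_id = circle_id,
    management = management,
    cover_crop = cover_crop,
    vegetation_cover_spring = unname(veg("spring")),
    vegetation_cover_summer = unname(veg("summer")),
    min_dist_woody = stats::runif(n, config$min_dist_woody_range[1],
                                  config$min_dist_woody_range[2]),
    stringsAsFactors = FALSE
  )
}

dirichlet_split <- function(total, k) {
  if (k == 1L) return(total)
  w <- stats::rgamma(k, shape = 2)
  total * w / sum(w)
}

#' Generate landscape patch tables
#'
#' Per circle, the total SNH share is drawn uniformly on the configured
#' band (10--55% by default) and split between woody and open SNH classes;
#' the vineyard share is drawn independently of the SNH share so the two
#' composition predictors are not collinear by construction; the four
#' non-analyzed classes occupy a small fixed share; the remainder is split
#' among arable and other analyzed classes. Patch areas per circle sum to
#' the circle area `pi * r^2`.
#'
#' @param config A `vm_config`.
#' @param design Output of [generate_design()].
#' @return Patch data frame with columns `patch_id`, `circle_id`,
#'   `habitat_class`, `area_m2`.
#' @export
generate_landscape <- function(config, design) {
  circles <- unique(design$circle_id)
  area_total <- pi * config$circle_radius_m^2
  ls <- config$landscape
  groups <- habitat_groups()
  woody_classes <- groups$woody_snh
  open_classes <- c("fallow", "grassland", "grass_strip")
  other_classes <- c("dry_grassland", "meadow_orchard", "scrub", "ruderal",
                     "garden")
  excl_classes <- c("artificial", "ponds_rivers", "roads", "yards")
  out <- lapply(circles, function(cid) {
    snh <- stats::runif(1, ls$snh_share[1], ls$snh_share[2])
    viney <- stats::runif(1, ls$vineyard_share[1], ls$vineyard_share[2])
    excl <- ls$excluded_share
    rest <- max(1 - snh - viney - excl, 1e-6)
    arable <- rest * stats::runif(1, 0.3, 0.7)
    other <- rest - arable
    woody <- snh * stats::runif(1, ls$woody_fraction[1], ls$woody_fraction[2])
    open <- snh - woody
    shares <- c(
      stats::setNames(dirichlet_split(woody, length(woody_classes)),
                      woody_classes),
      stats::setNames(dirichlet_split(open, length(open_classes)),
                      open_classes),
      vineyard = viney, arable_crop = arable,
      stats::setNames(dirichlet_split(other, length(other_classes)),
                      other_classes),
      stats::setNames(dirichlet_split(excl, length(excl_classes)),
                      excl_classes))
    shares <- shares[shares > 0]
    data.frame(patch_id = paste0(cid, "_", names(shares)),
               circle_id = cid,
               habitat_class = names(shares),
               area_m2 = unname(shares) * area_total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate spray records
#'
#' Per vineyard, application counts per category are drawn from truncated
#' normals with the configured management-specific means/sds and rounded;
#' organic vineyards receive no insecticides and no synthetic fungicides,
#' integrated ones no potassium bicarbonate (structural zeros of the
#' profile). Products sprayed on the same date form tank mixes, so the
#' number of distinct dates tracks the largest per-category count. Organic
#' acaricide use is the oil spray whose active ingredient carries a missing
#' LD50, exercising the toxicity exclusion path.
#'
#' @param config A `vm_config`.
#' @param design Output of [generate_design()].
#' @return List with `spray` (columns `vineyard_id`, `date`, `product`,
#'   `dose_g_per_ha`, `category`), `ingredients`, `products`.
#' @export
generate_spray_regimes <- function(config, design) {
  profile <- config$spray_profile
  product_for <- function(category, management) {
    switch(category,
           insecticide = "insecticide_a",
           acaricide = if (management == "organic") "oil_spray"
                       else "acaricide_a",
           synthetic_fungicide = "syn_fungicide_a",
           sulfur = "wettable_sulfur",
           copper = "copper_hydroxide_35",
           potassium_bicarbonate = "k_bicarb_85")
  }
  date_pool <- as.character(seq(as.Date("2019-04-15"), by = 7,
                                length.out = 30))
  rows <- list()
  for (i in seq_len(nrow(design))) {
    v <- design$vineyard_id[i]
    m <- design$management[i]
    prof <- profile[profile$management == m, , drop = FALSE]
    for (j in seq_len(nrow(prof))) {
      n_app <- round(rtrunc_norm(1, prof$mean[j], prof$sd[j]))
      if (n_app <= 0) next
      cat <- prof$category[j]
      dose <- config$dose_g_per_ha[[cat]] *
        stats::rlnorm(n_app, 0, config$dose_jitter_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        vineyard_id = v,
        date = date_pool[seq_len(n_app)],
        product = product_for(cat, m),
        dose_g_per_ha = dose,
        category = cat,
        stringsAsFactors = FALSE)
    }
  }
  spray <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vineyard_id = character(), date = character(),
               product = character(), dose_g_per_ha = numeric(),
               category = character())
  list(spray = spray, ingredients = default_ingredients(),
       products = default_products())
}

# Linear predictor for one response over the vineyard x date grid.
linear_predictor <- function(eff, grid) {
  lp <- rep(eff$intercept, nrow(grid))
  date_eff <- c(0, eff$date)
  lp <- lp + date_eff[grid$date_index]
  if (!is.null(eff$management_organic)) {
    lp <- lp + ifelse(grid$management == "organic",
                      eff$management_organic, 0)
  }
  if (!is.null(eff$cover_crop)) {
    cc <- c(species_poor = 0, eff$cover_crop)
    lp <- lp + unname(cc[grid$cover_crop])
  }
  for (term in c("pct_vineyards", "pct_total_snh", "min_dist_woody",
                 "vegetation_cover_spring", "vegetation_cover_summer")) {
    if (!is.null(eff[[term]])) lp <- lp + eff[[term]] * grid[[term]]
  }
  lp
}

#' Generate leaf-wash and pollen samples
#'
#' For each response a linear predictor on the log10(y + 1) scale combines
#' the configured effects with Gaussian noise, is back-transformed to a
#' density and converted to integer counts given a drawn leaf area (25
#' leaves of 100--200 cm2 each) or tape-square geometry. Eriophyoid counts
#' are split into the two species and zero-inflated; spider mites are always
#' zero. Pollen grains are drawn multinomially from the configured
#' composition, with the community total following the pollen predictor
#' (early-June peak).
#'
#' @param config A `vm_config`.
#' @param design Output of [generate_design()].
#' @param landscape Patch table from [generate_landscape()].
#' @return List with `mite_samples` (long leaf-wash schema), `pollen_samples`
#'   (long tape schema) and `expected` (the noiseless transformed means, for
#'   diagnostics).
#' @export
generate_field_samples <- function(config, design, landscape) {
  comp <- landscape_composition(landscape)
  grid <- merge(design, comp, by.x = "circle_id", by.y = "circle_id")
  grid <- grid[rep(seq_len(nrow(grid)), each = config$n_dates), ]
  grid$date_index <- rep(seq_len(config$n_dates),
                         times = nrow(grid) / config$n_dates)
  rownames(grid) <- NULL

  densities <- list()
  expected <- list()
  for (resp in names(config$effects)) {
    eff <- config$effects[[resp]]
    mu <- linear_predictor(eff, grid)
    z <- mu + stats::rnorm(nrow(grid), 0, eff$residual_sd)
    densities[[resp]] <- pmax(0, back_transform(z))
    expected[[resp]] <- mu
  }

  # leaf-wash samples ---------------------------------------------------------
  n_vd <- nrow(grid)
  leaf_area <- vapply(seq_len(n_vd), function(i) {
    sum(stats::runif(config$n_leaves, config$leaf_area_range_cm2[1],
                     config$leaf_area_range_cm2[2]))
  }, numeric(1))
  split <- config$eriophyoid_species_split
  zero <- stats::runif(n_vd) < config$eriophyoid_zero_inflation
  erio <- ifelse(zero, 0, densities$eriophyoid)
  taxon_density <- cbind(
    phytoseiid = densities$phytoseiid,
    tydeoid = densities$tydeoid,
    eriophyoid_colomerus = erio * split[["eriophyoid_colomerus"]],
    eriophyoid_calepitrimerus = erio * split[["eriophyoid_calepitrimerus"]],
    spider_mite = 0)
  mite_rows <- lapply(colnames(taxon_density), function(tx) {
    data.frame(vineyard_id = grid$vineyard_id,
               date_index = grid$date_index,
               taxon = tx,
               count = round(taxon_density[, tx] / 100 * leaf_area),
               leaf_area_cm2 = leaf_area,
               stringsAsFactors = FALSE)
  })
  mite_samples <- do.call(rbind, mite_rows)
  mite_samples <- mite_samples[order(mite_samples$vineyard_id,
                                     mite_samples$date_index,
                                     mite_samples$taxon), ]
  rownames(mite_samples) <- NULL

  # pollen tape samples -------------------------------------------------------
  area_cm2 <- (config$square_side_mm / 10)^2
  counted_area <- config$counted_fraction * area_cm2
  probs <- config$pollen_composition / sum(config$pollen_composition)
  herb_types <- c("Poaceae", "Amaranthaceae", "Plantaginaceae")
  arboreal_types <- c("Pinaceae", "Betulaceae", "Juglandaceae", "AP")
  # stable per-vineyard composition: Dirichlet around the base mixture,
  # with an herb-pollen boost under spontaneous inter-row vegetation
  vids <- unique(grid$vineyard_id)
  probs_v <- t(vapply(vids, function(v) {
    w <- probs
    if (grid$cover_crop[match(v, grid$vineyard_id)] == "spontaneous") {
      w[herb_types] <- w[herb_types] * config$pollen_spontaneous_herb_boost
    }
    g <- stats::rgamma(length(w), shape = w * config$pollen_heterogeneity)
    g / sum(g)
  }, numeric(length(probs))))
  rownames(probs_v) <- vids
  colnames(probs_v) <- names(probs)
  pollen_rows <- lapply(seq_len(n_vd), function(i) {
    p <- probs_v[grid$vineyard_id[i], ]
    if (grid$date_index[i] <= 2) {
      p[arboreal_types] <- p[arboreal_types] *
        config$pollen_spring_arboreal_boost
      p <- p / sum(p)
    }
    total_grains <- stats::rpois(1, densities$pollen[i] * counted_area)
    grains <- if (total_grains > 0) {
      as.integer(stats::rmultinom(1, total_grains, p))
    } else integer(length(probs))
    data.frame(vineyard_id = grid$vineyard_id[i],
               date_index = grid$date_index[i],
               pollen_type = names(probs),
               grains = grains,
               counted_fraction = config$counted_fraction,
               square_side_mm = config$square_side_mm,
               stringsAsFactors = FALSE)
  })
  pollen_samples <- do.call(rbind, pollen_rows)
  rownames(pollen_samples) <- NULL

  list(mite_samples = mite_samples, pollen_samples = pollen_samples,
       expected = data.frame(grid[, c("vineyard_id", "date_index")],
                             as.data.frame(expected)))
}

#' Generate a complete synthetic study
#'
#' Runs the design, landscape, spray and field-sample generators under one
#' seed; identical config + seed give identical output.
#'
#' @param config A `vm_config` from [synthetic_config()].
#' @param seed Integer seed for all randomness.
#' @return List of class `vm_study`: `design`, `patches`, `spray`,
#'   `ingredients`, `products`, `mite_samples`, `pollen_samples`,
#'   `ground_truth` (config, seed and noiseless expected means).
#' @export
generate_study <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  design <- generate_design(config)
  patches <- generate_landscape(config, design)
  sprays <- generate_spray_regimes(config, design)
  samples <- generate_field_samples(config, design, patches)
  structure(list(
    design = design,
    patches = patches,
    spray = sprays$spray,
    ingredients = sprays$ingredients,
    products = sprays$products,
    mite_samples = samples$mite_samples,
    pollen_samples = samples$pollen_samples,
    ground_truth = list(config = config, seed = seed,
                        expected = samples$expected)
  ), class = "vm_study")
}
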