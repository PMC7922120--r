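test_that("active-ingredient amounts multiply dose by concentration", {
  expect_equal(nrow(active_ingredient_amounts(empty_spray(),
                                              tiny_products())$totals), 0)

  prods <- data.frame(product = "sulfur80", ingredient = "sulfur",
                      concentration_pct = 80)
  out <- active_ingredient_amounts(app(product = "sulfur80", dose = 2000),
                                   prods)
  expect_equal(out$totals$total_g_per_ha, 1600)

  prods2 <- data.frame(product = "half", ingredient = "x",
                       concentration_pct = 50)
  spray2 <- rbind(app(product = "half", date = "2019-05-01", dose = 1000),
                  app(product = "half", date = "2019-06-01", dose = 1000))
  out2 <- active_ingredient_amounts(spray2, prods2)
  expect_equal(out2$per_application$amount_g_per_ha, c(500, 500))
  expect_equal(out2$totals$total_g_per_ha, 1000)

  expect_error(active_ingredient_amounts(app(product = "ghost"), prods),
               "ghost")
})

test_that("aAPTLc evaluates the hazard-quotient x persistence formula", {
  ing <- tiny_ingredients(); prods <- tiny_products()

  expect_equal(aaptlc(empty_spray(), ing, prods,
                      vineyard_ids = "v1")$scores$aaptlc, 0)

  # 1000 g/ha at 100%, LD50 100, half-life ln 2 days: 10 * 1 * 1e-4
  out <- aaptlc(app(product = "p_alpha", dose = 1000), ing, prods)
  expect_equal(out$scores$aaptlc, 1e-3, tolerance = 1e-12)

  # half-life = ln 2 makes the persistence multiplier exactly 1
  ing2 <- ing; ing2$half_life_days[ing2$name == "alpha"] <- 1
  out2 <- aaptlc(app(product = "p_alpha", dose = 1000), ing2, prods)
  expect_equal(out$scores$aaptlc * 1 / log(2), out2$scores$aaptlc)
})

test_that("potassium bicarbonate uses the configured 7-day half-life", {
  ing <- data.frame(name = "potassium_bicarbonate",
                    ld50_contact_ug_per_bee = 100,
                    half_life_days = NA_real_, harm_class = "harmless")
  prods <- data.frame(product = "khco3_85",
                      ingredient = "potassium_bicarbonate",
                      concentration_pct = 85)
  spray <- app(product = "khco3_85", dose = 3000,
               category = "potassium_bicarbonate")
  out <- aaptlc(spray, ing, prods)
  expect_equal(out$scores$aaptlc,
               1e-4 * (3000 * 0.85) / 100 * 7 / log(2), tolerance = 1e-12)
  expect_equal(nrow(out$excluded), 0)

  # without the default the ingredient is excluded and the score is 0
  expect_warning(
    out2 <- aaptlc(spray, ing, prods, halflife_defaults = NULL),
    "excluded")
  expect_equal(out2$scores$aaptlc, 0)
  expect_equal(out2$excluded$reason, "missing half_life")
})

test_that("missing toxicology excludes the ingredient and reports it", {
  ing <- tiny_ingredients(); prods <- tiny_products()
  spray <- rbind(app(product = "p_alpha", dose = 1000),
                 app(product = "p_no_ld50", date = "2019-05-02", dose = 500),
                 app(product = "p_no_hl", date = "2019-05-03", dose = 500))
  out <- aaptlc(spray, ing, prods)
  expect_setequal(out$excluded$ingredient, c("no_ld50", "no_hl"))
  expect_equal(out$scores$aaptlc, 1e-3, tolerance = 1e-12)
  expect_error(aaptlc(app(dose = -5), ing, prods), "negative dose")
})

test_that("aAPTLc is additive, dose-linear and monotone", {
  set.seed(42)
  for (rep in 1:20) {
    rr <- random_regime(n_apps = sample(1:5, 1))
    base <- aaptlc(rr$spray, rr$ingredients, rr$products)$scores$aaptlc

    # additivity over concatenated regimes
    spray_b <- rr$spray
    spray_b$date <- sprintf("2019-07-%02d", seq_len(nrow(spray_b)))
    both <- rbind(rr$spray, spray_b)
    expect_equal(aaptlc(both, rr$ingredients, rr$products)$scores$aaptlc,
                 2 * base, tolerance = 1e-12)

    # linearity in dose
    doubled <- rr$spray; doubled$dose_g_per_ha <- 2 * doubled$dose_g_per_ha
    expect_equal(aaptlc(doubled, rr$ingredients, rr$products)$scores$aaptlc,
                 2 * base, tolerance = 1e-12)

    # adding an application never decreases the score
    extra <- rbind(rr$spray, app(product = rr$products$product[1],
                                 date = "2019-08-01", dose = 100))
    expect_gte(aaptlc(extra, rr$ingredients, rr$products)$scores$aaptlc, base)
  }
})

test_that("per-ingredient contribution vanishes as LD50 grows", {
  prods <- data.frame(product = "p", ingredient = "x",
                      concentration_pct = 100)
  scores <- vapply(c(1e2, 1e6, 1e12), function(ld50) {
    ing <- data.frame(name = "x", ld50_contact_ug_per_bee = ld50,
                      half_life_days = 10, harm_class = "harmless")
    aaptlc(app(product = "p"), ing, prods)$scores$aaptlc
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_lt(scores[3], 1e-11)
})

test_that("T. pyri rating sums the 0.4/0.8/1.0 scale per occurrence", {
  ing <- tiny_ingredients(); prods <- tiny_products()
  expect_equal(tpyri_rating(empty_spray(), ing, prods,
                            vineyard_ids = "v1")$scores$tpyri_rating, 0)
  expect_equal(tpyri_rating(app(product = "p_alpha"), ing,
                            prods)$scores$tpyri_rating, 0.4)
  spray3 <- rbind(app(product = "p_alpha"),
                  app(product = "p_beta", date = "2019-05-02"),
                  app(product = "p_gamma", date = "2019-05-03"))
  out <- tpyri_rating(spray3, ing, prods)
  expect_equal(out$scores$tpyri_rating, 0.4 + 0.8 + 1.0)

  # repeated applications of the same ingredient count once per occurrence
  twice <- rbind(app(product = "p_gamma"),
                 app(product = "p_gamma", date = "2019-05-09"))
  expect_equal(tpyri_rating(twice, ing, prods)$scores$tpyri_rating, 2.0)

  # unknown harm class is excluded and reported
  out_u <- tpyri_rating(app(product = "p_mystery"), ing, prods)
  expect_equal(out_u$scores$tpyri_rating, 0)
  expect_equal(out_u$excluded$ingredient, "mystery")
})

test_that("rating is bounded by 0.4 and 1.0 per occurrence", {
  set.seed(7)
  for (rep in 1:20) {
    rr <- random_regime(n_apps = sample(1:5, 1))
    score <- tpyri_rating(rr$spray, rr$ingredients,
                          rr$products)$scores$tpyri_rating
    n_occ <- nrow(rr$spray)  # one ingredient per product here
    expect_gte(score, 0.4 * n_occ)
    expect_lte(score, 1.0 * n_occ)
  }
})

test_that("application totals count tank mixes as single applications", {
  ing <- tiny_ingredients(); prods <- tiny_products()
  expect_equal(application_counts(empty_spray(), vineyard_ids = "v1")$n_total,
               0L)
  mix <- rbind(app(product = "p_alpha", category = "sulfur"),
               app(product = "p_beta", category = "copper"))
  out <- application_counts(mix)
  expect_equal(out$n_total, 1L)
  expect_equal(out$n_sulfur, 1L)
  expect_equal(out$n_copper, 1L)

  three <- rbind(app(date = "2019-05-01"), app(date = "2019-05-08"),
                 app(date = "2019-05-15"))
  expect_equal(application_counts(three)$n_total, 3L)

  summary <- toxicity_summary(mix, ing, prods)
  cat_cols <- grep("^n_", names(summary), value = TRUE)
  cat_cols <- setdiff(cat_cols, "n_total")
  expect_equal(sum(summary[, cat_cols]), 2)
})
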