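test_that("response transform is log10(y+1) with exact round-trip", {
  expect_equal(transform_response(c(0, 9, 99)), c(0, 1, 2))
  expect_error(transform_response(-1), "non-negative")
  y <- c(0, 0.3, 7.13, 138.41)
  expect_equal(back_transform(transform_response(y)), y, tolerance = 1e-12)
})

test_that("collinearity screen flags pairs at |r| >= 0.5", {
  set.seed(1)
  x <- rnorm(1000)
  df <- data.frame(a = x, b = rnorm(1000), neg = -x, same = x,
                   const = rep(1, 1000))
  scr <- collinearity_screen(df)
  pair <- function(v1, v2) {
    p <- scr$pairs
    p$excluded[(p$var1 == v1 & p$var2 == v2) | (p$var1 == v2 & p$var2 == v1)]
  }
  expect_false(pair("a", "b"))       # independent normals
  expect_true(pair("a", "same"))     # r = 1
  expect_true(pair("a", "neg"))      # r = -1, absolute-value rule
  expect_equal(scr$constant, "const")

  # categorical predictors screened through indicator contrasts
  df2 <- data.frame(g = rep(c("u", "v"), each = 20),
                    x = rep(c(0, 1), each = 20) + rnorm(40, sd = 0.01))
  expect_true(collinearity_screen(df2)$pairs$excluded)
})

test_that("VIF equals 1/(1 - R2) of the auxiliary regression", {
  set.seed(2)
  n <- 60
  # orthogonal design: VIF exactly 1
  ortho <- data.frame(a = rep(c(-1, 1), n / 2),
                      b = rep(c(-1, -1, 1, 1), n / 4))
  expect_equal(unname(vif(ortho)), c(1, 1), tolerance = 1e-12)

  # duplicated predictor: infinite
  dup <- data.frame(a = rnorm(n)); dup$b <- dup$a
  expect_true(all(is.infinite(vif(dup))))

  # near-duplicate matches the closed form from an independent LS solve
  nd <- data.frame(x1 = rnorm(n), z = rnorm(n))
  nd$x2 <- nd$x1 + rnorm(n, sd = 0.1)
  v <- vif(nd, terms = c("x1", "x2", "z"))
  X <- cbind(1, nd$x2, nd$z)
  beta <- solve(crossprod(X), crossprod(X, nd$x1))
  r2_aux <- 1 - sum((nd$x1 - X %*% beta)^2) / sum((nd$x1 - mean(nd$x1))^2)
  expect_equal(unname(v["x1"]), 1 / (1 - r2_aux), tolerance = 1e-8)

  # cross-check against car's implementation on a numeric design
  fit <- lm(rnorm(n) ~ x1 + x2 + z, data = nd)
  expect_equal(unname(v[c("x1", "x2", "z")]), unname(car::vif(fit)),
               tolerance = 1e-8)
})

test_that("candidate enumeration respects forcing, caps and exclusions", {
  two <- enumerate_candidates("date")
  expect_length(two, 2)
  expect_identical(two[[1]], character(0))

  four <- enumerate_candidates(c("date", "A", "B"),
                               exclusions = list(c("A", "B")), max_extra = 2)
  labels <- vapply(four, function(x) paste(x, collapse = "+"), "")
  expect_setequal(labels, c("", "date", "date+A", "date+B"))

  # 6 extra terms with up to 3 per model: 42 non-null candidates
  pool42 <- enumerate_candidates(c("date", paste0("x", 1:6)), max_extra = 3)
  expect_equal(attr(pool42, "n_models"), 42)

  expect_error(
    enumerate_candidates(c("date", "A", "B"),
                         exclusions = list(c("A", "B")),
                         models = list(c("date", "A", "B"))),
    "exclusion")
})

test_that("Gaussian GLM fit matches closed-form likelihood and LS solves", {
  # exact linear response: R2 = adjusted R2 = 1
  d <- data.frame(x = 1:10)
  d$y <- 2 + 3 * d$x
  fit <- fit_gaussian_glm("y", "x", d)
  expect_equal(fit$adj_r2, 1)

  # intercept-only closed form: sigma2 = 0.25 for y = (0,0,1,1)
  d2 <- data.frame(y = c(0, 0, 1, 1))
  f2 <- fit_gaussian_glm("y", character(0), d2)
  n <- 4; sigma2 <- 0.25; k <- 2
  ll <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  expect_equal(f2$loglik, ll, tolerance = 1e-9)
  expect_equal(f2$k, k)
  expect_equal(f2$aicc, -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)
  expect_gt(f2$aicc, f2$aic)  # correction is positive when n - k - 1 > 0

  # coefficients match an independent normal-equations solve
  set.seed(5)
  d3 <- data.frame(x1 = rnorm(40), x2 = rnorm(40),
                   g = factor(rep(letters[1:2], 20)))
  d3$y <- 1 + 0.5 * d3$x1 - 0.2 * d3$x2 + (d3$g == "b") + rnorm(40)
  f3 <- fit_gaussian_glm("y", c("x1", "x2", "g"), d3)
  X <- model.matrix(~ x1 + x2 + g, d3)
  beta <- solve(crossprod(X), crossprod(X, d3$y))
  expect_equal(f3$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)

  # aliased designs error with the offending term
  d4 <- d3; d4$x3 <- d4$x1
  expect_error(fit_gaussian_glm("y", c("x1", "x3"), d4), "aliased")
})

test_that("AICc ranking orders models and applies the delta threshold", {
  single <- rank_models(list(fake_fit("date", -10)))
  expect_equal(single$delta_i, 0)
  expect_true(single$selected)

  pair <- rank_models(list(
    fake_fit("date + management + cover_crop + pct_vineyards + pct_total_snh",
             -45.87),
    fake_fit(paste("date + management + cover_crop + pct_vineyards +",
                   "pct_total_snh + pollen"), -43.74)))
  expect_equal(pair$delta_i, c(0, 2.13), tolerance = 1e-9)
  expect_equal(pair$selected, c(TRUE, FALSE))

  # permutation invariance of the ranking
  fits <- list(fake_fit("a", -5, k = 3), fake_fit("b", -7, k = 4),
               fake_fit("null", -6, k = 2))
  r1 <- rank_models(fits)
  r2 <- rank_models(rev(fits))
  expect_identical(r1$model, r2$model)
  expect_equal(r1$delta_i, r2$delta_i)

  # AICc ties broken by parameter count
  tied <- rank_models(list(fake_fit("big", -5, k = 6),
                           fake_fit("small", -5, k = 3)))
  expect_equal(tied$model, c("small", "big"))
})

test_that("adding a pure-noise predictor increases AICc in expectation", {
  set.seed(9)
  diffs <- replicate(40, {
    d <- data.frame(x = rnorm(50), noise = rnorm(50))
    d$y <- 1 + d$x + rnorm(50)
    fit_gaussian_glm("y", c("x", "noise"), d)$aicc -
      fit_gaussian_glm("y", "x", d)$aicc
  })
  expect_gt(mean(diffs), 0)
})
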