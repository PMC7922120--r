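## log10(y+1) response transform, collinearity / VIF screening, candidate
## enumeration, Gaussian-GLM fitting and AICc ranking.

#' log10(y + 1) response transform
#'
#' The densities are right-skewed with genuine zeros, so responses are
#' modelled on the `log10(y + 1)` scale: strictly monotone, 0 maps to 0.
#'
#' @param y Non-negative numeric vector.
#' @return Transformed vector.
#' @export
transform_response <- function(y) {
  if (any(y < 0, na.rm = TRUE)) {
    stop("response values must be non-negative", call. = FALSE)
  }
  log10(y + 1)
}

#' Inverse of [transform_response()]
#' @param z Transformed values.
#' @return Original-scale values.
#' @export
back_transform <- function(z) 10^z - 1

# Contrast columns of one variable (indicator encoding for factors/characters,
# the column itself for numerics), for correlation screening.
contrast_columns <- function(x) {
  if (is.numeric(x)) return(matrix(x, ncol = 1))
  x <- factor(x)
  stats::model.matrix(~ x)[, -1, drop = FALSE]
}

#' Pairwise collinearity screen
#'
#' Flags every unordered pair of predictors whose absolute Pearson
#' correlation reaches the threshold (default 0.5); flagged pairs must not
#' enter the same candidate model. Categorical predictors are expanded to
#' indicator contrasts and a pair is flagged when any contrast pair crosses
#' the threshold. Constant columns cannot be correlated and are reported
#' separately.
#'
#' @param predictors Data frame of candidate predictors (numeric, factor or
#'   character columns).
#' @param threshold Absolute-correlation exclusion threshold.
#' @return List with `pairs` (data frame `var1`, `var2`, `max_abs_cor`,
#'   `excluded`) and `constant` (names of constant columns).
#' @export
collinearity_screen <- function(predictors, threshold = 0.5) {
  stopifnot(is.data.frame(predictors))
  if (nrow(predictors) < 3L) {
    stop("need at least 3 rows to screen collinearity", call. = FALSE)
  }
  vars <- names(predictors)
  cols <- lapply(predictors, contrast_columns)
  constant <- vars[vapply(cols, function(m) {
    all(apply(m, 2, function(v) stats::sd(v) == 0))
  }, logical(1))]
  usable <- setdiff(vars, constant)
  if (length(usable) < 2L) {
    return(list(pairs = data.frame(var1 = character(), var2 = character(),
                                   max_abs_cor = numeric(),
                                   excluded = logical()),
                constant = constant))
  }
  pairs <- t(utils::combn(usable, 2))
  max_abs <- apply(pairs, 1, function(pr) {
    r <- suppressWarnings(stats::cor(cols[[pr[1]]], cols[[pr[2]]]))
    max(abs(r), na.rm = TRUE)
  })
  list(pairs = data.frame(var1 = pairs[, 1], var2 = pairs[, 2],
                          max_abs_cor = max_abs,
                          excluded = max_abs >= threshold),
       constant = constant)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing design column
#' j on all the others (auxiliary least squares). Perfectly collinear
#' columns get `Inf`. Terms with VIF > 5 are conventionally removed from the
#' candidate pool.
#'
#' @param predictors Data frame of predictors.
#' @param terms Which columns to assess (default all).
#' @return Named numeric vector of VIFs, one per design column (factor terms
#'   contribute one entry per contrast).
#' @export
vif <- function(predictors, terms = names(predictors)) {
  X <- stats::model.matrix(
    stats::reformulate(terms), data = predictors)[, -1, drop = FALSE]
  if (ncol(X) < 2L) {
    out <- rep(1, ncol(X)); names(out) <- colnames(X); return(out)
  }
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

normalize_exclusions <- function(exclusions) {
  if (is.null(exclusions)) return(list())
  if (is.data.frame(exclusions) || is.matrix(exclusions)) {
    exclusions <- lapply(seq_len(nrow(exclusions)),
                         function(i) as.character(unlist(exclusions[i, 1:2])))
  }
  exclusions
}

violates_exclusions <- function(terms, exclusions) {
  for (pr in exclusions) {
    if (all(pr %in% terms)) return(TRUE)
  }
  FALSE
}

#' Enumerate candidate models
#'
#' Emits the null (intercept-only) model plus every additive combination of
#' the forced term(s) with up to `max_extra` further pool terms, dropping any
#' combination that contains an excluded (collinear) pair. With 6 extra
#' terms and `max_extra = 3` this yields the 42 non-null candidates of a
#' date-forced candidate set. Alternatively an explicit `models` list can be
#' supplied (and is validated against the exclusions).
#'
#' @param pool Character vector of candidate terms (including forced terms).
#' @param exclusions List of length-2 character vectors (or a two-column
#'   data frame) of term pairs that must not co-occur.
#' @param force Terms present in every non-null model (default `"date"` if
#'   in the pool).
#' @param max_extra Maximum number of non-forced terms per model.
#' @param include_null Include the intercept-only model.
#' @param models Optional explicit list of character vectors of terms, used
#'   verbatim after validation.
#' @return List of candidate models; each element is a character vector of
#'   terms (`character(0)` = null model). The number of non-null candidates
#'   is attached as attribute `"n_models"`.
#' @export
enumerate_candidates <- function(pool, exclusions = NULL,
                                 force = intersect("date", pool),
                                 max_extra = length(setdiff(pool, force)),
                                 include_null = TRUE, models = NULL) {
  if (length(pool) == 0L && is.null(models)) {
    stop("candidate pool is empty", call. = FALSE)
  }
  exclusions <- normalize_exclusions(exclusions)
  if (!is.null(models)) {
    for (m in models) {
      if (violates_exclusions(m, exclusions)) {
        stop(sprintf("explicit model {%s} violates a collinearity exclusion",
                     paste(m, collapse = ", ")), call. = FALSE)
      }
    }
    out <- models
    if (include_null && !any(vapply(out, length, 1L) == 0L)) {
      out <- c(list(character(0)), out)
    }
  } else {
    extras <- setdiff(pool, force)
    combos <- list()
    for (j in 0:min(max_extra, length(extras))) {
      sets <- if (j == 0) list(character(0)) else {
        cc <- utils::combn(extras, j, simplify = FALSE)
        cc
      }
      for (s in sets) {
        terms <- c(force, s)
        if (length(terms) == 0L) next
        if (!violates_exclusions(terms, exclusions)) {
          combos[[length(combos) + 1L]] <- terms
        }
      }
    }
    out <- combos
    if (include_null) out <- c(list(character(0)), out)
  }
  attr(out, "n_models") <- sum(vapply(out, length, 1L) > 0L)
  out
}

#' Fit one Gaussian GLM candidate
#'
#' Identity-link Gaussian GLM, i.e. maximum-likelihood least squares of the
#' (already transformed) response on the additive terms. The parameter count
#' `k` includes the intercept, all coefficients and the residual variance,
#' the convention under which `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`
#' matches standard small-sample AIC implementations. The adjusted R2 uses
#' `1 - (1 - R2)(n - 1)/(n - p - 1)` with `p` coefficients excluding the
#' intercept.
#'
#' @param response Name of the (transformed) response column.
#' @param terms Character vector of predictor terms (`character(0)` fits the
#'   null model).
#' @param data Analysis table containing response and predictors.
#' @return Object of class `vm_fit`: list with `response`, `terms`, `label`,
#'   `n`, `k`, `loglik`, `aic`, `aicc`, `r2`, `adj_r2` and a `coefficients`
#'   data frame (term, estimate, se).
#' @export
fit_gaussian_glm <- function(response, terms, data) {
  fml <- if (length(terms) == 0L) {
    stats::reformulate("1", response = response)
  } else {
    stats::reformulate(terms, response = response)
  }
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    stop(sprintf("rank-deficient design; aliased: %s",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")), call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  ll <- stats::logLik(fit)            # Gaussian ML (variance divided by n)
  k <- as.integer(attr(ll, "df"))     # coefficients + residual variance
  if (n - k - 1 <= 0) {
    stop(sprintf("n = %d too small for k = %d parameters (AICc undefined)",
                 n, k), call. = FALSE)
  }
  aic <- -2 * as.numeric(ll) + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  sm <- summary(fit)
  p <- length(stats::coef(fit)) - 1L
  r2 <- sm$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(
    response = response,
    terms = terms,
    label = if (length(terms) == 0L) "null" else paste(terms, collapse = " + "),
    n = n, k = k,
    loglik = as.numeric(ll),
    aic = aic, aicc = aicc,
    r2 = r2, adj_r2 = adj,
    coefficients = data.frame(term = rownames(sm$coefficients),
                              estimate = sm$coefficients[, 1],
                              se = sm$coefficients[, 2],
                              row.names = NULL),
    lm = fit
  ), class = "vm_fit")
}

#' Rank fitted candidates by AICc
#'
#' Computes `delta_i = AICc_i - min(AICc)`, sorts ascending by AICc (ties
#' broken by fewer parameters, then by model label) and marks the
#' parsimonious set `delta_i <= delta_threshold`.
#'
#' @param fits List of `vm_fit` objects (same response).
#' @param delta_threshold Delta-AICc cut for the parsimonious set (default 2).
#' @return Data frame (class `vm_selection`) with columns `model`, `k`,
#'   `loglik`, `aicc`, `delta_i`, `adj_r2`, `selected`, ordered by AICc.
#' @export
rank_models <- function(fits, delta_threshold = 2) {
  stopifnot(length(fits) >= 1L)
  tab <- data.frame(
    model = vapply(fits, function(f) f$label, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1))
  )
  ord <- order(tab$aicc, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_i <- tab$aicc - tab$aicc[1]
  tab$selected <- tab$delta_i <= delta_threshold
  tab <- tab[, c("model", "k", "loglik", "aicc", "delta_i", "adj_r2",
                 "selected")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  attr(tab, "tied_best") <- sum(tab$aicc == tab$aicc[1]) > 1L
  class(tab) <- c("vm_selection", "data.frame")
  tab
}

#' Full model-selection run for one response
#'
#' Fits every candidate model and returns the AICc ranking.
#'
#' @inheritParams fit_gaussian_glm
#' @param candidates List of term vectors from [enumerate_candidates()].
#' @param delta_threshold Passed to [rank_models()].
#' @return A `vm_selection` table; the fitted objects are in the `"fits"`
#'   attribute, aligned with the rows.
#' @export
model_selection <- function(response, candidates, data, delta_threshold = 2) {
  fits <- lapply(candidates, function(tm) fit_gaussian_glm(response, tm, data))
  rank_models(fits, delta_threshold)
}
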