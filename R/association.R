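## Spearman correlations, Bray-Curtis dissimilarity, NMDS ordination and
## environmental trait fitting for the pollen-community analyses.

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average (midrank) ranks; the p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. Incomplete pairs are dropped listwise; a
#' constant vector leaves rho undefined (returned as `NA` with a warning).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List with `rho`, `p_value` and `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)`, in [0, 1], via
#' [vegan::vegdist()]. A pair of all-zero rows has no defined numerator or
#' denominator; it is set to 0 (identical empty communities) with a warning.
#'
#' @param mat Non-negative community matrix (rows = sites, columns = types).
#' @param method Dissimilarity passed to [vegan::vegdist()]; the default
#'   Bray-Curtis is the conventional choice for abundance data, with
#'   `"euclidean"` and `"jaccard"` as alternatives.
#' @return A `dist` object.
#' @export
bray_curtis <- function(mat, method = "bray") {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("community matrix must be non-negative", call. = FALSE)
  zero_rows <- rowSums(mat) == 0
  d <- suppressWarnings(vegan::vegdist(mat, method = method))
  if (any(zero_rows)) {
    warning("all-zero community row(s); their mutual dissimilarity set to 0",
            call. = FALSE)
    m <- as.matrix(d)
    m[zero_rows, zero_rows] <- 0
    d <- stats::as.dist(m)
  }
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS (0--1 scale) via [vegan::metaMDS()] on a
#' precomputed dissimilarity matrix, with random restarts; deterministic for
#' a fixed seed. Stress above ~0.2 warns that the configuration should be
#' interpreted with care.
#'
#' @param d A `dist` object (square symmetric, zero diagonal).
#' @param k Number of ordination dimensions.
#' @param n_restarts Random restarts (`try`/`trymax` of [vegan::metaMDS()]).
#' @param seed Integer seed controlling the restarts.
#' @return List of class `vm_nmds`: `scores` (n x k matrix, centred),
#'   `stress` (0--1), `k`, `converged`, and the underlying `ord` object.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1) {
  stopifnot(inherits(d, "dist") || (is.matrix(d) && isSymmetric(unname(d))))
  d <- stats::as.dist(d)
  set.seed(seed)
  ord <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   trace = 0, wascores = FALSE)
  ))
  if (!isTRUE(ord$converged)) {
    warning("NMDS did not converge; best configuration returned",
            call. = FALSE)
  }
  scores <- vegan::scores(ord, display = "sites")
  scores <- scale(scores, center = TRUE, scale = FALSE)
  structure(list(scores = scores, stress = ord$stress, k = k,
                 converged = isTRUE(ord$converged), ord = ord),
            class = "vm_nmds")
}

#' Fit environmental traits onto an ordination
#'
#' Continuous traits are fitted as least-squares directions in score space
#' (reported with squared correlation r2); categorical traits as level
#' centroids with a goodness-of-fit r2. Significance comes from permuting
#' trait rows ([vegan::envfit()], seeded). Constant traits are skipped with
#' a warning.
#'
#' @param ordination A `vm_nmds` object (or a score matrix).
#' @param traits Data frame of traits, rows aligned with ordination rows.
#' @param n_permutations Number of permutations for the p-values.
#' @param seed Integer seed.
#' @return List with `vectors` (data frame: trait, one direction cosine per
#'   axis, r2, p_value) and `factors` (data frame: trait, level centroids
#'   summarised by r2 and p_value), plus the raw `envfit` object.
#' @export
fit_traits <- function(ordination, traits, n_permutations = 999, seed = 1) {
  scores <- if (inherits(ordination, "vm_nmds")) ordination$scores
            else as.matrix(ordination)
  stopifnot(nrow(scores) == nrow(traits))
  constant <- vapply(traits, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant)) {
    warning(sprintf("constant trait(s) skipped: %s",
                    paste(names(traits)[constant], collapse = ", ")),
            call. = FALSE)
    traits <- traits[, !constant, drop = FALSE]
  }
  if (ncol(traits) == 0L) stop("no non-constant traits to fit", call. = FALSE)
  set.seed(seed)
  ef <- vegan::envfit(scores, traits, permutations = n_permutations)
  vectors <- NULL
  if (!is.null(ef$vectors)) {
    vectors <- data.frame(trait = rownames(ef$vectors$arrows),
                          ef$vectors$arrows,
                          r2 = ef$vectors$r,
                          p_value = ef$vectors$pvals,
                          row.names = NULL)
  }
  factors <- NULL
  if (!is.null(ef$factors)) {
    factors <- data.frame(trait = names(ef$factors$r),
                          r2 = ef$factors$r,
                          p_value = ef$factors$pvals,
                          row.names = NULL)
  }
  list(vectors = vectors, factors = factors, envfit = ef)
}

#' Split vineyard-date records into spring and summer
#'
#' Spring comprises sampling dates 1--2 (early May, early June), summer
#' dates 3--5 (July and August); the split is exhaustive and disjoint.
#'
#' @param records Data frame with a `date_index` column in 1--5.
#' @return List with `spring` and `summer` data frames.
#' @export
split_season <- function(records) {
  check_columns(records, "date_index", "records")
  bad <- setdiff(unique(records$date_index), 1:5)
  if (length(bad) > 0L) {
    stop(sprintf("unknown date_index: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  list(spring = records[records$date_index %in% 1:2, , drop = FALSE],
       summer = records[records$date_index %in% 3:5, , drop = FALSE])
}
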