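## Study containers, schema validation, assembly of the analysis table and
## the end-to-end pipeline.

#' Default pipeline settings
#'
#' Collects the constants of the analysis in one place: the aAPTLc scaling
#' and half-life defaults, collinearity and VIF thresholds, the delta-AICc
#' cut, candidate-pool definitions per response (six extra terms, date
#' forced in every non-null model, up to four extras so that the largest
#' field-plus-landscape models are reachable), and ordination settings.
#'
#' @param seed Integer seed for the ordination stage.
#' @return List of settings consumed by [run_pipeline()].
#' @export
pipeline_settings <- function(seed = 1) {
  list(
    scaling = 1e-4,
    halflife_defaults = c(potassium_bicarbonate = 7),
    cor_threshold = 0.5,
    vif_threshold = 5,
    delta_threshold = 2,
    max_extra = 4,
    pools = list(
      phytoseiid_t = c("management", "cover_crop", "pct_vineyards",
                       "pct_total_snh", "aaptlc", "pollen_t"),
      tydeoid_t = c("management", "cover_crop", "pct_vineyards",
                    "pct_total_snh", "aaptlc", "vegetation_cover_summer"),
      eriophyoid_t = c("management", "cover_crop", "pct_vineyards",
                       "vegetation_cover_spring", "vegetation_cover_summer",
                       "phytoseiid_t"),
      pollen_t = c("management", "cover_crop", "pct_vineyards",
                   "pct_total_snh", "min_dist_woody",
                   "vegetation_cover_summer")
    ),
    dissimilarity = "bray",
    nmds_k = 2,
    nmds_restarts = 20,
    n_permutations = 999,
    include_na_pollen_in_total = TRUE,
    seed = seed
  )
}

#' Validate the tables of a study against the pipeline input schemas
#'
#' Checks column presence, value ranges and closed sets for every table of a
#' study (synthetic or mapped from a deposit). Schema violations are errors;
#' recoverable conditions (e.g. missing toxicology values in the reference
#' table) are warnings.
#'
#' @param study A `vm_study` or a list with the same table names.
#' @return Data frame with columns `level` ("error"/"warning"), `table`,
#'   `message`; zero rows when everything validates.
#' @export
validate_study <- function(study) {
  report <- data.frame(level = character(), table = character(),
                       message = character(), stringsAsFactors = FALSE)
  note <- function(level, table, message) {
    rbind(report, data.frame(level = level, table = table, message = message))
  }
  try_check <- function(table, expr) {
    tryCatch({ expr; report },
             error = function(e) note("error", table, conditionMessage(e)))
  }
  report <- try_check("spray", check_spray(study$spray))
  report <- try_check("products", check_products(study$products))
  report <- try_check("ingredients", check_ingredients(study$ingredients))
  report <- try_check("patches", check_patches(study$patches))
  report <- try_check("mite_samples", {
    check_columns(study$mite_samples,
                  c("vineyard_id", "date_index", "taxon", "count",
                    "leaf_area_cm2"), "mite counts")
    if (any(study$mite_samples$count < 0))
      stop("negative mite count", call. = FALSE)
    if (any(study$mite_samples$leaf_area_cm2 <= 0))
      stop("non-positive leaf area", call. = FALSE)
  })
  if (!is.null(study$pollen_samples)) report <- try_check("pollen_samples", {
    check_columns(study$pollen_samples,
                  c("vineyard_id", "date_index", "pollen_type", "grains",
                    "counted_fraction", "square_side_mm"), "pollen counts")
    if (any(study$pollen_samples$grains < 0))
      stop("negative grain count", call. = FALSE)
    cf <- study$pollen_samples$counted_fraction
    if (any(cf <= 0 | cf > 1))
      stop("counted_fraction outside (0, 1]", call. = FALSE)
  })
  report <- try_check("design", {
    check_columns(study$design,
                  c("vineyard_id", "circle_id", "management", "cover_crop"),
                  "design")
    bad <- setdiff(unique(study$design$management),
                   c("organic", "integrated"))
    if (length(bad)) stop(sprintf("unknown management: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    bad <- setdiff(unique(study$design$cover_crop),
                   c("species_poor", "species_rich", "spontaneous"))
    if (length(bad)) stop(sprintf("unknown cover_crop: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
  })
  if (is.data.frame(study$ingredients) &&
      all(c("ld50_contact_ug_per_bee", "half_life_days") %in%
          names(study$ingredients))) {
    miss <- is.na(study$ingredients$ld50_contact_ug_per_bee) |
      is.na(study$ingredients$half_life_days)
    if (any(miss)) {
      report <- note("warning", "ingredients",
                     sprintf("missing toxicology values for: %s",
                             paste(study$ingredients$name[miss],
                                   collapse = ", ")))
    }
  }
  report
}

#' Assemble the vineyard x date analysis table
#'
#' Joins the per-vineyard toxicity summary, merged mite densities, pollen
#' totals, landscape composition and design metadata into the modelling
#' table: one row per vineyard and sampling date, categorical `date`,
#' `management` and `cover_crop` (treatment contrasts, first level
#' alphabetical), and transformed response columns `*_t` on the
#' log10(y + 1) scale (which double as cross-response predictors).
#'
#' @param study A `vm_study`.
#' @param settings Pipeline settings from [pipeline_settings()].
#' @return Data frame with responses, transformed responses and predictors.
#' @export
assemble_analysis_table <- function(study, settings = pipeline_settings()) {
  tox <- toxicity_summary(study$spray, study$ingredients, study$products,
                          scaling = settings$scaling,
                          halflife_defaults = settings$halflife_defaults,
                          vineyard_ids = study$design$vineyard_id)
  dens <- merge_eriophyoid(mite_density(study$mite_samples))
  has_pollen <- !is.null(study$pollen_samples) &&
    nrow(study$pollen_samples) > 0
  comp <- landscape_composition(study$patches)
  tab <- merge(study$design, comp, by = "circle_id")
  tab <- merge(tab, tox[, c("vineyard_id", "aaptlc", "tpyri_rating",
                            "n_total")], by = "vineyard_id")
  names(tab)[names(tab) == "n_total"] <- "n_applications_total"
  tab <- merge(tab, dens, by = "vineyard_id")  # expands to vineyard x date
  if (has_pollen) {
    pol <- merge_pollen_types(pollen_density(study$pollen_samples))
    if (!settings$include_na_pollen_in_total && "NA" %in% names(pol)) {
      pol$total_per_cm2 <- pol$total_per_cm2 - pol[["NA"]]
    }
    tab <- merge(tab,
                 pol[, c("vineyard_id", "date_index", "total_per_cm2")],
                 by = c("vineyard_id", "date_index"))
    names(tab)[names(tab) == "total_per_cm2"] <- "pollen"
  }
  tab$date <- factor(tab$date_index)
  tab$management <- factor(tab$management,
                           levels = c("integrated", "organic"))
  tab$cover_crop <- factor(tab$cover_crop,
                           levels = c("species_poor", "species_rich",
                                      "spontaneous"))
  responses <- c("phytoseiid", "tydeoid", "eriophyoid",
                 if (has_pollen) "pollen")
  for (resp in responses) {
    tab[[paste0(resp, "_t")]] <- transform_response(tab[[resp]])
  }
  tab[order(tab$vineyard_id, tab$date_index), , drop = FALSE]
}

# Pairwise collinearity exclusions for a candidate pool; constant columns
# are dropped from the pool (they cannot be estimated).
screen_pool <- function(pool, data, settings) {
  scr <- collinearity_screen(data[, pool, drop = FALSE],
                             threshold = settings$cor_threshold)
  exclusions <- scr$pairs[scr$pairs$excluded, c("var1", "var2"), drop = FALSE]
  list(pool = setdiff(pool, scr$constant), exclusions = exclusions,
       constant = scr$constant, screen = scr)
}

# Keep only candidates whose within-model VIFs are all <= the threshold;
# pairwise exclusions already keep the strongly collinear pairs apart, so
# this second screen catches multi-term near-collinearity.
vif_filter <- function(candidates, data, threshold) {
  keep <- vapply(candidates, function(tm) {
    if (length(tm) < 2L) return(TRUE)
    v <- tryCatch(vif(data, terms = tm), error = function(e) Inf)
    all(v <= threshold)
  }, logical(1))
  dropped <- candidates[!keep]
  out <- candidates[keep]
  attr(out, "n_models") <- sum(vapply(out, length, 1L) > 0L)
  attr(out, "dropped") <- dropped
  out
}

#' Run the full analysis pipeline on a study
#'
#' Executes toxicity scoring, density normalisation, landscape metrics,
#' analysis-table assembly, collinearity/VIF screening, AICc model selection
#' per response, the Spearman correlation set (aAPTLc vs. the T. pyri
#' rating, aAPTLc vs. phytoseiid densities over vineyard-dates, rating vs.
#' phytoseiid densities) and seasonal NMDS ordinations of the pollen
#' community with trait fitting. All randomness flows from
#' `settings$seed`.
#'
#' @param study A `vm_study` (from [generate_study()] or mapped input data).
#' @param settings Pipeline settings from [pipeline_settings()].
#' @return List with `toxicity`, `analysis_table`, `screening`,
#'   `selection` (one `vm_selection` per response), `correlations`,
#'   `ordinations` (`spring`/`summer`, each with `nmds` and `traits`; NULL
#'   when pollen input is absent), and `log` (character vector of the
#'   decisions taken).
#' @export
run_pipeline <- function(study, settings = pipeline_settings()) {
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  report <- validate_study(study)
  if (any(report$level == "error")) {
    stop(paste0("input validation failed:\n",
                paste(sprintf("  [%s] %s: %s", report$level, report$table,
                              report$message), collapse = "\n")),
         call. = FALSE)
  }
  for (i in which(report$level == "warning")) {
    say("validation warning (%s): %s", report$table[i], report$message[i])
  }

  tox <- toxicity_summary(study$spray, study$ingredients, study$products,
                          scaling = settings$scaling,
                          halflife_defaults = settings$halflife_defaults,
                          vineyard_ids = study$design$vineyard_id)
  excl <- attr(tox, "excluded")
  if (nrow(excl)) {
    say("toxicology exclusions: %s",
        paste(sprintf("%s (%s)", excl$ingredient, excl$reason),
              collapse = "; "))
  }

  tab <- assemble_analysis_table(study, settings)

  has_pollen <- "pollen_t" %in% names(tab)
  pools <- settings$pools
  if (!has_pollen) {
    pools$pollen_t <- NULL
    pools <- lapply(pools, setdiff, y = "pollen_t")
    say("pollen input absent: pollen models and pollen predictors dropped")
  }

  screening <- list()
  selection <- list()
  for (resp in names(pools)) {
    pool <- pools[[resp]]
    scr <- screen_pool(pool, tab, settings)
    if (length(scr$constant)) {
      say("%s: constant predictor(s) dropped: %s", resp,
          paste(scr$constant, collapse = ", "))
    }
    if (nrow(scr$exclusions)) {
      say("%s: collinear pairs (|r| >= %g) kept apart: %s", resp,
          settings$cor_threshold,
          paste(sprintf("%s~%s", scr$exclusions$var1, scr$exclusions$var2),
                collapse = ", "))
    }
    cands <- enumerate_candidates(c("date", scr$pool),
                                  exclusions = scr$exclusions,
                                  force = "date",
                                  max_extra = settings$max_extra)
    cands <- vif_filter(cands, tab, settings$vif_threshold)
    if (length(attr(cands, "dropped"))) {
      say("%s: %d candidate(s) dropped for within-model VIF > %g", resp,
          length(attr(cands, "dropped")), settings$vif_threshold)
    }
    sel <- model_selection(resp, cands, tab,
                           delta_threshold = settings$delta_threshold)
    if (isTRUE(attr(sel, "tied_best"))) {
      say("%s: AICc tie at the top broken by parameter count then label", resp)
    }
    screening[[resp]] <- scr
    selection[[resp]] <- sel
  }

  correlations <- list(
    aaptlc_vs_rating = spearman_cor(tox$aaptlc, tox$tpyri_rating),
    aaptlc_vs_phytoseiid = spearman_cor(tab$aaptlc, tab$phytoseiid_t),
    rating_vs_phytoseiid = spearman_cor(tab$tpyri_rating, tab$phytoseiid_t)
  )

  ordinations <- NULL
  if (!is.null(study$pollen_samples) && nrow(study$pollen_samples) > 0) {
    ordinations <- tryCatch(
      seasonal_ordinations(study, tab, settings),
      error = function(e) {
        say("ordination stage skipped: %s", conditionMessage(e))
        NULL
      })
  } else {
    say("ordination stage skipped: no pollen input")
  }

  list(toxicity = tox, analysis_table = tab, screening = screening,
       selection = selection, correlations = correlations,
       ordinations = ordinations, log = log)
}

# Seasonal pollen community matrices + NMDS + trait fitting.
seasonal_ordinations <- function(study, tab, settings) {
  pol <- merge_pollen_types(pollen_density(study$pollen_samples))
  seasons <- split_season(pol)
  traits_base <- tab[!duplicated(tab$vineyard_id),
                     c("vineyard_id", "cover_crop",
                       "vegetation_cover_spring", "vegetation_cover_summer",
                       "shdi", "min_dist_woody", "pct_total_snh",
                       "pct_total_agriculture")]
  phyto_mean <- tapply(tab$phytoseiid, tab$vineyard_id, mean)
  out <- list()
  for (season in c("spring", "summer")) {
    rec <- seasons[[season]]
    type_cols <- setdiff(names(rec), c("vineyard_id", "date_index",
                                       "total_per_cm2", "NA"))
    mats <- stats::aggregate(rec[, type_cols, drop = FALSE],
                             by = list(vineyard_id = rec$vineyard_id),
                             FUN = mean)
    mat <- as.matrix(mats[, type_cols, drop = FALSE])
    rownames(mat) <- mats$vineyard_id
    mat <- mat[, colSums(mat) > 0, drop = FALSE]
    d <- bray_curtis(mat, method = settings$dissimilarity)
    ord <- nmds(d, k = settings$nmds_k, n_restarts = settings$nmds_restarts,
                seed = settings$seed)
    traits <- traits_base[match(rownames(mat), traits_base$vineyard_id), ]
    traits$phytoseiid <- unname(phyto_mean[rownames(mat)])
    fitted <- fit_traits(ord, traits[, -1, drop = FALSE],
                         n_permutations = settings$n_permutations,
                         seed = settings$seed)
    out[[season]] <- list(community = mat, nmds = ord, traits = fitted)
  }
  out
}

## Delimited-text round trip ---------------------------------------------------

study_table_names <- function() {
  c("design", "patches", "spray", "ingredients", "products",
    "mite_samples", "pollen_samples")
}

#' Write a study to a directory of CSV files
#'
#' UTF-8 comma-separated files, "." decimal, ISO dates; one file per table.
#'
#' @param study A `vm_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in study_table_names()) {
    utils::write.csv(study[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study from a directory of CSV files
#'
#' The thin adapter between deposited delimited tables and the pipeline
#' schemas: files must be named as written by [write_study()].
#'
#' @param dir Directory holding the CSV files.
#' @return A `vm_study` (without ground truth).
#' @export
read_study <- function(dir) {
  out <- lapply(study_table_names(), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) return(NULL)
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  })
  names(out) <- study_table_names()
  structure(out, class = "vm_study")
}
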