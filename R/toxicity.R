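#' @keywords internal
"_PACKAGE"

## Closed sets shared across the package -------------------------------------

#' Pesticide application categories
#'
#' The closed set of spray-record categories used throughout the package:
#' insecticide, acaricide, synthetic fungicide, sulfur, copper, potassium
#' bicarbonate and a catch-all "other".
#'
#' @return Character vector of category names.
#' @export
application_categories <- function() {
  c("insecticide", "acaricide", "synthetic_fungicide",
    "sulfur", "copper", "potassium_bicarbonate", "other")
}

#' Harm classes and their numeric scale for the T. pyri toxicity rating
#'
#' Laboratory side-effect classes for *Typhlodromus pyri*: harmless (<40%
#' decrease of beneficial capacity), slightly harmful (40--80%) and harmful
#' (>80%), scaled 0.4 / 0.8 / 1.0. Ingredients with class `unknown`
#' contribute nothing and are reported as excluded.
#'
#' @return Named numeric vector mapping harm class to its scale value.
#' @export
harm_class_scale <- function() {
  c(harmless = 0.4, slightly_harmful = 0.8, harmful = 1.0)
}

harm_classes <- function() c(names(harm_class_scale()), "unknown")

## Input checks ---------------------------------------------------------------

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table is missing column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_spray <- function(spray) {
  check_columns(spray, c("vineyard_id", "date", "product",
                         "dose_g_per_ha", "category"), "spray")
  if (nrow(spray) == 0L) return(invisible(spray))
  if (any(spray$dose_g_per_ha < 0, na.rm = TRUE)) {
    bad <- which(spray$dose_g_per_ha < 0)[1L]
    stop(sprintf("negative dose_g_per_ha in spray row %d", bad), call. = FALSE)
  }
  unknown <- setdiff(unique(spray$category), application_categories())
  if (length(unknown) > 0L) {
    stop(sprintf("unknown application category: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(spray)
}

check_products <- function(products) {
  check_columns(products, c("product", "ingredient", "concentration_pct"),
                "products")
  bad <- products$concentration_pct <= 0 | products$concentration_pct > 100
  if (any(bad, na.rm = TRUE)) {
    stop("product concentrations must lie in (0, 100]", call. = FALSE)
  }
  invisible(products)
}

check_ingredients <- function(ingredients) {
  check_columns(ingredients,
                c("name", "ld50_contact_ug_per_bee", "half_life_days",
                  "harm_class"), "ingredients")
  if (any(ingredients$ld50_contact_ug_per_bee <= 0, na.rm = TRUE))
    stop("ld50_contact_ug_per_bee must be positive when present", call. = FALSE)
  if (any(ingredients$half_life_days <= 0, na.rm = TRUE))
    stop("half_life_days must be positive when present", call. = FALSE)
  unknown <- setdiff(unique(ingredients$harm_class), harm_classes())
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown) > 0L) {
    stop(sprintf("unknown harm_class: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ingredients)
}

## Operations ------------------------------------------------------------------

#' Resolve spray records to active-ingredient amounts
#'
#' Each product application is expanded into its active ingredients; every
#' ingredient contributes `dose_g_per_ha * concentration_pct / 100` grams of
#' active ingredient per hectare. Both the per-application contributions and
#' the per-vineyard ingredient totals are returned, since the toxicity
#' loading sums over individual applications.
#'
#' @param spray Data frame with columns `vineyard_id`, `date`, `product`,
#'   `dose_g_per_ha`, `category`.
#' @param products Long-format product composition table with columns
#'   `product`, `ingredient`, `concentration_pct`.
#' @return List with elements `per_application` (one row per application x
#'   ingredient, column `amount_g_per_ha`) and `totals` (per vineyard x
#'   ingredient sums, column `total_g_per_ha`).
#' @examples
#' spray <- data.frame(vineyard_id = "v1", date = "2019-05-07",
#'                     product = "wettable_sulfur", dose_g_per_ha = 2000,
#'                     category = "sulfur")
#' prods <- data.frame(product = "wettable_sulfur", ingredient = "sulfur",
#'                     concentration_pct = 80)
#' active_ingredient_amounts(spray, prods)$totals
#' @export
active_ingredient_amounts <- function(spray, products) {
  check_spray(spray)
  check_products(products)
  empty <- data.frame(vineyard_id = character(), date = character(),
                      product = character(), category = character(),
                      ingredient = character(), amount_g_per_ha = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(spray) == 0L) {
    return(list(per_application = empty,
                totals = data.frame(vineyard_id = character(),
                                    ingredient = character(),
                                    total_g_per_ha = numeric())))
  }
  unresolved <- setdiff(unique(spray$product), unique(products$product))
  if (length(unresolved) > 0L) {
    stop(sprintf("product(s) not found in composition table: %s",
                 paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  per_app <- merge(spray, products, by = "product", sort = FALSE)
  per_app$amount_g_per_ha <-
    per_app$dose_g_per_ha * per_app$concentration_pct / 100
  per_app <- per_app[, c("vineyard_id", "date", "product", "category",
                         "ingredient", "amount_g_per_ha")]
  totals <- stats::aggregate(amount_g_per_ha ~ vineyard_id + ingredient,
                             data = per_app, FUN = sum)
  names(totals)[names(totals) == "amount_g_per_ha"] <- "total_g_per_ha"
  list(per_application = per_app, totals = totals)
}

# Join toxicology onto per-application ingredient amounts, applying
# half-life defaults for named ingredients (potassium bicarbonate's 7-day
# assumption ships as the default).
join_toxicology <- function(per_app, ingredients,
                            halflife_defaults = c(potassium_bicarbonate = 7)) {
  idx <- match(per_app$ingredient, ingredients$name)
  if (anyNA(idx)) {
    stop(sprintf("ingredient(s) absent from reference table: %s",
                 paste(unique(per_app$ingredient[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  per_app$ld50 <- ingredients$ld50_contact_ug_per_bee[idx]
  per_app$half_life <- ingredients$half_life_days[idx]
  per_app$harm_class <- ingredients$harm_class[idx]
  if (length(halflife_defaults) > 0L) {
    fill <- is.na(per_app$half_life) &
      per_app$ingredient %in% names(halflife_defaults)
    per_app$half_life[fill] <-
      halflife_defaults[per_app$ingredient[fill]]
  }
  per_app
}

#' Area-related acute pesticide contact toxicity loading (aAPTLc)
#'
#' For every application of every active ingredient the index accumulates
#' `amount (g/ha) / honeybee contact LD50 (ug/bee) x half-life (days) / ln 2`,
#' scaled by `scaling` (default 1e-4, purely for readable magnitudes; it has
#' no effect on any rank-based downstream result). Ingredients with a missing
#' LD50 or half-life are skipped and reported in the exclusion list, except
#' where `halflife_defaults` supplies a value (potassium bicarbonate is
#' assigned a 7-day half-life by default).
#'
#' @inheritParams active_ingredient_amounts
#' @param ingredients Reference table with columns `name`,
#'   `ld50_contact_ug_per_bee`, `half_life_days`, `harm_class` (`NA` = missing).
#' @param scaling Positive scaling factor applied to the sum.
#' @param halflife_defaults Named numeric vector of fallback half-lives (days)
#'   for ingredients whose reference value is missing.
#' @param vineyard_ids Optional vector of vineyard ids that must appear in the
#'   output even when they have no applications (score 0).
#' @return List with `scores` (data frame `vineyard_id`, `aaptlc`) and
#'   `excluded` (data frame `ingredient`, `reason`).
#' @export
aaptlc <- function(spray, ingredients, products, scaling = 1e-4,
                   halflife_defaults = c(potassium_bicarbonate = 7),
                   vineyard_ids = NULL) {
  stopifnot(is.numeric(scaling), length(scaling) == 1L, scaling > 0)
  check_ingredients(ingredients)
  amounts <- active_ingredient_amounts(spray, products)
  per_app <- amounts$per_application
  ids <- unique(c(as.character(spray$vineyard_id), as.character(vineyard_ids)))
  no_excl <- data.frame(ingredient = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (nrow(per_app) == 0L) {
    return(list(scores = data.frame(vineyard_id = ids,
                                    aaptlc = rep(0, length(ids))),
                excluded = no_excl))
  }
  per_app <- join_toxicology(per_app, ingredients, halflife_defaults)
  miss_ld50 <- is.na(per_app$ld50)
  miss_hl <- is.na(per_app$half_life)
  ld50_out <- unique(per_app$ingredient[miss_ld50])
  hl_out <- unique(per_app$ingredient[!miss_ld50 & miss_hl])
  excl <- data.frame(
    ingredient = c(ld50_out, hl_out),
    reason = c(rep("missing ld50_contact", length(ld50_out)),
               rep("missing half_life", length(hl_out))),
    stringsAsFactors = FALSE)
  keep <- !miss_ld50 & !miss_hl
  if (!any(keep)) {
    warning("all applied ingredients excluded for missing toxicology; ",
            "aAPTLc is 0 for every vineyard", call. = FALSE)
  }
  used <- per_app[keep, , drop = FALSE]
  contrib <- used$amount_g_per_ha / used$ld50 * used$half_life / log(2)
  per_v <- tapply(contrib, used$vineyard_id, sum)
  scores <- data.frame(vineyard_id = ids,
                       aaptlc = scaling * unname(ifelse(
                         is.na(per_v[ids]), 0, per_v[ids])))
  list(scores = scores, excluded = if (nrow(excl)) excl else no_excl)
}

#' Categorical toxicity rating for Typhlodromus pyri
#'
#' Every application of every active ingredient contributes the numeric scale
#' value of its harm class (harmless 0.4, slightly harmful 0.8, harmful 1.0);
#' the rating is the sum over all such occurrences per vineyard. Occurrences
#' of ingredients with harm class `unknown` (or missing) are excluded and
#' reported.
#'
#' @inheritParams aaptlc
#' @return List with `scores` (data frame `vineyard_id`, `tpyri_rating`) and
#'   `excluded` (data frame `ingredient`, `reason`).
#' @export
tpyri_rating <- function(spray, ingredients, products, vineyard_ids = NULL) {
  check_ingredients(ingredients)
  amounts <- active_ingredient_amounts(spray, products)
  per_app <- amounts$per_application
  ids <- unique(c(as.character(spray$vineyard_id), as.character(vineyard_ids)))
  no_excl <- data.frame(ingredient = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (nrow(per_app) == 0L) {
    return(list(scores = data.frame(vineyard_id = ids,
                                    tpyri_rating = rep(0, length(ids))),
                excluded = no_excl))
  }
  per_app <- join_toxicology(per_app, ingredients, halflife_defaults = NULL)
  scale <- harm_class_scale()
  known <- per_app$harm_class %in% names(scale)
  unk <- unique(per_app$ingredient[!known])
  excl <- data.frame(ingredient = unk,
                     reason = rep("unknown harm_class", length(unk)),
                     stringsAsFactors = FALSE)
  used <- per_app[known, , drop = FALSE]
  contrib <- unname(scale[used$harm_class])
  per_v <- tapply(contrib, used$vineyard_id, sum)
  scores <- data.frame(vineyard_id = ids,
                       tpyri_rating = unname(ifelse(
                         is.na(per_v[ids]), 0, per_v[ids])))
  list(scores = scores, excluded = if (nrow(excl)) excl else no_excl)
}

#' Count pesticide applications per vineyard
#'
#' The total counts distinct application dates (several products sprayed on
#' the same date form a single application, i.e. a tank mix); the per-category
#' counts count individual product applications in each category.
#'
#' @inheritParams aaptlc
#' @return Data frame with `vineyard_id`, `n_total` and one `n_<category>`
#'   column per application category.
#' @export
application_counts <- function(spray, vineyard_ids = NULL) {
  check_spray(spray)
  ids <- unique(c(as.character(spray$vineyard_id), as.character(vineyard_ids)))
  cats <- application_categories()
  out <- data.frame(vineyard_id = ids, n_total = 0L)
  for (cat in cats) out[[paste0("n_", cat)]] <- 0L
  if (nrow(spray) > 0L) {
    for (i in seq_along(ids)) {
      rows <- spray[spray$vineyard_id == ids[i], , drop = FALSE]
      out$n_total[i] <- length(unique(rows$date))
      tab <- table(factor(rows$category, levels = cats))
      for (cat in cats) out[[paste0("n_", cat)]][i] <- as.integer(tab[[cat]])
    }
  }
  out
}

#' Per-vineyard toxicity summary
#'
#' Convenience wrapper combining [aaptlc()], [tpyri_rating()] and
#' [application_counts()] into one table, with the union of exclusion
#' reports attached as the `"excluded"` attribute.
#'
#' @inheritParams aaptlc
#' @return Data frame with one row per vineyard: `aaptlc`, `tpyri_rating`,
#'   `n_total` and per-category application counts.
#' @export
toxicity_summary <- function(spray, ingredients, products, scaling = 1e-4,
                             halflife_defaults = c(potassium_bicarbonate = 7),
                             vineyard_ids = NULL) {
  a <- aaptlc(spray, ingredients, products, scaling, halflife_defaults,
              vineyard_ids)
  r <- tpyri_rating(spray, ingredients, products, vineyard_ids)
  n <- application_counts(spray, vineyard_ids)
  out <- merge(merge(a$scores, r$scores, by = "vineyard_id"), n,
               by = "vineyard_id")
  attr(out, "excluded") <- unique(rbind(a$excluded, r$excluded))
  out
}
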