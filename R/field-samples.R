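## Leaf-wash mite counts and sticky-tape pollen counts -> areal densities.

mite_taxa <- function() {
  c("phytoseiid", "tydeoid", "eriophyoid_colomerus",
    "eriophyoid_calepitrimerus", "spider_mite")
}

#' Mite densities per 100 cm2 vine leaf area
#'
#' Converts long-format leaf-wash counts (one row per vineyard x sampling
#' date x taxon, with the measured total leaf area of the washed sample) to
#' densities: `count / leaf_area_cm2 * 100`.
#'
#' @param counts Data frame with columns `vineyard_id`, `date_index`, `taxon`,
#'   `count`, `leaf_area_cm2`. Leaf area must be constant within a
#'   vineyard-date (one washed sample).
#' @return Wide data frame, one row per vineyard-date, one density column per
#'   taxon (individuals per 100 cm2).
#' @examples
#' x <- data.frame(vineyard_id = "v1", date_index = 1, taxon = "phytoseiid",
#'                 count = 50, leaf_area_cm2 = 2500)
#' mite_density(x)$phytoseiid  # 2 per 100 cm2
#' @export
mite_density <- function(counts) {
  check_columns(counts, c("vineyard_id", "date_index", "taxon", "count",
                          "leaf_area_cm2"), "mite counts")
  if (any(counts$leaf_area_cm2 <= 0)) {
    stop("leaf_area_cm2 must be positive", call. = FALSE)
  }
  if (any(counts$count < 0)) stop("counts must be non-negative", call. = FALSE)
  counts$density <- counts$count / counts$leaf_area_cm2 * 100
  wide <- stats::reshape(
    counts[, c("vineyard_id", "date_index", "taxon", "density")],
    idvar = c("vineyard_id", "date_index"), timevar = "taxon",
    direction = "wide")
  names(wide) <- sub("^density\\.", "", names(wide))
  wide[is.na(wide)] <- 0
  rownames(wide) <- NULL
  wide[order(wide$vineyard_id, wide$date_index), , drop = FALSE]
}

#' Merge the two eriophyoid species into one taxon
#'
#' Eriophyoid densities are very low in this system, so the two species
#' (*Colomerus vitis*, *Calepitrimerus vitis*) are pooled per vineyard-date
#' before modelling. Idempotent: records that already carry a merged
#' `eriophyoid` column are returned unchanged.
#'
#' @param records Wide density table from [mite_density()].
#' @return The table with a single `eriophyoid` column replacing the two
#'   species columns.
#' @export
merge_eriophyoid <- function(records) {
  species <- c("eriophyoid_colomerus", "eriophyoid_calepitrimerus")
  if (!any(species %in% names(records))) {
    if (!"eriophyoid" %in% names(records)) {
      stop("no eriophyoid columns present", call. = FALSE)
    }
    return(records)
  }
  present <- intersect(species, names(records))
  merged <- rowSums(records[, present, drop = FALSE])
  if ("eriophyoid" %in% names(records)) merged <- merged + records$eriophyoid
  records <- records[, setdiff(names(records), present), drop = FALSE]
  records$eriophyoid <- merged
  records
}

#' Relative species abundance (percent)
#'
#' @param tally Named non-negative counts (e.g. individuals per species).
#' @return Named percentages summing to 100.
#' @examples
#' round(relative_abundance(c(T_pyri = 6824, E_finlandicus = 45,
#'                            P_talbii = 43)), 2)
#' @export
relative_abundance <- function(tally) {
  if (length(tally) == 0L || sum(tally) <= 0) {
    stop("tally must contain at least one positive count", call. = FALSE)
  }
  if (any(tally < 0)) stop("counts must be non-negative", call. = FALSE)
  100 * tally / sum(tally)
}

#' Pollen density per square centimetre
#'
#' Grains counted on transects across a sticky-tape square are extrapolated
#' to grains per cm2: `grains / (counted_fraction * square_area_cm2)` with
#' `square_area_cm2 = (square_side_mm / 10)^2`. For the 19 mm protocol square
#' the area is 3.61 cm2.
#'
#' @param sample Data frame with columns `vineyard_id`, `date_index`,
#'   `pollen_type`, `grains`, `counted_fraction` (fraction of the square
#'   actually counted, in (0, 1]), `square_side_mm`.
#' @return Wide data frame, one row per vineyard-date, one grains/cm2 column
#'   per pollen type plus `total_per_cm2`.
#' @export
pollen_density <- function(sample) {
  check_columns(sample, c("vineyard_id", "date_index", "pollen_type",
                          "grains", "counted_fraction", "square_side_mm"),
                "pollen counts")
  if (any(sample$counted_fraction <= 0 | sample$counted_fraction > 1)) {
    stop("counted_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(sample$grains < 0)) stop("grains must be non-negative", call. = FALSE)
  area_cm2 <- (sample$square_side_mm / 10)^2
  sample$density <- sample$grains / (sample$counted_fraction * area_cm2)
  wide <- stats::reshape(
    sample[, c("vineyard_id", "date_index", "pollen_type", "density")],
    idvar = c("vineyard_id", "date_index"), timevar = "pollen_type",
    direction = "wide")
  names(wide) <- sub("^density\\.", "", names(wide))
  wide[is.na(wide)] <- 0
  rownames(wide) <- NULL
  type_cols <- setdiff(names(wide), c("vineyard_id", "date_index"))
  wide$total_per_cm2 <- rowSums(wide[, type_cols, drop = FALSE])
  wide[order(wide$vineyard_id, wide$date_index), , drop = FALSE]
}

#' Merge morphologically similar pollen types
#'
#' Applies source -> target merge rules (by default Caryophyllaceae into
#' Amaranthaceae and Moraceae into Urticaceae, the types that cannot be
#' separated reliably under the light microscope). The AP / NAP / NA
#' categories pass through unchanged and totals are conserved.
#'
#' @param record Wide pollen density table from [pollen_density()].
#' @param rules Named character vector: `names(rules)` are source columns,
#'   values are target columns. A source may appear only once.
#' @return The table with source columns summed into their targets.
#' @export
merge_pollen_types <- function(record,
                               rules = c(Caryophyllaceae = "Amaranthaceae",
                                         Moraceae = "Urticaceae")) {
  if (anyDuplicated(names(rules))) {
    stop("a pollen type is mapped by more than one merge rule", call. = FALSE)
  }
  for (src in names(rules)) {
    if (!src %in% names(record)) next
    tgt <- rules[[src]]
    if (!tgt %in% names(record)) record[[tgt]] <- 0
    record[[tgt]] <- record[[tgt]] + record[[src]]
    record[[src]] <- NULL
  }
  record
}
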