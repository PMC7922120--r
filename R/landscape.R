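## Habitat patches within 500-m landscape circles -> composition metrics.

#' Habitat classes
#'
#' The closed set of mapped habitat classes: 14 analyzed classes plus four
#' (artificial, ponds/rivers, roads, yards) that occupy circle area but are
#' kept out of the statistical analysis.
#'
#' @param analyzed_only If `TRUE`, return only the 14 analyzed classes.
#' @return Character vector of class names.
#' @export
habitat_classes <- function(analyzed_only = FALSE) {
  analyzed <- c("hedgerow", "solitary_trees", "tree_rows", "woodland",
                "fallow", "grassland", "grass_strip", "dry_grassland",
                "meadow_orchard", "scrub", "ruderal", "garden",
                "vineyard", "arable_crop")
  excluded <- c("artificial", "ponds_rivers", "roads", "yards")
  if (analyzed_only) analyzed else c(analyzed, excluded)
}

#' Habitat groupings behind the four composition percentages
#'
#' Woody semi-natural habitats (SNHs) are hedgerows, solitary trees, tree
#' rows and woodland; total SNHs add fallows, grasslands and grass strips;
#' total agriculture is vineyards plus arable crops.
#'
#' @return Named list of character vectors of habitat classes.
#' @export
habitat_groups <- function() {
  woody <- c("hedgerow", "solitary_trees", "tree_rows", "woodland")
  list(
    woody_snh = woody,
    total_snh = c(woody, "fallow", "grassland", "grass_strip"),
    vineyards = "vineyard",
    total_agriculture = c("vineyard", "arable_crop")
  )
}

check_patches <- function(patches) {
  check_columns(patches, c("patch_id", "circle_id", "habitat_class",
                           "area_m2"), "patches")
  if (any(patches$area_m2 <= 0)) {
    stop("patch areas must be positive", call. = FALSE)
  }
  unknown <- setdiff(unique(patches$habitat_class), habitat_classes())
  if (length(unknown) > 0L) {
    stop(sprintf("unknown habitat_class: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  invisible(patches)
}

#' Shannon landscape diversity index (SHDI)
#'
#' `-sum(p_c * log(p_c))` over habitat-class area shares within one circle,
#' in nats. Classes with zero area contribute nothing; a single-class
#' landscape has SHDI 0, and k equal classes give `log(k)`.
#'
#' @param areas Named numeric vector (or plain vector) of per-class areas, or
#'   a patch table for a single circle (columns `habitat_class`, `area_m2`).
#' @param analyzed_only If the input is a patch table, drop the four
#'   non-analyzed classes before computing shares.
#' @return SHDI in nats (>= 0).
#' @export
shdi <- function(areas, analyzed_only = FALSE) {
  if (is.data.frame(areas)) {
    if (analyzed_only) {
      areas <- areas[areas$habitat_class %in% habitat_classes(TRUE), ,
                     drop = FALSE]
    }
    areas <- tapply(areas$area_m2, areas$habitat_class, sum)
  }
  areas <- areas[!is.na(areas) & areas > 0]
  total <- sum(areas)
  if (total <= 0) stop("total area must be positive", call. = FALSE)
  p <- areas / total
  -sum(p * log(p))
}

#' Landscape composition of each circle
#'
#' Aggregates the habitat patches of each 500-m circle into the four
#' composition percentages (woody SNHs, total SNHs, vineyards, total
#' agriculture) plus SHDI. The percentage denominator is by default the full
#' mapped circle area including the four non-analyzed classes, which keeps
#' the percentages physically interpretable as shares of the circle;
#' `analyzed_only = TRUE` switches both the denominator and the SHDI to the
#' 14 analyzed classes.
#'
#' @param patches Patch table with columns `patch_id`, `circle_id`,
#'   `habitat_class`, `area_m2`.
#' @param analyzed_only Restrict denominator and SHDI to analyzed classes.
#' @return Data frame with one row per circle: `pct_woody_snh`,
#'   `pct_total_snh`, `pct_vineyards`, `pct_total_agriculture`, `shdi`,
#'   `total_area_m2`.
#' @export
landscape_composition <- function(patches, analyzed_only = FALSE) {
  check_patches(patches)
  groups <- habitat_groups()
  circles <- unique(patches$circle_id)
  out <- lapply(circles, function(cid) {
    p <- patches[patches$circle_id == cid, , drop = FALSE]
    denom_p <- if (analyzed_only) {
      p[p$habitat_class %in% habitat_classes(TRUE), , drop = FALSE]
    } else p
    denom <- sum(denom_p$area_m2)
    if (denom <= 0) stop(sprintf("circle %s has zero denominator area", cid),
                         call. = FALSE)
    pct <- vapply(groups, function(classes) {
      100 * sum(p$area_m2[p$habitat_class %in% classes]) / denom
    }, numeric(1))
    data.frame(circle_id = cid,
               pct_woody_snh = pct[["woody_snh"]],
               pct_total_snh = pct[["total_snh"]],
               pct_vineyards = pct[["vineyards"]],
               pct_total_agriculture = pct[["total_agriculture"]],
               shdi = shdi(p, analyzed_only = analyzed_only),
               total_area_m2 = sum(p$area_m2))
  })
  do.call(rbind, out)
}

## Minimal planar geometry (projected metric coordinates) ---------------------

# Distance between a point and a segment.
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

# Proper / touching intersection test for two segments via orientation signs.
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    orient(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, q1) || on_seg(p1, p2, q2) ||
    on_seg(q1, q2, p1) || on_seg(q1, q2, p2)
}

segment_segment_distance <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(point_segment_distance(p1, q1, q2),
      point_segment_distance(p2, q1, q2),
      point_segment_distance(q1, p1, p2),
      point_segment_distance(q2, p1, p2))
}

# Ray-casting point-in-polygon (boundary counts as inside).
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (point_segment_distance(p, c(xi, yi), c(xj, yj)) == 0) return(TRUE)
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- (xj - xi) * (p[2] - yi) / (yj - yi) + xi
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

polygon_edges <- function(poly) {
  n <- nrow(poly)
  lapply(seq_len(n), function(i) {
    list(a = poly[i, ], b = poly[if (i == n) 1L else i + 1L, ])
  })
}

#' Minimum edge-to-edge distance between two polygons
#'
#' Polygons are closed rings given as two-column coordinate matrices in a
#' shared projected metric system (metres); the last vertex need not repeat
#' the first. Overlapping or touching polygons have distance 0.
#'
#' @param poly_a,poly_b Two-column numeric matrices of ring vertices.
#' @return Distance in the coordinate units (m).
#' @export
polygon_distance <- function(poly_a, poly_b) {
  poly_a <- as.matrix(poly_a); poly_b <- as.matrix(poly_b)
  if (point_in_polygon(poly_a[1, ], poly_b) ||
      point_in_polygon(poly_b[1, ], poly_a)) return(0)
  best <- Inf
  for (ea in polygon_edges(poly_a)) {
    for (eb in polygon_edges(poly_b)) {
      d <- segment_segment_distance(ea$a, ea$b, eb$a, eb$b)
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

#' Minimum distance from a vineyard to the nearest woody SNH
#'
#' @param vineyard Polygon (two-column coordinate matrix) of the focal
#'   vineyard in projected metric coordinates.
#' @param woody_patches List of polygons of the woody SNH patches within the
#'   vineyard's circle. May be empty, in which case the distance is `NA`
#'   with a warning (absence of woody habitat is not distance 0).
#' @return Minimum edge-to-edge distance in metres, 0 when adjacent.
#' @export
min_distance_to_woody <- function(vineyard, woody_patches) {
  if (length(woody_patches) == 0L) {
    warning("no woody SNH patch in circle; distance is NA", call. = FALSE)
    return(NA_real_)
  }
  min(vapply(woody_patches, function(w) polygon_distance(vineyard, w),
             numeric(1)))
}

#' Read patch polygons from a GeoJSON FeatureCollection
#'
#' Features must carry a `patch_id` property and Polygon geometry in a
#' projected metric coordinate system; the outer ring is used.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of two-column coordinate matrices keyed by `patch_id`.
#' @export
read_patch_geometry <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  out <- list()
  for (f in gj$features) {
    id <- f$properties$patch_id
    if (is.null(id)) stop("feature without patch_id property", call. = FALSE)
    if (!identical(f$geometry$type, "Polygon")) {
      stop(sprintf("patch %s: only Polygon geometry is supported", id),
           call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    # drop the repeated closing vertex if present
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    out[[as.character(id)]] <- m
  }
  out
}
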