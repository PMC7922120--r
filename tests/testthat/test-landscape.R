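patches_df <- function(classes, areas, circle = "c1") {
  data.frame(patch_id = paste0("p", seq_along(classes)), circle_id = circle,
             habitat_class = classes, area_m2 = areas,
             stringsAsFactors = FALSE)
}

test_that("composition percentages aggregate the habitat groupings", {
  all_vine <- landscape_composition(patches_df("vineyard", 1e5))
  expect_equal(all_vine$pct_vineyards, 100)
  expect_equal(all_vine$pct_total_agriculture, 100)
  expect_equal(all_vine$pct_total_snh, 0)

  mix <- landscape_composition(
    patches_df(c("woodland", "vineyard", "fallow"), c(20000, 60000, 20000)))
  expect_equal(mix$pct_woody_snh, 20)
  expect_equal(mix$pct_total_snh, 40)
  expect_equal(mix$pct_vineyards, 60)
  expect_equal(mix$pct_total_agriculture, 60)

  expect_error(landscape_composition(patches_df("moonbase", 10)), "moonbase")

  # percentages bounded by 100 and nested groupings ordered
  set.seed(11)
  cls <- sample(habitat_classes(), 10, replace = TRUE)
  comp <- landscape_composition(patches_df(cls, runif(10, 1, 100)))
  pcts <- unlist(comp[, c("pct_woody_snh", "pct_total_snh", "pct_vineyards",
                          "pct_total_agriculture")])
  expect_true(all(pcts >= 0 & pcts <= 100))
  expect_lte(comp$pct_woody_snh, comp$pct_total_snh)
  expect_lte(comp$pct_vineyards, comp$pct_total_agriculture)
})

test_that("SHDI matches entropy identities and is merge-invariant", {
  expect_equal(shdi(c(vineyard = 100)), 0)
  expect_equal(shdi(rep(25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shdi(c(0.5, 0.3, 0.2)),
               -sum(c(0.5, 0.3, 0.2) * log(c(0.5, 0.3, 0.2))),
               tolerance = 1e-12)

  # permutation and split invariance
  a <- c(woodland = 30, vineyard = 50, fallow = 20)
  expect_equal(shdi(a), shdi(rev(a)))
  split_patches <- patches_df(c("woodland", "woodland", "vineyard", "fallow"),
                              c(10, 20, 50, 20))
  expect_equal(shdi(split_patches), shdi(a), tolerance = 1e-12)

  # zero-area classes contribute nothing
  expect_equal(shdi(c(a, roads = 0)), shdi(a))
})

test_that("analyzed-only flag switches denominator and SHDI support", {
  p <- patches_df(c("vineyard", "roads"), c(75, 25))
  full <- landscape_composition(p)
  only <- landscape_composition(p, analyzed_only = TRUE)
  expect_equal(full$pct_vineyards, 75)
  expect_equal(only$pct_vineyards, 100)
  expect_gt(full$shdi, 0)
  expect_equal(only$shdi, 0)
})

square <- function(x0, y0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

test_that("polygon distances are edge-to-edge with 0 for contact", {
  # 10 m gap between nearest edges of two unit squares
  expect_equal(polygon_distance(square(0, 0), square(11, 0)), 10)
  # touching edges
  expect_equal(polygon_distance(square(0, 0), square(1, 0)), 0)
  # overlap / containment
  expect_equal(polygon_distance(square(0, 0, 4), square(1, 1)), 0)
  # diagonal offset: nearest corners are sqrt(2) * 2 apart
  expect_equal(polygon_distance(square(0, 0), square(3, 3)),
               sqrt(8), tolerance = 1e-12)
})

test_that("distances are symmetric and satisfy the triangle inequality", {
  set.seed(3)
  polys <- lapply(1:3, function(i) square(runif(1, 0, 50), runif(1, 0, 50)))
  d12 <- polygon_distance(polys[[1]], polys[[2]])
  d21 <- polygon_distance(polys[[2]], polys[[1]])
  d13 <- polygon_distance(polys[[1]], polys[[3]])
  d23 <- polygon_distance(polys[[2]], polys[[3]])
  expect_equal(d12, d21)
  # triangle inequality with slack for polygon extent (unit squares)
  expect_lte(d13, d12 + d23 + 2 * sqrt(2))
})

test_that("minimum distance to woody SNHs handles adjacency and absence", {
  vine <- square(0, 0, 2)
  hedge <- square(2, 0)        # shares an edge
  wood <- square(10, 0, 3)
  expect_equal(min_distance_to_woody(vine, list(hedge, wood)), 0)
  expect_equal(min_distance_to_woody(vine, list(wood)), 8)
  expect_warning(d <- min_distance_to_woody(vine, list()), "NA")
  expect_true(is.na(d))
})

test_that("GeoJSON patch geometries round-trip through the reader", {
  ring <- function(m) {
    m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) list(m[i, 1], m[i, 2]))
  }
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(patch_id = "a"),
         geometry = list(type = "Polygon",
                         coordinates = list(ring(square(0, 0))))),
    list(type = "Feature", properties = list(patch_id = "b"),
         geometry = list(type = "Polygon",
                         coordinates = list(ring(square(11, 0)))))
  ))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  polys <- read_patch_geometry(path)
  expect_named(polys, c("a", "b"))
  expect_equal(polygon_distance(polys$a, polys$b), 10)
})
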