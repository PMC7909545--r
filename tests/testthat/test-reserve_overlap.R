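test_that("coverage handles full, half and outside polygons exactly", {
  g <- toy_grid()
  whole <- make_polyset(rect_poly(-1, -1, 21, 21))
  expect_equal(cell_coverage(g, 0:3, whole)$fraction, rep(1, 4),
               tolerance = 1e-9)
  half <- make_polyset(rect_poly(0, 0, 5, 10))
  expect_equal(cell_coverage(g, 0:1, half)$fraction, c(0.5, 0),
               tolerance = 1e-9)
})

test_that("union semantics: stacked and overlapping polygons never double count", {
  g <- toy_grid()
  two_same <- make_polyset(rect_poly(0, 0, 5, 10), rect_poly(0, 0, 5, 10))
  expect_equal(cell_coverage(g, 0L, two_same)$fraction, 0.5,
               tolerance = 1e-9)
  overlapping <- make_polyset(rect_poly(0, 0, 6, 10), rect_poly(4, 0, 8, 10))
  expect_equal(cell_coverage(g, 0L, overlapping)$fraction, 0.8,
               tolerance = 1e-9)
})

test_that("holes subtract and triangles clip exactly", {
  g <- toy_grid()
  donut <- phyloendemix:::new_polygon_set(
    list(list(rect_poly(1, 1, 9, 9)[[1]], rect_poly(3, 3, 7, 7)[[1]])), "d")
  expect_equal(cell_coverage(g, 0L, donut)$fraction, 0.48, tolerance = 1e-9)
  tri <- make_polyset(list(rbind(c(0, 0), c(10, 0), c(0, 10))))
  expect_equal(cell_coverage(g, 0L, tri)$fraction, 0.5, tolerance = 1e-9)
})

test_that("coverage is additive under polygon partition", {
  g <- toy_grid()
  whole <- make_polyset(rect_poly(2, 1, 9, 8))
  parts <- make_polyset(rect_poly(2, 1, 5.5, 8), rect_poly(5.5, 1, 9, 8))
  a <- cell_coverage(g, 0:3, whole)$fraction
  b <- cell_coverage(g, 0:3, parts)$fraction
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("gap arithmetic matches the worked example", {
  cov <- tibble::tibble(cell = 0:3, fraction = c(0, 0.05, 0.10, 0.5))
  rep <- conservation_gaps(0:3, cov, threshold = 0.10)
  expect_setequal(rep$gaps, 0:1)
  expect_equal(rep$overlap_pct, 50)
  # threshold 0: only exactly-zero cells are gaps
  rep0 <- conservation_gaps(0:3, cov, threshold = 1e-12)
  expect_identical(rep0$gaps, 0L)
  # empty set: overlap reported as NA
  rep_empty <- conservation_gaps(integer(), cov)
  expect_true(is.na(rep_empty$overlap_pct))
})

test_that("raising the threshold never shrinks the gap set", {
  for (seed in 1:10) {
    cov <- withr::with_seed(seed,
      tibble::tibble(cell = 0:49, fraction = runif(50)))
    ths <- sort(withr::with_seed(seed + 1, runif(4)))
    gaps <- lapply(ths, function(t)
      conservation_gaps(0:49, cov, threshold = t)$gaps)
    for (i in seq_along(gaps)[-1])
      expect_true(all(gaps[[i - 1]] %in% gaps[[i]]))
  }
})

test_that("simulated protected areas hit their coverage target", {
  g <- grid_spec(0, 0, 10, 10, 10)
  targets <- 0:49
  sim <- simulate_protected_areas(g, targets, coverage_fraction = 0.8,
                                  decoy_count = 3, seed = 5)
  cov <- cell_coverage(g, targets, sim$polygons)
  rep <- conservation_gaps(targets, cov, threshold = 0.10)
  expect_equal(rep$overlap_pct, 80)
  expect_setequal(rep$covered, sim$ledger$cell[sim$ledger$intended_covered])
  # boundary cases
  expect_equal(conservation_gaps(
    targets, cell_coverage(g, targets,
      simulate_protected_areas(g, targets, 1, 0, seed = 2)$polygons))$gaps,
    integer())
  all_gap <- conservation_gaps(
    targets, cell_coverage(g, targets,
      simulate_protected_areas(g, targets, 0, 0, seed = 2)$polygons))
  expect_setequal(all_gap$gaps, targets)
  expect_error(simulate_protected_areas(g, targets, 1.4, seed = 1), "0, 1")
})

test_that("GeoJSON polygons round-trip and marine polygons filter out", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sac.geojson")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(label = "land", marine = FALSE),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(0, 0), c(4, 0), c(4, 4),
                                                 c(0, 4), c(0, 0))))),
    list(type = "Feature", properties = list(label = "sea", marine = TRUE),
         geometry = list(type = "MultiPolygon",
                         coordinates = list(list(list(c(5, 5), c(6, 5),
                                                      c(6, 6), c(5, 6),
                                                      c(5, 5)))))))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  ps <- read_polygons_geojson(path)
  expect_identical(length(ps$polygons), 2L)
  expect_identical(ps$labels, c("land", "sea"))
  land <- filter_marine(ps)
  expect_identical(land$labels, "land")
  # write back and re-read
  out <- file.path(dir, "back.geojson")
  write_polygons_geojson(land, out)
  again <- read_polygons_geojson(out)
  expect_equal(again$polygons[[1]][[1]], land$polygons[[1]][[1]])
})
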