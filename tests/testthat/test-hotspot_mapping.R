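test_that("percentile sets count the expected cells on distinct values", {
  vals <- tibble::tibble(cell = 0:999, v = sample(1:1000))
  l3 <- percentile_cells(vals, "L3", "high")
  expect_identical(length(l3$cells), 100L)
  expect_setequal(vals$cell[vals$v >= 901], l3$cells)
  l1lo <- percentile_cells(vals, "L1", "low")
  expect_setequal(vals$cell[vals$v <= 10], l1lo$cells)
})

test_that("ties at the threshold are all included", {
  # 100 cells; 20 tied at the L2 threshold value
  v <- c(rep(10, 20), seq_len(80))
  vals <- tibble::tibble(cell = seq_along(v) - 1L, v = v)
  l2 <- percentile_cells(vals, "L2", "high")
  # k = 5; the 5th highest is 76 -> members are 76..80 exactly (no ties)
  expect_identical(length(l2$cells), 5L)
  v2 <- c(rep(80, 20), seq_len(80))
  l2b <- percentile_cells(tibble::tibble(cell = seq_along(v2) - 1L, v = v2),
                          "L2", "high")
  expect_identical(length(l2b$cells), 21L)   # all 20 ties + the 80
  expect_gt(length(l2b$cells) / 100, 0.05)
})

test_that("hotspot sets are nested L1 within L2 within L3 on any input", {
  for (seed in 1:5) {
    vals <- withr::with_seed(seed,
      tibble::tibble(cell = 0:199, v = rnorm(200)))
    for (tl in c("high", "low")) {
      s1 <- percentile_cells(vals, "L1", tl)$cells
      s2 <- percentile_cells(vals, "L2", tl)$cells
      s3 <- percentile_cells(vals, "L3", tl)$cells
      expect_true(all(s1 %in% s2))
      expect_true(all(s2 %in% s3))
    }
  }
})

test_that("degenerate all-equal input includes every cell with a message", {
  vals <- tibble::tibble(cell = 0:9, v = rep(2, 10))
  expect_message(s <- percentile_cells(vals, "L1", "high"), "degenerate")
  expect_identical(length(s$cells), 10L)
})

test_that("priority hotspots are the intersection of both top sets", {
  cwe <- tibble::tibble(cell = 0:99, v = c(100:1))
  pe <- tibble::tibble(cell = 0:99, v = c(50:1, 51:100))
  pr <- priority_hotspots(cwe, pe, "L3")
  expect_setequal(pr$cells,
                  intersect(percentile_cells(cwe, "L3", "high")$cells,
                            percentile_cells(pe, "L3", "high")$cells))
  expect_true(all(pr$cells %in% pr$components$CWE_END$cells))
  expect_true(all(pr$cells %in% pr$components$PE$cells))
  # top-1%-of-both membership
  cwe2 <- tibble::tibble(cell = 0:99, v = 1:100)
  pe2 <- tibble::tibble(cell = 0:99, v = 1:100)
  expect_identical(priority_hotspots(cwe2, pe2, "L1")$cells, 99L)
  expect_error(priority_hotspots(cwe, tibble::tibble(cell = 200:210,
                                                     v = 1:11), "L1"),
               "share no cells")
})

test_that("independent metrics give an L3 intersection near the product rate", {
  hits <- withr::with_seed(21, vapply(1:40, function(i) {
    cwe <- tibble::tibble(cell = 0:999, v = runif(1000))
    pe <- tibble::tibble(cell = 0:999, v = runif(1000))
    length(priority_hotspots(cwe, pe, "L3")$cells)
  }, numeric(1)))
  expect_gt(mean(hits), 5)     # expected 10 under independence
  expect_lt(mean(hits), 15)
})

test_that("climate stability follows the inverse-deviation law and finds refugia", {
  n <- 40
  ages <- c(4, 2, 1, 0)                      # Myr before present
  base <- tibble::tibble(cell = 0:(n - 1))
  withr::with_seed(6, {
    temp <- base; prec <- base
    for (k in 1:4) {
      temp[[paste0("t", k)]] <- rnorm(n, 20, 2)
      prec[[paste0("p", k)]] <- rnorm(n, 800, 60)
    }
  })
  # plant a constant-in-time patch: cells 0..3
  for (k in 1:4) {
    temp[1:4, paste0("t", k)] <- 15
    prec[1:4, paste0("p", k)] <- 700
  }
  out <- suppressMessages(climate_stability(temp, prec, ages))
  expect_true(all(out$stability$stability > 0 & out$stability$stability <= 1))
  expect_equal(out$stability$stability[1:4], rep(1, 4))  # capped, most stable
  expect_true(all(0:3 %in% out$refugia$cells))
  expect_identical(out$refugia$level, "L3")

  # deviations d and 2d give stabilities in ratio 2:1 before rescale
  t2 <- tibble::tibble(cell = 0:1, a = c(0, 0), b = c(1, 2))
  s2 <- phyloendemix:::slice_stability(t2, c(1, 0))
  expect_equal(s2$stability[1] / s2$stability[2], 2)

  # scaling a variable's units leaves the rescaled index unchanged
  tempc <- temp; tempc[-1] <- lapply(tempc[-1], function(z) z * 3.6)
  outc <- suppressMessages(climate_stability(tempc, prec, ages))
  expect_equal(outc$stability$stability, out$stability$stability,
               tolerance = 1e-12)

  expect_error(suppressMessages(climate_stability(
    tibble::tibble(cell = 0:1, a = c(1, 1), b = c(1, 1)),
    tibble::tibble(cell = 0:1, a = c(1, 1), b = c(1, 1)), c(1, 0))),
    "zero deviation")
})
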