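test_that("richness and weighted endemism match hand arithmetic", {
  m <- toy_matrix()                       # A in {0,1}, B in {1}, B endemic
  expect_identical(richness(m)$richness, c(1, 2))
  expect_identical(richness(m, endemic_only = TRUE)$richness, c(0, 1))
  expect_equal(weighted_endemism(m)$WE, c(0.5, 1.5))  # 1/2; 1/2 + 1
  # all-endemic matrix: ER = SR
  m2 <- random_matrix(8, 5, 1)
  expect_identical(richness(m2)$richness,
                   richness(m2, endemic_only = TRUE)$richness)
})

test_that("CWE is WE over richness, bounded by 1, with closed forms", {
  m <- toy_matrix()
  cwe <- corrected_weighted_endemism(weighted_endemism(m), richness(m))
  expect_equal(cwe$CWE, c(0.5, 0.75))
  # every taxon single-cell -> CWE = 1 exactly
  g <- toy_grid()
  m1 <- build_matrix(tibble::tibble(taxon = c("A", "B"), cell = 0:1,
                                    endemic = TRUE), g)
  expect_equal(
    corrected_weighted_endemism(weighted_endemism(m1), richness(m1))$CWE,
    c(1, 1))
  # all taxa of a cell with common range R -> CWE = 1/R
  m3 <- build_matrix(tibble::tibble(taxon = rep(c("A", "B"), each = 3),
                                    cell = rep(0:2, 2), endemic = TRUE),
                     grid_spec(0, 0, 1, 3, 1))
  cwe3 <- corrected_weighted_endemism(weighted_endemism(m3), richness(m3))
  expect_equal(cwe3$CWE, rep(1 / 3, 3))
  for (seed in 1:5) {
    mm <- random_matrix(10, 6, seed)
    cc <- corrected_weighted_endemism(weighted_endemism(mm), richness(mm))
    expect_true(all(cc$CWE > 0 & cc$CWE <= 1))
    expect_true(all(weighted_endemism(mm)$WE <= richness(mm)$richness))
  }
})

test_that("branch incidence marks a branch wherever any descendant tip occurs", {
  g <- toy_grid()
  m <- build_matrix(tibble::tibble(taxon = c("A", "B"), cell = 0:1,
                                   endemic = TRUE), g)
  tr <- ape::read.tree(text = "(A:1,B:1):1;")
  inc <- branch_incidence(tr, m)
  expect_identical(inc$range, c(1, 1))    # two pendants, one cell each
  # taxon present everywhere -> pendant range = number of cells
  m2 <- build_matrix(tibble::tibble(taxon = rep(c("A", "B"), c(4, 1)),
                                    cell = c(0:3, 0L), endemic = TRUE),
                     grid_spec(0, 0, 1, 4, 1))
  tr2 <- ape::read.tree(text = "(A:1,B:2);")
  inc2 <- branch_incidence(tr2, m2)
  expect_identical(inc2$range[inc2$tree$edge[, 2] ==
                                match("A", inc2$tree$tip.label)], 4)
  expect_error(branch_incidence(ape::read.tree(text = "(X:1,Y:1);"), m),
               "missing from tree")
})

test_that("PE matches brute force and satisfies the conservation identity", {
  for (seed in 1:10) {
    n_tips <- sample(4:20, 1)
    m <- random_matrix(sample(5:25, 1), n_tips, seed)
    tr <- random_tree(n_tips, seed + 100)
    inc <- branch_incidence(tr, m)
    pe <- phylogenetic_endemism(inc)
    expect_equal(pe$PE, brute_force_pe(tr, m)$PE, tolerance = 1e-12)
    expect_equal(sum(pe$PE), sum(tr$edge.length), tolerance = 1e-9)
    expect_equal(sum(weighted_endemism(m)$WE), n_tips, tolerance = 1e-9)
  }
})

test_that("star tree with disjoint single-cell taxa gives symmetric PE", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1);")
  m <- build_matrix(tibble::tibble(taxon = c("A", "B", "C"), cell = 0:2,
                                   endemic = TRUE),
                    grid_spec(0, 0, 1, 3, 1))
  pe <- phylogenetic_endemism(branch_incidence(tr, m))
  expect_equal(pe$PE, rep(1, 3))
})

test_that("comparison tree equalizes branch lengths preserving the total", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,C:1);")
  ct <- make_comparison_tree(tr)
  expect_equal(ct$edge.length, rep(7 / 4, 4))
  expect_equal(sum(ct$edge.length), sum(tr$edge.length), tolerance = 1e-12)
  # fixed point: already-equal tree unchanged
  expect_equal(make_comparison_tree(ct)$edge.length, ct$edge.length)
  tr0 <- tr; tr0$edge.length <- rep(0, 4)
  expect_error(make_comparison_tree(tr0), "zero total")
})

test_that("RPE is 1 on equal-length trees and scale-invariant", {
  tr <- random_tree(8, 5)
  tr$edge.length <- rep(2, length(tr$edge.length))
  m <- random_matrix(10, 8, 6)
  pe <- phylogenetic_endemism(branch_incidence(tr, m))
  pa <- phylogenetic_endemism(branch_incidence(make_comparison_tree(tr), m))
  expect_equal(relative_phylogenetic_endemism(pe, pa)$RPE, rep(1, 10))

  tr2 <- random_tree(8, 7)
  m2 <- random_matrix(10, 8, 8)
  rpe1 <- relative_phylogenetic_endemism(
    phylogenetic_endemism(branch_incidence(tr2, m2)),
    phylogenetic_endemism(branch_incidence(make_comparison_tree(tr2), m2)))
  tr3 <- tr2; tr3$edge.length <- tr3$edge.length * 7.3
  rpe2 <- relative_phylogenetic_endemism(
    phylogenetic_endemism(branch_incidence(tr3, m2)),
    phylogenetic_endemism(branch_incidence(make_comparison_tree(tr3), m2)))
  expect_equal(rpe1$RPE, rpe2$RPE, tolerance = 1e-12)
})

test_that("a cell dominated by one long restricted branch has RPE above 1", {
  # 4 tips; D has a very long pendant and occurs alone in cell 3
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:10):1);")
  m <- build_matrix(tibble::tibble(taxon = c("A", "B", "C", "D"),
                                   cell = 0:3, endemic = TRUE),
                    grid_spec(0, 0, 1, 4, 1))
  rpe <- relative_phylogenetic_endemism(
    phylogenetic_endemism(branch_incidence(tr, m)),
    phylogenetic_endemism(branch_incidence(make_comparison_tree(tr), m)))
  expect_gt(rpe$RPE[4], 1)
  expect_lt(rpe$RPE[1], 1)
})

test_that("adding a single-cell taxon strictly increases that cell's WE and PE", {
  for (seed in 1:5) {
    m <- random_matrix(8, 6, seed)
    tr <- random_tree(7, seed)
    we0 <- weighted_endemism(m)$WE[3]
    pe0 <- phylogenetic_endemism(branch_incidence(
      ape::drop.tip(tr, "t07"), m))$PE[3]
    rec <- tidy(m)
    rec <- dplyr::bind_rows(rec, tibble::tibble(cell = m$cell_id[3],
                                                taxon = "t07",
                                                endemic = TRUE))
    m1 <- build_matrix(rec, m$grid)
    we1 <- weighted_endemism(m1)$WE[m1$cell_id == m$cell_id[3]]
    pe1 <- phylogenetic_endemism(branch_incidence(tr, m1))$PE[
      m1$cell_id == m$cell_id[3]]
    expect_gt(we1, we0)
    expect_gt(pe1, pe0)
  }
})

test_that("cell_metrics assembles the full table with endemic-only PE", {
  sc <- synthetic_scenario(n_rows = 8, n_cols = 8, n_taxa = 40, seed = 3,
                           n_paleo_taxa = 3, neo_clade_size = 4)
  com <- suppressMessages(simulate_grid_community(sc))
  tre <- simulate_endemism_tree(sc, com)
  met <- suppressMessages(cell_metrics(com$matrix, tre$tree))
  expect_true(all(c("SR", "ER", "WE", "CWE_NAT", "WE_END", "CWE_END",
                    "PE_obs", "PE_alt", "RPE") %in% names(met)))
  expect_true(all(met$ER <= met$SR))
  has_end <- !is.na(met$CWE_END) & met$ER > 0
  expect_true(all(met$CWE_END[has_end] > 0 & met$CWE_END[has_end] <= 1))
  expect_true(all(met$PE_obs[!is.na(met$PE_obs)] > 0))
})
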