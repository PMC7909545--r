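# small in-code fixtures shared across test files

toy_grid <- function(size = 10, nr = 2, nc = 2)
  grid_spec(0, 0, size, nr, nc)

# 2-cell community: A in {0,1}, B in {1}, B endemic
toy_matrix <- function() {
  build_matrix(tibble::tibble(taxon = c("A", "A", "B"),
                              cell = c(0L, 1L, 1L),
                              endemic = c(FALSE, FALSE, TRUE)),
               toy_grid())
}

# random community matrix on a small grid (all taxa endemic by default)
random_matrix <- function(n_cells, n_taxa, seed, p = 0.3,
                          endemic = rep(TRUE, n_taxa)) {
  withr::with_seed(seed, {
    repeat {
      pres <- matrix(rbinom(n_cells * n_taxa, 1, p), n_cells, n_taxa)
      if (all(colSums(pres) > 0) && all(rowSums(pres) > 0)) break
    }
    recs <- tibble::tibble(
      taxon = sprintf("t%02d", rep(seq_len(n_taxa), each = n_cells)),
      cell = rep(seq_len(n_cells) - 1L, n_taxa),
      endemic = rep(endemic, each = n_cells))[as.logical(pres), ]
    build_matrix(recs, grid_spec(0, 0, 1, n_cells, 1))
  })
}

random_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips)
    tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
    tr
  })
}

# independent brute-force PE: enumerate each branch's descendant tips by
# walking the edge list recursively, count branch ranges by scanning cells
brute_force_pe <- function(tree, matrix) {
  tips_below <- function(node) {
    if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  branch_tips <- lapply(tree$edge[, 2], tips_below)
  pres <- matrix$presence[, tree$tip.label, drop = FALSE]
  in_cell <- function(cell_row, tips) any(pres[cell_row, tips] == 1L)
  r_b <- vapply(branch_tips, function(tps)
    sum(vapply(seq_len(nrow(pres)), in_cell, logical(1), tips = tps)),
    numeric(1))
  pe <- vapply(seq_len(nrow(pres)), function(i) {
    present <- vapply(branch_tips, in_cell, logical(1), cell_row = i)
    sum(tree$edge.length[present] / r_b[present])
  }, numeric(1))
  tibble::tibble(cell = matrix$cell_id, PE = pe)
}

# rectangle polygon helper
rect_poly <- function(x0, y0, x1, y1)
  list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))

make_polyset <- function(..., labels = NULL) {
  polys <- list(...)
  phyloendemix:::new_polygon_set(
    polys, labels %||% paste0("p", seq_along(polys)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
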