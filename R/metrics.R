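#' Per-cell species richness
#'
#' SR counts all taxa present in a cell; ER counts the endemic subset.
#'
#' @param matrix A `community_matrix`.
#' @param endemic_only Count endemic taxa only (ER)?
#' @return A tibble with columns `cell` and `richness`.
#' @export
richness <- function(matrix, endemic_only = FALSE) {
  stopifnot(inherits(matrix, "community_matrix"))
  p <- matrix$presence
  if (endemic_only) p <- p[, matrix$endemic, drop = FALSE]
  tibble::tibble(cell = matrix$cell_id, richness = unname(rowSums(p)))
}

#' Per-cell weighted endemism
#'
#' WE sums, over the taxa present in a cell, the inverse of each taxon's
#' range size (number of occupied cells, optionally scaled by
#' `range_unit`).  Summed over all cells WE equals the number of taxa (the
#' conservation identity), since each taxon contributes 1/r in each of its
#' r cells.
#'
#' @param matrix A `community_matrix`.
#' @param endemic_only Use the endemic taxon subset only?
#' @param range_unit Scale factor applied to ranges (range in "units" is
#'   `range_cells * range_unit`); the default 1 keeps ranges in cells and
#'   bounds CWE by 1.
#' @return A tibble with columns `cell` and `WE`.
#' @export
weighted_endemism <- function(matrix, endemic_only = FALSE, range_unit = 1) {
  stopifnot(inherits(matrix, "community_matrix"))
  p <- matrix$presence
  if (endemic_only) p <- p[, matrix$endemic, drop = FALSE]
  if (ncol(p) == 0L) stop("empty taxon selection", call. = FALSE)
  r <- colSums(p) * range_unit
  tibble::tibble(cell = matrix$cell_id,
                 WE = as.numeric(p %*% (1 / r)))
}

#' Corrected weighted endemism
#'
#' CWE divides WE by the matching richness so the score reflects the
#' proportion of range-restriction rather than how many taxa a cell holds;
#' with ranges in cells it equals 1 exactly when every taxon in the cell
#' occurs nowhere else.  Zero-richness cells are excluded (with a message),
#' never propagated as NaN.
#'
#' @param we Per-cell WE tibble (columns `cell`, `WE`).
#' @param richness Per-cell richness tibble (columns `cell`, `richness`).
#' @return A tibble with columns `cell` and `CWE`.
#' @export
corrected_weighted_endemism <- function(we, richness) {
  stopifnot(is.data.frame(we), is.data.frame(richness))
  d <- dplyr::inner_join(we, richness, by = "cell")
  drop <- d$richness == 0
  if (any(drop))
    message(sum(drop), " zero-richness cells excluded from CWE")
  d <- d[!drop, , drop = FALSE]
  tibble::tibble(cell = d$cell, CWE = d$WE / d$richness)
}

# ---- branch incidence and phylogenetic endemism ---------------------------

#' Branch-by-cell incidence with branch lengths and ranges
#'
#' For every branch of the (pruned) tree, the branch is present in a cell
#' iff at least one descendant tip occurs there; the branch range is the
#' number of cells where it is present.  Computed with one post-order sweep
#' over the edge table.  The root path is included: every ancestral branch
#' of a present tip is present.
#'
#' @param tree An [ape::phylo]; tips must cover all matrix taxa (tree-only
#'   tips are pruned first).
#' @param matrix A `community_matrix`.
#' @return A `branch_incidence`: list with `incidence` (cells x branches
#'   binary matrix), `length` (per-branch), `range` (per-branch cell
#'   count), `cell_id`, and `tree` (the pruned tree; branch j is edge j of
#'   its edge table).
#' @export
branch_incidence <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "community_matrix"))
  miss <- setdiff(matrix$taxon_id, tree$tip.label)
  if (length(miss))
    stop("matrix taxa missing from tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(tree$tip.label, matrix$taxon_id)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)

  D <- edge_descendants(tree)                      # branches x tips
  P <- matrix$presence[, tree$tip.label, drop = FALSE]
  inc <- (P %*% t(D)) > 0                          # cells x branches
  storage.mode(inc) <- "integer"
  structure(
    list(incidence = inc,
         length = tree$edge.length,
         range = unname(colSums(inc)),
         cell_id = matrix$cell_id,
         tree = tree),
    class = "branch_incidence"
  )
}

# Binary branches x tips descendant indicator via post-order accumulation.
edge_descendants <- function(tree) {
  nt <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- nt + tree$Nnode
  below <- matrix(FALSE, nn, nt)                  # node -> descendant tips
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    below[a, ] <- below[a, ] | below[b, ]
  }
  D <- below[tree$edge[, 2], , drop = FALSE]      # original edge order
  storage.mode(D) <- "integer"
  colnames(D) <- tree$tip.label
  D
}

#' @export
print.branch_incidence <- function(x, ...) {
  cat(sprintf("<branch_incidence> %d cells x %d branches, total length %g\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$length)))
  invisible(x)
}

#' Per-cell phylogenetic endemism
#'
#' PE sums, over the branches present in a cell, branch length divided by
#' branch range: the cell's share of the evolutionary history it houses.
#' Summed over cells PE equals the total retained tree length.
#'
#' @param inc A [branch_incidence()].
#' @param drop_root Drop the branches incident to the root node (the basal
#'   split) from the sum?  Default keeps the full root path.
#' @return A tibble with columns `cell` and `PE`.
#' @export
phylogenetic_endemism <- function(inc, drop_root = FALSE) {
  stopifnot(inherits(inc, "branch_incidence"))
  w <- inc$length / inc$range
  if (drop_root) {
    root <- ape::Ntip(inc$tree) + 1L
    w[inc$tree$edge[, 1] == root] <- 0
  }
  tibble::tibble(cell = inc$cell_id,
                 PE = as.numeric(inc$incidence %*% w))
}

#' Equal-branch-length comparison tree
#'
#' Same topology, every branch set to T/N (total length over branch
#' count), so total length is preserved.  PE on this tree isolates the
#' spatial structure of endemism from branch-length variation; the
#' observed/comparison PE ratio (RPE) is then scale-free.
#'
#' @param tree An [ape::phylo] with positive total branch length.
#' @return A `phylo` with equalized branch lengths.
#' @export
make_comparison_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    stop("tree has zero total branch length", call. = FALSE)
  tree$edge.length <- rep(sum(tree$edge.length) / length(tree$edge.length),
                          length(tree$edge.length))
  tree
}

#' Relative phylogenetic endemism
#'
#' RPE = PE on the observed tree / PE on the equal-branch-length
#' comparison tree.  RPE > 1 flags cells whose restricted branches are
#' unusually long (old lineages), RPE < 1 unusually short (recent
#' radiations).  Cells with zero comparison PE are excluded (message).
#'
#' @param pe_obs,pe_alt Per-cell PE tibbles (columns `cell`, `PE`) on the
#'   observed and comparison trees.
#' @return A tibble with columns `cell` and `RPE`.
#' @export
relative_phylogenetic_endemism <- function(pe_obs, pe_alt) {
  d <- dplyr::inner_join(pe_obs, pe_alt, by = "cell",
                         suffix = c("_obs", "_alt"))
  drop <- d$PE_alt <= 0
  if (any(drop))
    message(sum(drop), " cells with zero comparison-tree PE excluded")
  d <- d[!drop, , drop = FALSE]
  tibble::tibble(cell = d$cell, RPE = d$PE_obs / d$PE_alt)
}

#' Full per-cell metric table
#'
#' One call computing the whole per-cell table: SR, ER, WE and CWE over
#' all native taxa (`WE`, `CWE_NAT`) and over endemics only (`WE_END`,
#' `CWE_END`), plus — when a tree is supplied — phylogenetic endemism on
#' the observed (`PE_obs`) and comparison (`PE_alt`) trees and their ratio
#' `RPE`, all computed on the endemic subset (the endemism-centre
#' analysis targets endemics).
#'
#' @param matrix A `community_matrix`.
#' @param tree Optional [ape::phylo] covering the endemic taxa.
#' @param range_unit Passed to [weighted_endemism()].
#' @return A tibble keyed by `cell`.
#' @export
cell_metrics <- function(matrix, tree = NULL, range_unit = 1) {
  stopifnot(inherits(matrix, "community_matrix"))
  sr <- richness(matrix)
  er <- richness(matrix, endemic_only = TRUE)
  we <- weighted_endemism(matrix, range_unit = range_unit)
  out <- tibble::tibble(cell = sr$cell, SR = sr$richness, ER = er$richness,
                        WE = we$WE)
  cwe_nat <- corrected_weighted_endemism(we, sr)
  out$CWE_NAT <- cwe_nat$CWE[match(out$cell, cwe_nat$cell)]
  if (any(matrix$endemic)) {
    wee <- weighted_endemism(matrix, endemic_only = TRUE,
                             range_unit = range_unit)
    cwee <- corrected_weighted_endemism(wee, er)
    out$WE_END <- wee$WE[match(out$cell, wee$cell)]
    out$CWE_END <- cwee$CWE[match(out$cell, cwee$cell)]
  }
  if (!is.null(tree)) {
    em <- subset_taxa(matrix, matrix$taxon_id[matrix$endemic])
    inc <- branch_incidence(tree, em)
    inc_alt <- branch_incidence(make_comparison_tree(inc$tree), em)
    pe <- phylogenetic_endemism(inc)
    pa <- phylogenetic_endemism(inc_alt)
    rpe <- relative_phylogenetic_endemism(pe, pa)
    out$PE_obs <- pe$PE[match(out$cell, pe$cell)]
    out$PE_alt <- pa$PE[match(out$cell, pa$cell)]
    out$RPE <- rpe$RPE[match(out$cell, rpe$cell)]
  }
  out
}
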