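#' Curveball (fixed-fixed) randomization of a community matrix
#'
#' One draw from a Markov chain over binary matrices with both margins
#' fixed: repeated "trades" pick two taxa and reshuffle the cells unique
#' to each between them, preserving every cell's richness and every
#' taxon's range exactly.  This is stricter than a richness-only
#' reallocation null: it also holds fixed the range sizes that weighted
#' endemism and phylogenetic endemism divide by.
#'
#' @param matrix A `community_matrix` with at least 2 cells and 2 taxa.
#' @param n_trades Number of trade attempts (default `5 * fill`, fill =
#'   number of presences).
#' @param seed Integer seed.
#' @return A `community_matrix` with identical margins.
#' @export
curveball_randomize <- function(matrix, n_trades = NULL, seed = 1L) {
  stopifnot(inherits(matrix, "community_matrix"))
  if (nrow(matrix$presence) < 2L || ncol(matrix$presence) < 2L)
    stop("need at least 2 cells and 2 taxa", call. = FALSE)
  fill <- sum(matrix$presence)
  if (is.null(n_trades)) n_trades <- 5L * fill
  if (n_trades < 0) stop("`n_trades` must be non-negative", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  sets <- presence_sets(matrix$presence)
  sets <- curveball_trades(sets, n_trades)
  new_community_matrix(sets_to_presence(sets, nrow(matrix$presence),
                                        dimnames(matrix$presence)),
                       matrix$cell_id, matrix$endemic, matrix$grid)
}

# taxa as lists of occupied row indices
presence_sets <- function(p) apply(p, 2L, function(col) which(col == 1L),
                                   simplify = FALSE)

sets_to_presence <- function(sets, n_rows, dn) {
  p <- matrix(0L, n_rows, length(sets), dimnames = dn)
  for (j in seq_along(sets)) p[sets[[j]], j] <- 1L
  p
}

# core chain: n_trades curveball trades on the set representation
curveball_trades <- function(sets, n_trades) {
  nt <- length(sets)
  if (n_trades == 0L) return(sets)
  pairs_i <- sample.int(nt, n_trades, replace = TRUE)
  pairs_j <- sample.int(nt - 1L, n_trades, replace = TRUE)
  pairs_j <- ifelse(pairs_j >= pairs_i, pairs_j + 1L, pairs_j)  # j != i
  for (t in seq_len(n_trades)) {
    i <- pairs_i[t]; j <- pairs_j[t]
    a <- sets[[i]]; b <- sets[[j]]
    ua <- a[!(a %in% b)]
    if (!length(ua)) next
    ub <- b[!(b %in% a)]
    if (!length(ub)) next
    pool <- c(ua, ub)
    pick <- sample.int(length(pool), length(ua))
    sets[[i]] <- c(a[a %in% b], pool[pick])
    sets[[j]] <- c(b[b %in% a], pool[-pick])
  }
  sets
}

# richness-only null: cells keep their richness, taxa reassigned uniformly
richness_randomize_sets <- function(row_sums, n_taxa) {
  lapply_sets <- vector("list", n_taxa)
  draws <- lapply(row_sums, function(k) sample.int(n_taxa, k))
  for (cell in seq_along(draws))
    for (tx in draws[[cell]])
      lapply_sets[[tx]] <- c(lapply_sets[[tx]], cell)
  lapply_sets
}

#' Null-model rank p-values for endemism metrics
#'
#' Recomputes the selected metrics on `reps` randomized matrices (tree
#' held fixed) and converts each cell's observed value into one-tailed
#' rank p-values: `p_high = (#\{null >= obs\} + 1) / (reps + 1)` and the
#' analogous `p_low`, both including the observation so p is never 0.
#' Ties (to a 1e-12 relative tolerance) count toward significance on both
#' tails.
#'
#' The default null is the curveball chain run continuously: a burn-in of
#' `n_trades` trades from the observed matrix, then one rep every
#' `n_trades` trades (thinning) without restarting.  `null = "richness"`
#' instead redraws each cell's taxa uniformly (richness fixed, ranges
#' free), closer to a richness-constrained reallocation null.
#'
#' @param matrix A `community_matrix` (for a CANAPE run, pass the
#'   endemic-taxa submatrix, e.g. `subset_taxa(m, m$taxon_id[m$endemic])`).
#' @param tree Optional [ape::phylo]; required for PE/RPE metrics.
#' @param metrics Character subset of
#'   `c("WE", "CWE", "PE_obs", "PE_alt", "RPE")`.
#' @param reps Number of null matrices (study analogue 999).
#' @param seed Integer seed (deterministic replay).
#' @param null `"curveball"` (fixed-fixed, default) or `"richness"`.
#' @param n_trades Trades per rep for the curveball chain (default
#'   `5 * fill`).
#' @return A `null_result`: list with `observed`, `p_high`, `p_low`
#'   (cells x metrics matrices), `n_used` (reps available per entry),
#'   `cell_id`, `reps`, `seed`, `null`.
#' @export
null_pvalues <- function(matrix, tree = NULL,
                         metrics = c("WE", "CWE", "PE_obs", "PE_alt", "RPE"),
                         reps = 999L, seed = 1L,
                         null = c("curveball", "richness"),
                         n_trades = NULL) {
  stopifnot(inherits(matrix, "community_matrix"), reps >= 1L)
  null <- match.arg(null)
  metrics <- match.arg(metrics, c("WE", "CWE", "PE_obs", "PE_alt", "RPE"),
                       several.ok = TRUE)
  need_tree <- any(metrics %in% c("PE_obs", "PE_alt", "RPE"))
  if (need_tree && is.null(tree))
    stop("PE/RPE metrics need a tree", call. = FALSE)

  p0 <- matrix$presence
  n_cell <- nrow(p0); n_taxa <- ncol(p0)
  fill <- sum(p0)
  if (is.null(n_trades)) n_trades <- 5L * fill

  pe_ctx <- NULL
  if (need_tree) {
    inc <- branch_incidence(tree, matrix)     # prunes tree to matrix taxa
    tr <- inc$tree
    alt <- make_comparison_tree(tr)
    D <- t(edge_descendants(tr))              # tips x branches
    D <- D[colnames(p0), , drop = FALSE]
    pe_ctx <- list(D = D, len_obs = tr$edge.length, len_alt = alt$edge.length)
  }

  eval_metrics <- function(p) {
    out <- matrix(NA_real_, n_cell, length(metrics),
                  dimnames = list(NULL, metrics))
    r <- colSums(p)
    if (any(c("WE", "CWE") %in% metrics)) {
      w <- ifelse(r > 0, 1 / r, 0)
      we <- as.numeric(p %*% w)
      if ("WE" %in% metrics) out[, "WE"] <- we
      if ("CWE" %in% metrics) {
        sr <- rowSums(p)
        out[, "CWE"] <- ifelse(sr > 0, we / sr, NA_real_)
      }
    }
    if (!is.null(pe_ctx) &&
        any(c("PE_obs", "PE_alt", "RPE") %in% metrics)) {
      binc <- (p %*% pe_ctx$D) > 0
      storage.mode(binc) <- "double"
      rb <- colSums(binc)
      wo <- ifelse(rb > 0, pe_ctx$len_obs / rb, 0)
      wa <- ifelse(rb > 0, pe_ctx$len_alt / rb, 0)
      pe_o <- as.numeric(binc %*% wo)
      pe_a <- as.numeric(binc %*% wa)
      if ("PE_obs" %in% metrics) out[, "PE_obs"] <- pe_o
      if ("PE_alt" %in% metrics) out[, "PE_alt"] <- pe_a
      if ("RPE" %in% metrics)
        out[, "RPE"] <- ifelse(pe_a > 0, pe_o / pe_a, NA_real_)
    }
    out
  }

  obs <- eval_metrics(p0)
  hi <- lo <- nn <- matrix(0L, n_cell, length(metrics),
                           dimnames = list(NULL, metrics))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  sets <- presence_sets(p0)
  if (null == "curveball") sets <- curveball_trades(sets, n_trades)  # burn-in
  row_sums <- rowSums(p0)
  eps <- 1e-12

  for (rep in seq_len(reps)) {
    sets <- if (null == "curveball") curveball_trades(sets, n_trades)
            else richness_randomize_sets(row_sums, n_taxa)
    p <- sets_to_presence(sets, n_cell, NULL)
    v <- eval_metrics(p)
    ok <- !is.na(v) & !is.na(obs)
    tol <- eps * pmax(abs(obs), 1)
    hi[ok & v >= obs - tol] <- hi[ok & v >= obs - tol] + 1L
    lo[ok & v <= obs + tol] <- lo[ok & v <= obs + tol] + 1L
    nn[ok] <- nn[ok] + 1L
  }
  if (any(nn < reps))
    message("some cells had metrics undefined on null matrices; ",
            "p-values use the available reps there")

  structure(
    list(observed = obs,
         p_high = (hi + 1L) / (nn + 1L),
         p_low = (lo + 1L) / (nn + 1L),
         n_used = nn, cell_id = matrix$cell_id,
         reps = as.integer(reps), seed = as.integer(seed), null = null),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> %d cells x %d metrics, %d reps, '%s' null, seed %d\n",
              nrow(x$observed), ncol(x$observed), x$reps, x$null, x$seed))
  invisible(x)
}

#' Tidy a null result into long form
#'
#' @param x A `null_result`.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `metric`, `observed`, `p_high`,
#'   `p_low`.
#' @method tidy null_result
#' @export
tidy.null_result <- function(x, ...) {
  mets <- colnames(x$observed)
  purrr::map_dfr(mets, function(m)
    tibble::tibble(cell = x$cell_id, metric = m,
                   observed = x$observed[, m],
                   p_high = x$p_high[, m], p_low = x$p_low[, m]))
}
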