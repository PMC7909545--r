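#' Define a synthetic landscape scenario
#'
#' Bundles every knob of the synthetic-data generator: grid size, taxon
#' counts, the right-skewed (log-normal) range-size distribution, the
#' planted paleo- and neo-endemism structure, the Gaussian-random-field
#' environmental surfaces with known linear effects, and the
#' protected-area coverage target.  One master `seed` fixes all
#' downstream randomness (each stage draws from a sub-seed derived from
#' it).
#'
#' Defaults describe the standard test landscape: a 25 x 20 grid (500
#' cells, the ~5 km national-grid analogue at desk scale), 300 taxa of
#' which the narrowest-ranged half are flagged endemic, ranges
#' log-normal with median 15 cells, five planted paleo cells hosting ten
#' old range-restricted lineages (pendant branches stretched 8x the
#' median, dye-confined to the paleo block), five planted neo cells
#' hosting a twelve-taxon recent radiation (crown at 10% of the anchor
#' depth, confined to the neo block), SAR effects beta = (1, -0.5) with
#' error autocorrelation lambda = 0.6, and protected areas covering 80%
#' of target cells.  Planted taxa are much narrower-ranged than the
#' landscape median, which is what makes their cells recoverable
#' endemism centres.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param n_taxa Total taxon count.
#' @param endemic_quantile Fraction of taxa (the narrowest-ranged) flagged
#'   endemic.
#' @param range_meanlog,range_sdlog Log-normal range-size parameters (cells).
#' @param paleo_cells,neo_cells Planted cell ids (`NULL` = compact blocks
#'   chosen in opposite grid corners; `integer(0)` disables planting).
#' @param n_paleo_taxa Number of planted old lineages.
#' @param paleo_multiplier Pendant-length multiplier for paleo lineages.
#' @param neo_clade_size Number of tips in the planted radiation.
#' @param neo_depth_fraction Crown depth of the radiation as a fraction of
#'   its anchor branch.
#' @param gp_range Gaussian-field correlation range (in cell widths).
#' @param beta True regression effects of the synthetic predictors.
#' @param lambda True spatial error autocorrelation.
#' @param sigma Error standard deviation.
#' @param coverage_fraction Fraction of target cells the synthetic
#'   protected areas cover (at >= the gap threshold each).
#' @param decoy_count Protected-area polygons placed away from targets.
#' @param cell_size,origin_x,origin_y Grid geometry (planar units).
#' @param seed Master seed.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_rows = 25, n_cols = 20, n_taxa = 300,
                               endemic_quantile = 0.5,
                               range_meanlog = log(15), range_sdlog = 0.75,
                               paleo_cells = NULL, n_paleo_taxa = 10,
                               paleo_multiplier = 8,
                               neo_cells = NULL, neo_clade_size = 12,
                               neo_depth_fraction = 0.1,
                               gp_range = 4, beta = c(1, -0.5),
                               lambda = 0.6, sigma = 1,
                               coverage_fraction = 0.8, decoy_count = 3,
                               cell_size = 5000, origin_x = 0, origin_y = 0,
                               seed = 1L) {
  grid <- grid_spec(origin_x, origin_y, cell_size, n_rows, n_cols)
  nc <- n_rows * n_cols
  block <- function(r0, c0, h, w)
    as.integer(outer((r0:(r0 + h - 1)) * n_cols, c0:(c0 + w - 1), "+"))
  if (is.null(paleo_cells) && n_paleo_taxa > 0)
    paleo_cells <- block(1, 1, 1, 5)                 # lower-left block
  if (is.null(neo_cells) && neo_clade_size > 0)
    neo_cells <- block(n_rows - 2, n_cols - 6, 1, 5) # upper-right block
  paleo_cells <- as.integer(paleo_cells %||% integer())
  neo_cells <- as.integer(neo_cells %||% integer())
  stopifnot(all(c(paleo_cells, neo_cells) >= 0),
            all(c(paleo_cells, neo_cells) < nc),
            n_taxa > 0, abs(lambda) < 1,
            endemic_quantile > 0, endemic_quantile <= 1)
  structure(
    list(grid = grid, n_taxa = as.integer(n_taxa),
         endemic_quantile = endemic_quantile,
         range_meanlog = range_meanlog, range_sdlog = range_sdlog,
         paleo_cells = paleo_cells, n_paleo_taxa = as.integer(n_paleo_taxa),
         paleo_multiplier = paleo_multiplier,
         neo_cells = neo_cells, neo_clade_size = as.integer(neo_clade_size),
         neo_depth_fraction = neo_depth_fraction,
         gp_range = gp_range, beta = beta, lambda = lambda, sigma = sigma,
         coverage_fraction = coverage_fraction,
         decoy_count = as.integer(decoy_count),
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

sub_seed <- function(sc, offset) (sc$seed * 97L + offset) %% 2147483642L + 1L

#' Simulate a gridded community with planted structure
#'
#' Ranges are drawn log-normal (rounded, clipped to `[1, n_cells]`) and
#' realized as spatially contiguous patches by a spreading-dye walk (a
#' patch grows from a random seed cell by annexing uniform random
#' 4-neighbours), giving the spatially coherent range geometry of real
#' floras.  The lowest range-size quantile is flagged endemic.  Planted
#' paleo/neo taxa are endemic taxa whose dye walk is confined to the
#' planted cell blocks.
#'
#' @param sc A [synthetic_scenario()].
#' @param scatter Use scattered random cells instead of contiguous
#'   patches.
#' @return A list: `matrix` (a `community_matrix`) and `ledger` (tibble
#'   `taxon`, `endemic`, `role` in `{background, paleo, neo}`, `range`,
#'   `cells` list-column).
#' @export
simulate_grid_community <- function(sc, scatter = FALSE) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  grid <- sc$grid
  nc <- n_cells(grid)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(sub_seed(sc, 1L))

  n <- sc$n_taxa
  raw <- round(stats::rlnorm(n, sc$range_meanlog, sc$range_sdlog))
  if (any(raw > nc))
    message(sum(raw > nc), " requested ranges clipped to the grid size")
  ranges <- as.integer(pmin(pmax(raw, 1L), nc))
  # endemic = narrowest-ranged quantile
  n_end <- max(round(sc$endemic_quantile * n),
               sc$n_paleo_taxa + sc$neo_clade_size)
  endemic <- rank(ranges, ties.method = "first") <= n_end
  taxon <- sprintf("t%03d", seq_len(n))
  role <- rep("background", n)
  end_idx <- which(endemic)
  if (sc$n_paleo_taxa > 0)
    role[end_idx[seq_len(sc$n_paleo_taxa)]] <- "paleo"
  if (sc$neo_clade_size > 0)
    role[end_idx[sc$n_paleo_taxa + seq_len(sc$neo_clade_size)]] <- "neo"

  cells <- vector("list", n)
  planted_rank <- ave(seq_len(n), role, FUN = seq_along)
  for (i in seq_len(n)) {
    allowed <- switch(role[i], paleo = sc$paleo_cells, neo = sc$neo_cells,
                      seq_len(nc) - 1L)
    # planted taxa: narrow ranges inside their block, independent of the
    # landscape range draw; every other planted taxon spans the whole
    # block so each planted cell is guaranteed several planted lineages
    size <- if (role[i] == "background") {
      min(ranges[i], length(allowed))
    } else if (planted_rank[i] %% 2L == 1L) {
      length(allowed)
    } else {
      sample.int(length(allowed), 1L)
    }
    cells[[i]] <- if (scatter) sample(allowed, size)
                  else spread_dye(allowed, size, grid)
    ranges[i] <- length(cells[[i]])
  }
  recs <- tibble::tibble(
    taxon = rep(taxon, ranges),
    cell = unlist(cells),
    endemic = rep(endemic, ranges))
  m <- build_matrix(recs, grid)
  ledger <- tibble::tibble(taxon = taxon, endemic = endemic, role = role,
                           range = ranges, cells = cells)
  list(matrix = m, ledger = ledger)
}

# grow a contiguous 4-connected patch of `size` cells inside `allowed`
spread_dye <- function(allowed, size, grid) {
  allowed_set <- allowed
  patch <- sample(allowed_set, 1L)
  frontier <- neighbours4(patch, grid)
  frontier <- frontier[frontier %in% allowed_set]
  while (length(patch) < size) {
    if (!length(frontier)) break   # exhausted the allowed component
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    patch <- c(patch, nxt)
    nb <- neighbours4(nxt, grid)
    frontier <- unique(c(frontier, nb))
    frontier <- frontier[frontier %in% allowed_set & !(frontier %in% patch)]
  }
  sort(patch)
}

neighbours4 <- function(cell, grid) {
  r <- cell %/% grid$n_cols; c <- cell %% grid$n_cols
  nb <- c(if (r > 0) cell - grid$n_cols,
          if (r < grid$n_rows - 1) cell + grid$n_cols,
          if (c > 0) cell - 1L,
          if (c < grid$n_cols - 1) cell + 1L)
  as.integer(nb)
}

#' Simulate a dated phylogeny with planted paleo / neo signal
#'
#' A Yule (pure-birth) backbone covers all background and paleo taxa plus
#' one anchor tip.  Planted paleo lineages get their pendant branch
#' stretched to `paleo_multiplier` times the median pendant length: old,
#' isolated, range-restricted lineages.  The anchor tip is replaced by a
#' Yule radiation of the planted neo clade whose crown depth is
#' `neo_depth_fraction` of the anchor pendant: young, short-branched,
#' range-restricted lineages.  With no planted taxa a plain Yule tree
#' over all taxa is returned (the null control).
#'
#' @param sc A [synthetic_scenario()].
#' @param community Output of [simulate_grid_community()].
#' @return A list: `tree` (phylo over all matrix taxa) and
#'   `planted` (tibble `cell`, `expected` in `{paleo, neo}`).
#' @export
simulate_endemism_tree <- function(sc, community) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  ledger <- community$ledger
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(sub_seed(sc, 2L))

  neo <- ledger$taxon[ledger$role == "neo"]
  paleo <- ledger$taxon[ledger$role == "paleo"]
  other <- ledger$taxon[ledger$role == "background"]
  if (length(neo) > 0 && length(neo) < 2)
    stop("neo clade needs at least 2 taxa", call. = FALSE)

  n_backbone <- length(other) + length(paleo) + (length(neo) > 0)
  tree <- ape::rphylo(n_backbone, birth = 1, death = 0)
  labs <- sample(c(other, paleo, if (length(neo)) "NEO_ANCHOR"))
  tree$tip.label <- labs

  # stretch paleo pendants
  if (length(paleo)) {
    pend <- tree$edge[, 2] <= ape::Ntip(tree)
    med <- stats::median(tree$edge.length[pend])
    for (tx in paleo) {
      i <- which(tree$edge[, 2] == match(tx, tree$tip.label))
      tree$edge.length[i] <- sc$paleo_multiplier * med
    }
  }

  # replace the anchor with a shallow radiation
  if (length(neo)) {
    wi <- match("NEO_ANCHOR", tree$tip.label)
    anchor_len <- tree$edge.length[tree$edge[, 2] == wi]
    clade <- ape::rphylo(length(neo), birth = 1, death = 0)
    clade$tip.label <- neo
    depth <- max(ape::node.depth.edgelength(clade))
    target_depth <- sc$neo_depth_fraction * anchor_len
    clade$edge.length <- clade$edge.length * (target_depth / depth)
    clade$root.edge <- anchor_len - target_depth
    tree <- ape::bind.tree(tree, clade, where = wi)
    tree <- ape::drop.tip(tree, "NEO_ANCHOR")
  }

  planted <- dplyr::bind_rows(
    if (length(sc$paleo_cells) && length(paleo))
      tibble::tibble(cell = sc$paleo_cells, expected = "paleo"),
    if (length(sc$neo_cells) && length(neo))
      tibble::tibble(cell = sc$neo_cells, expected = "neo"))
  list(tree = tree, planted = planted)
}

#' Simulate spatially structured predictors and a SAR-error response
#'
#' Predictors are mean-zero Gaussian random fields with exponential
#' covariance (`exp(-d / gp_range)`, distances in cell widths) over the
#' cell centres; the response is `y = X beta + u` with
#' `u = (I - lambda W)^(-1) e`, `e ~ N(0, sigma^2)`, on k = 4
#' symmetrized-union row-standardized nearest-neighbour weights.
#'
#' @param sc A [synthetic_scenario()].
#' @param cells Optional integer cell ids to simulate on (default all).
#' @param seed_offset Increment the scenario sub-seed (for replicate
#'   draws).
#' @return A list: `data` (tibble `cell`, `y`, `x1`..`xp`), `truth`
#'   (list `beta`, `lambda`, `sigma`), `W` (the weights list), `coords`.
#' @export
simulate_sar_surface <- function(sc, cells = NULL, seed_offset = 0L) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  grid <- sc$grid
  if (is.null(cells)) cells <- seq_len(n_cells(grid)) - 1L
  ctr <- cell_centers(grid, cells)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(sub_seed(sc, 3L + 1000L * as.integer(seed_offset)))

  n <- nrow(ctr); p <- length(sc$beta)
  d <- as.matrix(stats::dist(cbind(ctr$x, ctr$y))) / grid$cell_size
  L <- chol(exp(-d / sc$gp_range) + diag(1e-8, n))
  X <- crossprod(L, matrix(stats::rnorm(n * p), n, p))
  colnames(X) <- paste0("x", seq_len(p))
  Wl <- knn_weights(ctr[, c("x", "y")], 4L)
  eps <- stats::rnorm(n, 0, sc$sigma)
  u <- solve(diag(n) - sc$lambda * Wl$W, eps)
  y <- as.numeric(X %*% sc$beta + u)
  list(data = tibble::tibble(cell = ctr$cell, y = y,
                             tibble::as_tibble(X)),
       truth = list(beta = sc$beta, lambda = sc$lambda, sigma = sc$sigma),
       W = Wl, coords = ctr)
}

#' Simulate protected-area polygons with a known coverage split
#'
#' Places one rectangle over a configurable fraction of the target cells
#' — each rectangle covers 60% x 60% = 36% of its cell, comfortably above
#' the 10% gap threshold — plus `decoy_count` rectangles over random
#' non-target cells.  The ledger records the intended covered/uncovered
#' split, so gap arithmetic is checkable against ground truth.
#'
#' @param grid A [grid_spec()].
#' @param target_cells Integer cell ids the hotspot analysis will query.
#' @param coverage_fraction Fraction of targets to cover (in `[0, 1]`).
#' @param decoy_count Number of decoy polygons.
#' @param seed Integer seed.
#' @return A list: `polygons` (a `polygon_set`), `ledger` (tibble `cell`,
#'   `intended_covered`).
#' @export
simulate_protected_areas <- function(grid, target_cells, coverage_fraction,
                                     decoy_count = 3L, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("`coverage_fraction` must lie in [0, 1]", call. = FALSE)
  target_cells <- as.integer(target_cells)
  if (any(target_cells < 0 | target_cells >= n_cells(grid)))
    stop("target cells outside grid", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  n_cov <- round(coverage_fraction * length(target_cells))
  covered <- if (n_cov > 0) sort(sample(target_cells, n_cov)) else integer()
  rect_in_cell <- function(cell, f = 0.6) {
    b <- cell_bounds(grid, cell)
    w <- (b$xmax - b$xmin) * f / 2; h <- (b$ymax - b$ymin) * f / 2
    cx <- (b$xmin + b$xmax) / 2; cy <- (b$ymin + b$ymax) / 2
    list(rbind(c(cx - w, cy - h), c(cx + w, cy - h),
               c(cx + w, cy + h), c(cx - w, cy + h), c(cx - w, cy - h)))
  }
  polys <- lapply(covered, rect_in_cell)
  labs <- if (length(covered)) paste0("sac_", covered) else character()
  pool <- setdiff(seq_len(n_cells(grid)) - 1L, target_cells)
  if (decoy_count > 0 && length(pool)) {
    dec <- sample(pool, min(decoy_count, length(pool)))
    polys <- c(polys, lapply(dec, rect_in_cell))
    labs <- c(labs, paste0("decoy_", dec))
  }
  list(polygons = new_polygon_set(polys, labs),
       ledger = tibble::tibble(cell = target_cells,
                               intended_covered = target_cells %in% covered))
}

#' Simulate a collinear predictor table with a known independent core
#'
#' Builds `n_core` independent standard-normal predictors plus
#' `n_derived` redundant columns.  Each derived column mixes a primary
#' core (weight 0.8, giving a pairwise correlation ~0.8 that trips the
#' screen), a second core (weight 0.3), a *latent* group factor shared
#' by the siblings of one core, a latent factor common to all derived
#' columns, and private noise.  The latent factors are deliberately not
#' columns: the group factor stops any linear combination of siblings
#' from reconstructing their core, so core VIFs stay bounded, while the
#' common factor makes the derived columns mutually predictable, keeping
#' every derived column's VIF strictly above any core's at every stage
#' of an iterative screen.  A screen that drops the larger-VIF member of
#' every over-correlated pair therefore recovers exactly the core.
#'
#' @param n Number of rows (cells).
#' @param n_core Number of independent core predictors.
#' @param n_derived Number of redundant derived predictors.
#' @param seed Integer seed.
#' @return A list: `data` (tibble `core1..coreK, deriv1..derivM`) and
#'   `core` (the core column names).
#' @export
simulate_collinear_predictors <- function(n = 2000, n_core = 13,
                                          n_derived = 34, seed = 1L) {
  stopifnot(n_core >= 2, n_derived >= 0, n > n_core + n_derived)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  core <- matrix(stats::rnorm(n * n_core), n, n_core)
  colnames(core) <- paste0("core", seq_len(n_core))
  der <- matrix(NA_real_, n, n_derived)
  if (n_derived > 0) {
    latent <- matrix(stats::rnorm(n * n_core), n, n_core)
    global_f <- stats::rnorm(n)
    a <- 0.8; e <- 0.3; g <- 0.35; s <- 0.15
    b <- sqrt(1 - a^2 - e^2 - g^2 - s^2)      # unit total variance
    for (j in seq_len(n_derived)) {
      p0 <- (j - 1L) %% n_core                # primary core (0-based)
      q0 <- (p0 + 1L) %% n_core               # secondary core
      der[, j] <- a * core[, p0 + 1L] + e * core[, q0 + 1L] +
        g * global_f + b * latent[, p0 + 1L] + s * stats::rnorm(n)
    }
    colnames(der) <- paste0("deriv", seq_len(n_derived))
  }
  list(data = tibble::as_tibble(cbind(core, der)),
       core = colnames(core))
}
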