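#' Protected-area coverage fraction per grid cell
#'
#' Computes, for every requested cell, the exact planar area of the
#' intersection between the cell square and the union of all polygons,
#' divided by the cell area.  Overlapping polygons are unioned implicitly
#' (each point counts once), holes subtract, and stacking two identical
#' polygons changes nothing.  The computation is a vertical slab sweep:
#' within a slab no two edges cross (slab boundaries are placed at every
#' vertex, pairwise edge intersection and cell-boundary crossing), so each
#' polygon's interior is a set of trapezoids by the even-odd rule and the
#' union area is a sum of merged trapezoids — exact up to floating point.
#'
#' @param grid A [grid_spec()].
#' @param occupied_cells Integer cell ids to evaluate.
#' @param polygons A `polygon_set` (see [read_polygons_geojson()]).
#' @return A tibble with columns `cell` and `fraction` in `[0, 1]`.
#' @export
cell_coverage <- function(grid, occupied_cells, polygons) {
  stopifnot(inherits(grid, "grid_spec"), inherits(polygons, "polygon_set"))
  occupied_cells <- as.integer(occupied_cells)
  edges <- polygons_edge_table(polygons)
  bb <- cell_bounds(grid, occupied_cells)
  area <- grid$cell_size^2
  frac <- vapply(seq_len(nrow(bb)), function(i) {
    rect <- c(bb$xmin[i], bb$ymin[i], bb$xmax[i], bb$ymax[i])
    # bounding-box prefilter on polygons
    keep <- edges$poly_bb$xmin <= rect[3] & edges$poly_bb$xmax >= rect[1] &
            edges$poly_bb$ymin <= rect[4] & edges$poly_bb$ymax >= rect[2]
    if (!any(keep)) return(0)
    e <- edges$edges[edges$edges$poly %in% which(keep), , drop = FALSE]
    union_area_in_rect(e, rect) / area
  }, numeric(1))
  tibble::tibble(cell = occupied_cells, fraction = pmin(pmax(frac, 0), 1))
}

# flatten a polygon_set into an edge table (one row per non-vertical edge)
# plus per-polygon bounding boxes; degenerate rings are an error.
polygons_edge_table <- function(polygons) {
  rows <- list(); bb <- list()
  for (p in seq_along(polygons$polygons)) {
    xs <- c(); ys <- c()
    for (ring in polygons$polygons[[p]]) {
      m <- as.matrix(ring)
      # drop an explicit closing vertex, then re-close
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ,
                                                             drop = FALSE]
      m <- m[!duplicated(m), , drop = FALSE]
      if (nrow(m) < 3L)
        stop("degenerate ring in polygon '", polygons$labels[[p]], "'",
             call. = FALSE)
      nxt <- c(2:nrow(m), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        poly = p, x1 = m[, 1], y1 = m[, 2], x2 = m[nxt, 1], y2 = m[nxt, 2])
      xs <- c(xs, m[, 1]); ys <- c(ys, m[, 2])
    }
    bb[[p]] <- c(min(xs), min(ys), max(xs), max(ys))
  }
  edges <- do.call(rbind, rows)
  edges <- edges[edges$x1 != edges$x2, , drop = FALSE]  # vertical: no x-span
  bbm <- do.call(rbind, bb)
  list(edges = edges,
       poly_bb = data.frame(xmin = bbm[, 1], ymin = bbm[, 2],
                            xmax = bbm[, 3], ymax = bbm[, 4]))
}

# area of (union of polygons) %intersect% rectangle, given the edge table
union_area_in_rect <- function(e, rect) {
  if (!nrow(e)) return(0)
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  eps <- 1e-12 * max(abs(c(rect, e$x1, e$x2, e$y1, e$y2)), 1)

  lo <- pmin(e$x1, e$x2); hi <- pmax(e$x1, e$x2)
  keep <- hi > x0 & lo < x1
  e <- e[keep, , drop = FALSE]
  if (!nrow(e)) return(0)
  slope <- (e$y2 - e$y1) / (e$x2 - e$x1)

  xb <- c(x0, x1, e$x1, e$x2)
  # x where edges cross the rectangle's horizontal sides
  for (yc in c(y0, y1)) {
    xc <- e$x1 + (yc - e$y1) / slope
    ok <- is.finite(xc) & xc > pmin(e$x1, e$x2) & xc < pmax(e$x1, e$x2)
    xb <- c(xb, xc[ok])
  }
  # pairwise edge-line intersections within both segments
  n <- nrow(e)
  if (n > 1) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      ds <- slope[i] - slope[j]
      if (abs(ds) < eps) next
      xc <- ((e$y1[j] - slope[j] * e$x1[j]) -
             (e$y1[i] - slope[i] * e$x1[i])) / ds
      if (xc > max(pmin(e$x1, e$x2)[c(i, j)]) + eps &&
          xc < min(pmax(e$x1, e$x2)[c(i, j)]) - eps)
        xb <- c(xb, xc)
    }
  }
  xb <- sort(unique(pmin(pmax(xb, x0), x1)))
  xb <- xb[c(TRUE, diff(xb) > eps)]
  if (length(xb) < 2L) return(0)

  total <- 0
  exlo <- pmin(e$x1, e$x2); exhi <- pmax(e$x1, e$x2)
  for (s in seq_len(length(xb) - 1L)) {
    xa <- xb[s]; xz <- xb[s + 1L]; xm <- (xa + xz) / 2
    act <- which(exlo < xm & exhi > xm)
    if (!length(act)) next
    ya <- e$y1[act] + slope[act] * (xa - e$x1[act])
    ym <- e$y1[act] + slope[act] * (xm - e$x1[act])
    yz <- e$y1[act] + slope[act] * (xz - e$x1[act])
    ints <- list()
    for (p in unique(e$poly[act])) {
      idx <- which(e$poly[act] == p)
      if (length(idx) < 2L) next
      ord <- idx[order(ym[idx])]
      for (k in seq(1L, length(ord) - 1L, by = 2L)) {
        i1 <- ord[k]; i2 <- ord[k + 1L]
        # clamp to the rectangle's y-range (consistent within the slab)
        la <- min(max(ya[i1], y0), y1); lz <- min(max(yz[i1], y0), y1)
        ha <- min(max(ya[i2], y0), y1); hz <- min(max(yz[i2], y0), y1)
        if ((ha - la) + (hz - lz) <= 0) next
        ints[[length(ints) + 1L]] <-
          c(lo_a = la, lo_z = lz, hi_a = ha, hi_z = hz,
            lo_m = (la + lz) / 2, hi_m = (ha + hz) / 2)
      }
    }
    if (!length(ints)) next
    im <- do.call(rbind, ints)
    im <- im[order(im[, "lo_m"]), , drop = FALSE]
    # merge intervals (ordering at the midpoint holds across the slab)
    cur <- im[1, ]
    flush <- function(cv) ((cv[["hi_a"]] - cv[["lo_a"]]) +
                           (cv[["hi_z"]] - cv[["lo_z"]])) / 2 * (xz - xa)
    for (r in seq_len(nrow(im))[-1]) {
      nx <- im[r, ]
      if (nx[["lo_m"]] <= cur[["hi_m"]] + eps) {
        if (nx[["hi_m"]] > cur[["hi_m"]]) {
          cur[["hi_m"]] <- nx[["hi_m"]]
          cur[["hi_a"]] <- nx[["hi_a"]]; cur[["hi_z"]] <- nx[["hi_z"]]
        }
      } else {
        total <- total + flush(cur)
        cur <- nx
      }
    }
    total <- total + flush(cur)
  }
  total
}

#' Conservation gaps of a hotspot or endemism-centre cell set
#'
#' A member cell is a *gap* when its protected-area coverage fraction is
#' below `threshold` (default 10%, the minimum-coverage rule); the
#' overlap percentage is the share of member cells at or above it.
#'
#' @param set A `hotspot_set`, a `canape_classification` (all significant
#'   categories), or an integer vector of cell ids.
#' @param coverage A [cell_coverage()] tibble covering all member cells.
#' @param threshold Coverage fraction below which a cell is a gap.
#' @return A `gap_report`: list with `set_name`, `cells`, `coverage`
#'   (member-cell tibble), `covered`, `gaps` (cell id vectors) and
#'   `overlap_pct` (`NA` for an empty set).
#' @export
conservation_gaps <- function(set, coverage, threshold = 0.10) {
  stopifnot(is.data.frame(coverage),
            all(c("cell", "fraction") %in% names(coverage)))
  if (inherits(set, "hotspot_set")) {
    cells <- set$cells
    name <- paste(set$metric, set$level, set$tail, sep = "_")
  } else if (inherits(set, "canape_classification")) {
    cells <- set$cell[set$category != "not_significant"]
    name <- "canape_significant"
  } else {
    cells <- as.integer(set)
    name <- "cells"
  }
  if (!length(cells)) {
    return(structure(list(set_name = name, cells = integer(),
                          coverage = coverage[0, ], covered = integer(),
                          gaps = integer(), threshold = threshold,
                          overlap_pct = NA_real_),
                     class = "gap_report"))
  }
  miss <- setdiff(cells, coverage$cell)
  if (length(miss))
    stop("coverage missing for member cells: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  cov <- coverage[match(cells, coverage$cell), , drop = FALSE]
  gap <- cov$fraction < threshold
  structure(list(set_name = name, cells = cells, coverage = cov,
                 covered = cells[!gap], gaps = cells[gap],
                 threshold = threshold,
                 overlap_pct = 100 * mean(!gap)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %s: %d cells, %d covered, %d gaps (overlap %s%%)\n",
              x$set_name, length(x$cells), length(x$covered),
              length(x$gaps),
              if (is.na(x$overlap_pct)) "NA" else
                format(round(x$overlap_pct, 1))))
  invisible(x)
}

#' @method tidy gap_report
#' @export
tidy.gap_report <- function(x, ...) {
  tibble::tibble(cell = x$cells, fraction = x$coverage$fraction,
                 gap = x$cells %in% x$gaps, set = x$set_name)
}

#' @method glance gap_report
#' @export
glance.gap_report <- function(x, ...) {
  tibble::tibble(set = x$set_name, n_cells = length(x$cells),
                 n_covered = length(x$covered), n_gaps = length(x$gaps),
                 threshold = x$threshold, overlap_pct = x$overlap_pct)
}
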