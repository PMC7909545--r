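#' Percentile hotspot / coldspot cell sets
#'
#' L1/L2/L3 map to the most extreme 1%, 5% and 10% of cells.  The
#' threshold is the nearest-rank empirical quantile: with `k =
#' ceiling(frac * n)` cells in the tail, the threshold is the k-th most
#' extreme value, and *every* cell at the threshold is a member (ties are
#' never silently dropped — conservative for conservation ranking), so
#' membership can exceed `k` under ties.  If all values are identical the
#' set degenerates to all cells (a message is emitted).
#'
#' @param values A data frame with a `cell` column and one value column
#'   (the first non-cell column is used unless `value_col` names one).
#' @param level `"L1"`, `"L2"` or `"L3"` (top/bottom 1/5/10%).
#' @param tail `"high"` (hotspots) or `"low"` (coldspots).
#' @param metric Optional metric name recorded in the result.
#' @param value_col Optional name of the value column.
#' @return A `hotspot_set`: list with `metric`, `level`, `tail`,
#'   `threshold` and `cells` (integer ids).
#' @export
percentile_cells <- function(values, level = c("L3", "L2", "L1"),
                             tail = c("high", "low"), metric = NULL,
                             value_col = NULL) {
  level <- match.arg(level); tail <- match.arg(tail)
  stopifnot(is.data.frame(values), "cell" %in% names(values))
  if (is.null(value_col))
    value_col <- setdiff(names(values), "cell")[1]
  v <- values[[value_col]]
  keep <- is.finite(v)
  v <- v[keep]; cells <- values$cell[keep]
  if (!length(v)) stop("no finite values", call. = FALSE)
  frac <- c(L1 = 0.01, L2 = 0.05, L3 = 0.10)[[level]]
  k <- max(1L, ceiling(frac * length(v)))
  sv <- sort(v)
  if (tail == "high") {
    threshold <- sv[length(sv) - k + 1L]
    member <- v >= threshold
  } else {
    threshold <- sv[k]
    member <- v <= threshold
  }
  if (all(member)) message("degenerate percentile set: all cells members")
  structure(list(metric = metric %||% value_col, level = level, tail = tail,
                 threshold = threshold,
                 cells = sort(as.integer(cells[member]))),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> %s %s %s-tail: %d cells (threshold %g)\n",
              x$metric, x$level, x$tail, length(x$cells), x$threshold))
  invisible(x)
}

#' @method tidy hotspot_set
#' @export
tidy.hotspot_set <- function(x, ...) {
  tibble::tibble(cell = x$cells, metric = x$metric, level = x$level,
                 tail = x$tail)
}

#' Priority Hotspots: joint top-percentile cells of two metrics
#'
#' The intersection, at one level, of the high-tail percentile sets of
#' corrected weighted endemism of the endemics and phylogenetic endemism
#' — cells extreme on both the taxonomic and the phylogenetic
#' range-weighted facet of diversity.
#'
#' @param cwe_end Per-cell tibble (`cell` + value) of CWE over endemics.
#' @param pe Per-cell tibble (`cell` + value) of PE.
#' @param level `"L1"`, `"L2"` or `"L3"`.
#' @return A `hotspot_set` with the intersection cells.
#' @export
priority_hotspots <- function(cwe_end, pe, level = c("L3", "L2", "L1")) {
  level <- match.arg(level)
  if (!length(intersect(cwe_end$cell, pe$cell)))
    stop("metric tables share no cells", call. = FALSE)
  a <- percentile_cells(cwe_end, level, "high", metric = "CWE_END")
  b <- percentile_cells(pe, level, "high", metric = "PE")
  structure(list(metric = "priority", level = level, tail = "high",
                 threshold = NA_real_,
                 cells = intersect(a$cells, b$cells),
                 components = list(CWE_END = a, PE = b)),
            class = "hotspot_set")
}

#' Climate-stability index and refugia from time-slice stacks
#'
#' Per variable, the deviation of a cell is the mean over consecutive
#' time-slice pairs of `|v[t+1] - v[t]| / (elapsed time)`; stability is
#' the inverse deviation rescaled by its maximum to (0, 1].  Cells with
#' zero deviation (constant through time) are capped at the largest
#' finite stability before rescaling, so they score 1.  The overall index
#' is the product of the temperature and precipitation stabilities,
#' itself rescaled to max 1.  Climate refugia are the top 10% of cells of
#' the overall index.
#'
#' @param temperature,precipitation Data frames with a `cell` column and
#'   one column per time slice, ordered oldest to youngest.
#' @param ages Numeric slice ages (same length as slice columns; any
#'   monotone unit, e.g. Myr before present).
#' @return A list with `stability` (tibble: `cell`,
#'   `stability_temperature`, `stability_precipitation`, `stability`) and
#'   `refugia` (a `hotspot_set` at the 10% level).
#' @export
climate_stability <- function(temperature, precipitation, ages) {
  st <- slice_stability(temperature, ages)
  sp <- slice_stability(precipitation, ages)
  d <- dplyr::inner_join(st, sp, by = "cell", suffix = c("_t", "_p"))
  idx <- d$stability_t * d$stability_p
  idx <- idx / max(idx)
  out <- tibble::tibble(cell = d$cell,
                        stability_temperature = d$stability_t,
                        stability_precipitation = d$stability_p,
                        stability = idx)
  refugia <- percentile_cells(out[, c("cell", "stability")], "L3", "high",
                              metric = "climate_stability")
  list(stability = out, refugia = refugia)
}

# per-variable stability: inverse mean elapsed-time-weighted deviation,
# capped and rescaled to max 1
slice_stability <- function(slices, ages) {
  stopifnot(is.data.frame(slices), "cell" %in% names(slices))
  v <- as.matrix(slices[, setdiff(names(slices), "cell"), drop = FALSE])
  if (ncol(v) < 2L) stop("need at least 2 time slices", call. = FALSE)
  if (length(ages) != ncol(v))
    stop("`ages` must match the number of slice columns", call. = FALSE)
  dt <- abs(diff(ages))
  if (any(dt <= 0)) stop("slice ages must be strictly monotone", call. = FALSE)
  dev <- sweep(abs(v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]),
               2L, dt, "/")
  dev <- rowMeans(dev)
  if (all(dev == 0)) stop("constant climate: zero deviation everywhere",
                          call. = FALSE)
  stab <- 1 / dev
  finite_max <- max(stab[is.finite(stab)])
  if (any(!is.finite(stab)))
    message(sum(!is.finite(stab)),
            " zero-deviation cells capped at the maximum finite stability")
  stab[!is.finite(stab)] <- finite_max
  tibble::tibble(cell = slices$cell, stability = stab / max(stab))
}
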