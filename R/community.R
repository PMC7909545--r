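#' Build a gridded community matrix from occurrence records
#'
#' Collapses occurrence records into a binary cells x taxa presence matrix.
#' Duplicate (taxon, cell) records collapse silently to a single presence
#' (the number collapsed is reported via `message()`).  Cells with no
#' records are excluded from the row index (they are recoverable from the
#' grid), because richness-corrected endemism is undefined at zero
#' richness.
#'
#' @param records A data frame with columns `taxon`, `cell` (0-based id)
#'   and logical `endemic`; e.g. the `records` element of [assign_cells()].
#' @param grid A [grid_spec()].
#' @return A `community_matrix`: list with `presence` (binary integer
#'   matrix, occupied cells x taxa, dimnames = cell ids / taxon ids),
#'   `cell_id` (integer), `taxon_id` (character), `endemic` (named logical)
#'   and `grid`.
#' @examples
#' g <- grid_spec(0, 0, 10, 2, 2)
#' recs <- tibble::tibble(taxon = c("A", "A", "B"), cell = c(0L, 0L, 1L),
#'                        endemic = c(FALSE, FALSE, TRUE))
#' m <- build_matrix(recs, g)
#' richness(m)
#' @export
build_matrix <- function(records, grid) {
  stopifnot(is.data.frame(records), inherits(grid, "grid_spec"))
  if (nrow(records) == 0L) stop("no occurrence records", call. = FALSE)
  req <- c("taxon", "cell", "endemic")
  if (!all(req %in% names(records)))
    stop("`records` must have columns taxon, cell, endemic", call. = FALSE)
  if (anyNA(records$cell)) stop("records with missing cell id", call. = FALSE)
  if (any(records$cell < 0L | records$cell >= n_cells(grid)))
    stop("cell ids outside the grid", call. = FALSE)

  flag <- tapply(as.logical(records$endemic), records$taxon,
                 function(z) length(unique(z)))
  if (any(flag > 1L))
    stop("conflicting endemic flags for taxa: ",
         paste(names(flag)[flag > 1L], collapse = ", "), call. = FALSE)

  key <- paste(records$taxon, records$cell, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate (taxon, cell) records collapsed")
  rec <- records[!dup, , drop = FALSE]

  taxa <- sort(unique(rec$taxon))
  cells <- sort(unique(as.integer(rec$cell)))
  pres <- matrix(0L, nrow = length(cells), ncol = length(taxa),
                 dimnames = list(as.character(cells), taxa))
  pres[cbind(match(as.integer(rec$cell), cells), match(rec$taxon, taxa))] <- 1L

  endemic <- tapply(as.logical(rec$endemic), rec$taxon, `[`, 1L)[taxa]
  new_community_matrix(pres, cells, endemic, grid)
}

new_community_matrix <- function(presence, cell_id, endemic, grid) {
  structure(
    list(presence = presence,
         cell_id = as.integer(cell_id),
         taxon_id = colnames(presence),
         endemic = stats::setNames(as.logical(endemic), colnames(presence)),
         grid = grid),
    class = "community_matrix"
  )
}

validate_community_matrix <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  p <- m$presence
  if (!all(p %in% c(0L, 1L))) stop("presence entries must be 0/1", call. = FALSE)
  if (any(colSums(p) < 1L)) stop("taxa occupying zero cells", call. = FALSE)
  if (any(rowSums(p) < 1L)) stop("cells with zero taxa", call. = FALSE)
  invisible(m)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d occupied cells x %d taxa (%d endemic), %d presences\n",
              nrow(x$presence), ncol(x$presence), sum(x$endemic),
              sum(x$presence)))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$presence)

#' Per-taxon range sizes (number of occupied cells)
#'
#' @param matrix A `community_matrix`.
#' @return A tibble with columns `taxon`, `endemic`, `range`.
#' @export
taxon_ranges <- function(matrix) {
  stopifnot(inherits(matrix, "community_matrix"))
  tibble::tibble(taxon = matrix$taxon_id,
                 endemic = unname(matrix$endemic),
                 range = unname(colSums(matrix$presence)))
}

#' Tidy a community matrix into occurrence triplets
#'
#' @param x A `community_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `taxon`, `endemic`, one row per
#'   presence.
#' @method tidy community_matrix
#' @export
tidy.community_matrix <- function(x, ...) {
  idx <- which(x$presence == 1L, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(cell = x$cell_id[idx[, 1L]],
                 taxon = x$taxon_id[idx[, 2L]],
                 endemic = unname(x$endemic[idx[, 2L]]))
}

#' Restrict a community matrix to a taxon subset
#'
#' Cells left empty by the subset are dropped from the row index.
#'
#' @param matrix A `community_matrix`.
#' @param taxa Character vector of taxon ids to keep.
#' @return A `community_matrix`.
#' @export
subset_taxa <- function(matrix, taxa) {
  stopifnot(inherits(matrix, "community_matrix"))
  keep <- matrix$taxon_id %in% taxa
  if (!any(keep)) stop("empty taxon selection", call. = FALSE)
  p <- matrix$presence[, keep, drop = FALSE]
  occ <- rowSums(p) > 0L
  new_community_matrix(p[occ, , drop = FALSE], matrix$cell_id[occ],
                       matrix$endemic[keep], matrix$grid)
}
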