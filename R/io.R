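#' Read occurrence records from delimited text
#'
#' Accepts either `taxon,x,y,endemic` or `taxon,cell,endemic` headers (any
#' additional columns pass through).  `endemic` is parsed as logical
#' (TRUE/FALSE or 0/1).
#'
#' @param path Path to a comma-delimited file with a header.
#' @return A tibble of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(df) ||
      !("cell" %in% names(df) || all(c("x", "y") %in% names(df))))
    stop("occurrence file needs `taxon` and either `cell` or `x`+`y`",
         call. = FALSE)
  if (!"endemic" %in% names(df))
    stop("occurrence file needs an `endemic` column", call. = FALSE)
  df$endemic <- as.logical(df$endemic)
  if ("cell" %in% names(df)) df$cell <- as.integer(df$cell)
  tibble::as_tibble(df)
}

#' Write / read a community matrix as sparse triplet text
#'
#' The matrix is stored as two plain-text tables: `<stem>_presence.csv`
#' with columns `cell,taxon` (one row per presence) and a taxa sidecar
#' `<stem>_taxa.csv` with `taxon,endemic,range`, plus `<stem>_grid.csv`
#' holding the grid definition.  The round trip is exact.
#'
#' @param matrix A `community_matrix`.
#' @param stem Path stem (directory must exist).
#' @return `write_matrix()` returns the paths invisibly; `read_matrix()`
#'   returns the reconstructed `community_matrix`.
#' @export
write_matrix <- function(matrix, stem) {
  stopifnot(inherits(matrix, "community_matrix"))
  tr <- tidy.community_matrix(matrix)
  p1 <- paste0(stem, "_presence.csv")
  p2 <- paste0(stem, "_taxa.csv")
  p3 <- paste0(stem, "_grid.csv")
  utils::write.csv(tr[, c("cell", "taxon")], p1, row.names = FALSE)
  utils::write.csv(taxon_ranges(matrix), p2, row.names = FALSE)
  g <- matrix$grid
  utils::write.csv(data.frame(origin_x = g$origin_x, origin_y = g$origin_y,
                              cell_size = g$cell_size, n_rows = g$n_rows,
                              n_cols = g$n_cols, crs_label = g$crs_label),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' @rdname write_matrix
#' @export
read_matrix <- function(stem) {
  tr <- utils::read.csv(paste0(stem, "_presence.csv"),
                        stringsAsFactors = FALSE)
  tx <- utils::read.csv(paste0(stem, "_taxa.csv"), stringsAsFactors = FALSE)
  gd <- utils::read.csv(paste0(stem, "_grid.csv"), stringsAsFactors = FALSE)
  grid <- grid_spec(gd$origin_x, gd$origin_y, gd$cell_size, gd$n_rows,
                    gd$n_cols, gd$crs_label)
  tr$endemic <- tx$endemic[match(tr$taxon, tx$taxon)]
  build_matrix(tibble::as_tibble(tr), grid)
}

#' Read / write per-cell values as `cell,value` text
#'
#' @param path File path.
#' @param values A data frame with a `cell` column and one or more value
#'   columns.
#' @return `read_cell_values()` returns a tibble.
#' @export
write_cell_values <- function(values, path) {
  utils::write.csv(values, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_values
#' @export
read_cell_values <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# ---- polygons (GeoJSON) ----------------------------------------------------

#' Read polygons from GeoJSON
#'
#' Supports FeatureCollection / Feature / Polygon / MultiPolygon objects in
#' planar coordinates.  Each polygon is represented as a list of rings,
#' each ring an n x 2 coordinate matrix; the first ring is the outer
#' boundary, the rest are holes (GeoJSON convention).
#'
#' @param path Path to a GeoJSON file.
#' @return A `polygon_set`: list with `polygons` (list of lists of ring
#'   matrices), `labels` (character) and `properties` (tibble of feature
#'   properties, including a logical `marine` column when present).
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(gj$type,
    FeatureCollection = gj$features,
    Feature = list(gj),
    Polygon = ,
    MultiPolygon = list(list(type = "Feature", geometry = gj,
                             properties = list())),
    stop("unsupported GeoJSON type: ", gj$type, call. = FALSE))
  polys <- list(); labs <- character(); props <- list()
  ring_mat <- function(r)
    do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates,
                            function(pp) lapply(pp, ring_mat)),
      stop("unsupported geometry: ", geom$type, call. = FALSE))
    # MultiPolygon parts become separate entries sharing the label
    pr <- f$properties %||% list()
    lab <- pr$label %||% pr$name %||% paste0("poly_", i)
    for (part in rings) {
      polys[[length(polys) + 1L]] <- part
      labs <- c(labs, lab)
      props[[length(props) + 1L]] <- pr
    }
  }
  marine <- vapply(props, function(p) isTRUE(p$marine) ||
                     identical(p$marine, 1L) || identical(p$marine, 1), NA)
  new_polygon_set(polys, labs, marine)
}

new_polygon_set <- function(polygons, labels,
                            marine = rep(NA, length(polygons))) {
  structure(list(polygons = polygons, labels = labels,
                 marine = as.logical(marine)),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d polygon(s)\n", length(x$polygons)))
  invisible(x)
}

#' Drop marine-flagged polygons
#'
#' Protected-area layers may carry a `marine` attribute; polygons flagged
#' marine are excluded from terrestrial gap analysis.
#'
#' @param polys A `polygon_set`.
#' @return A `polygon_set` without marine polygons.
#' @export
filter_marine <- function(polys) {
  stopifnot(inherits(polys, "polygon_set"))
  keep <- !(polys$marine %in% TRUE)
  new_polygon_set(polys$polygons[keep], polys$labels[keep],
                  polys$marine[keep])
}

#' Write polygons (or labelled grid cells) to GeoJSON
#'
#' @param polys A `polygon_set`, or a tibble with `cell` plus attribute
#'   columns together with a `grid` to emit cell squares.
#' @param path Output path.
#' @param grid Optional [grid_spec()] when writing cell squares.
#' @return The path, invisibly.
#' @export
write_polygons_geojson <- function(polys, path, grid = NULL) {
  if (inherits(polys, "polygon_set")) {
    feats <- purrr::map2(polys$polygons, seq_along(polys$polygons),
      function(rings, i) {
        coords <- lapply(rings, function(m)
          lapply(seq_len(nrow(m)), function(j) as.numeric(m[j, ])))
        list(type = "Feature",
             properties = list(label = polys$labels[[i]]),
             geometry = list(type = "Polygon", coordinates = coords))
      })
  } else if (is.data.frame(polys) && !is.null(grid)) {
    bb <- cell_bounds(grid, polys$cell)
    attrs <- polys[setdiff(names(polys), "cell")]
    feats <- lapply(seq_len(nrow(bb)), function(i) {
      ring <- list(c(bb$xmin[i], bb$ymin[i]), c(bb$xmax[i], bb$ymin[i]),
                   c(bb$xmax[i], bb$ymax[i]), c(bb$xmin[i], bb$ymax[i]),
                   c(bb$xmin[i], bb$ymin[i]))
      list(type = "Feature",
           properties = c(list(cell = bb$cell[i]),
                          as.list(attrs[i, , drop = FALSE])),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
  } else stop("need a polygon_set, or a cell table plus `grid`", call. = FALSE)
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
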