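## Plain-text interchange formats: GeoJSON / CSV for geometry and point
## sets, CSV + JSON sidecar for gridded fields, JSON for configs.

#' Write cell outlines to GeoJSON
#'
#' One Polygon feature per cell with a `cell_id` property.
#'
#' @param outlines list of [cell_outline()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_outlines_geojson <- function(outlines, path) {
  feats <- lapply(outlines, function(o) {
    ring <- rbind(o$vertices, o$vertices[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(cell_id = o$cell_id),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell outlines from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of Polygon features with a
#'   `cell_id` property.
#' @return List of [cell_outline()] objects.
#' @export
read_outlines_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    if (f$geometry$type != "Polygon")
      stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ]))
      v <- v[-nrow(v), , drop = FALSE]
    cell_outline(v, cell_id = f$properties$cell_id)
  })
}

#' Write cell outlines to long-format CSV
#'
#' Columns: `cell_id`, `vertex_index`, `x_um`, `y_um`.
#'
#' @inheritParams write_outlines_geojson
#' @return `path`, invisibly.
#' @export
write_outlines_csv <- function(outlines, path) {
  rows <- lapply(outlines, function(o)
    data.frame(cell_id = o$cell_id,
               vertex_index = seq_len(nrow(o$vertices)),
               x_um = o$vertices[, 1], y_um = o$vertices[, 2]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read cell outlines from long-format CSV
#'
#' @param path CSV with columns `cell_id`, `vertex_index`, `x_um`, `y_um`.
#' @return List of [cell_outline()] objects.
#' @export
read_outlines_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cell_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("outline CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$vertex_index), ]
    cell_outline(cbind(g$x_um, g$y_um), cell_id = g$cell_id[1])
  })
}

read_outlines_any <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
    read_outlines_geojson(path)
  else read_outlines_csv(path)
}

#' Write nucleus/Golgi detections to CSV
#'
#' Columns: `frame`, `label`, `id`, `x_um`, `y_um`.
#'
#' @param nuclei,golgi [point_set()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(nuclei, golgi, path) {
  d <- rbind(
    data.frame(frame = nuclei$frame, label = "nucleus", id = nuclei$id,
               x_um = nuclei$x, y_um = nuclei$y),
    data.frame(frame = golgi$frame, label = "golgi", id = golgi$id,
               x_um = golgi$x, y_um = golgi$y))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read nucleus/Golgi detections from CSV
#'
#' @param path CSV with columns `frame`, `label` (nucleus/golgi), `id`,
#'   `x_um`, `y_um`.
#' @return A list with [point_set()]s `nuclei` and `golgi`.
#' @export
read_points_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "label", "id", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("points CSV must have columns: ", paste(need, collapse = ", "))
  n <- d[d$label == "nucleus", ]
  g <- d[d$label == "golgi", ]
  if (nrow(n) == 0) stop("no nuclei in points file")
  list(nuclei = point_set(n$x_um, n$y_um, id = n$id, label = "nucleus",
                          frame = n$frame),
       golgi = if (nrow(g)) point_set(g$x_um, g$y_um, id = g$id,
                                      label = "golgi", frame = g$frame)
               else point_set(numeric(0), numeric(0), id = integer(0),
                              label = "golgi"))
}

#' Write a gridded vector field as CSV plus JSON metadata
#'
#' Produces `<prefix>.csv` (columns `i`, `j`, `u`, `v`; row/column grid
#' indices) and `<prefix>.json` (`dx_um`, `kind`, `nx`, `ny`).
#'
#' @param field a [vector_field2d()].
#' @param prefix output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_field <- function(field, prefix) {
  stopifnot(inherits(field, "vector_field2d"))
  nx <- nrow(field$u); ny <- ncol(field$u)
  d <- data.frame(i = rep(seq_len(nx), ny),
                  j = rep(seq_len(ny), each = nx),
                  u = as.vector(field$u), v = as.vector(field$v))
  utils::write.csv(d, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(dx_um = field$dx, kind = field$kind,
                            nx = nx, ny = ny),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a gridded vector field written by [write_field()]
#'
#' @param prefix path prefix of the `.csv`/`.json` pair.
#' @return A [vector_field2d()].
#' @export
read_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  d <- utils::read.csv(paste0(prefix, ".csv"))
  u <- matrix(NA_real_, meta$nx, meta$ny)
  v <- matrix(NA_real_, meta$nx, meta$ny)
  u[cbind(d$i, d$j)] <- d$u
  v[cbind(d$i, d$j)] <- d$v
  vector_field2d(u, v, dx = meta$dx_um, kind = meta$kind)
}
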