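#' Planar point set
#'
#' Positions of detected nuclei or Golgi apparatus in micrometres.
#'
#' @param x,y coordinates (micrometres), finite.
#' @param id identifiers (defaults to `seq_along(x)`).
#' @param label `"nucleus"` or `"golgi"`.
#' @param frame time-frame index.
#' @return A data frame of class `point_set`.
#' @export
point_set <- function(x, y, id = seq_along(x),
                      label = c("nucleus", "golgi"), frame = 1L) {
  label <- match.arg(label)
  stopifnot(length(x) == length(y), length(id) == length(x))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("point coordinates must be finite")
  n <- length(x)
  structure(data.frame(id = id, x = x, y = y,
                       label = rep_len(label, n),
                       frame = rep_len(frame, n)),
            class = c("point_set", "data.frame"))
}

#' Assign Golgi detections to nuclei by Voronoi tessellation
#'
#' Each Golgi detection is associated with the nucleus whose Voronoi cell
#' contains it — equivalently, its nearest nucleus.  Exact distance ties
#' (points on a Voronoi edge) are broken towards the lowest nucleus id.
#'
#' @param nuclei a [point_set()] (or data frame with `id`, `x`, `y`) of
#'   nuclei; at least one.
#' @param golgi a point set of Golgi detections; may be empty.
#' @return A named list, one element per nucleus id, each an integer vector
#'   of row indices into `golgi` (possibly empty).
#' @export
voronoi_assign <- function(nuclei, golgi) {
  if (nrow(nuclei) == 0) stop("at least one nucleus is required")
  out <- stats::setNames(
    rep(list(integer(0)), nrow(nuclei)), as.character(nuclei$id))
  if (is.null(golgi) || nrow(golgi) == 0) return(out)
  for (g in seq_len(nrow(golgi))) {
    d2 <- (nuclei$x - golgi$x[g])^2 + (nuclei$y - golgi$y[g])^2
    cand <- which(d2 == min(d2))
    k <- cand[which.min(nuclei$id[cand])]
    key <- as.character(nuclei$id[k])
    out[[key]] <- c(out[[key]], g)
  }
  out
}

#' Distance-weighted Golgi position
#'
#' Multiple Golgi fragments of one cell are combined into a single
#' position by inverse-distance weighting from the nucleus,
#' \eqn{w_i = 1 / (d_i + \delta)}, with a small guard distance
#' \eqn{\delta} keeping the weights bounded at the nucleus.
#'
#' @param nucleus_pos length-2 numeric (micrometres).
#' @param golgi_positions n x 2 matrix of fragment positions; n >= 1.
#' @param delta guard distance in micrometres.
#' @return Length-2 weighted position.
#' @export
weighted_golgi_position <- function(nucleus_pos, golgi_positions,
                                    delta = 0.1) {
  golgi_positions <- matrix(as.numeric(golgi_positions), ncol = 2)
  if (nrow(golgi_positions) == 0) stop("at least one Golgi is required")
  d <- sqrt((golgi_positions[, 1] - nucleus_pos[1])^2 +
              (golgi_positions[, 2] - nucleus_pos[2])^2)
  w <- 1 / (d + delta)
  c(sum(w * golgi_positions[, 1]), sum(w * golgi_positions[, 2])) / sum(w)
}

#' Planar-cell-polarity index of one cell
#'
#' Forms the nucleus-to-Golgi vector and measures its angle \eqn{\phi}
#' against the flow direction; the PCP index is \eqn{\cos\phi}.  Under
#' this convention a Golgi displaced downstream (with the flow) scores +1
#' and the physiological upstream polarisation (Golgi against the flow)
#' scores -1.
#'
#' @param nucleus_pos,golgi_pos length-2 positions (micrometres).
#' @param flow_direction flow direction: either a length-2 vector
#'   (normalised internally) or a single angle in degrees.
#' @param nucleus_id identifier carried into the record.
#' @return A one-row data frame (`nucleus_id`, `nucleus_x`, `nucleus_y`,
#'   `golgi_x`, `golgi_y`, `phi` in degrees `[0, 180]`, `phi_signed` in
#'   degrees `(-180, 180]`, `pcp_index`); `phi` and `pcp_index` are `NA`
#'   when the points coincide.
#' @export
pcp_index <- function(nucleus_pos, golgi_pos, flow_direction = 0,
                      nucleus_id = NA) {
  f <- flow_unit(flow_direction)
  v <- c(golgi_pos[1] - nucleus_pos[1], golgi_pos[2] - nucleus_pos[2])
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    phi <- NA_real_; phis <- NA_real_; idx <- NA_real_
  } else {
    ct <- sum(v * f) / nv
    ct <- max(-1, min(1, ct))
    phi <- acos(ct) * 180 / pi
    phis <- atan2(f[1] * v[2] - f[2] * v[1], sum(v * f)) * 180 / pi
    idx <- ct
  }
  data.frame(nucleus_id = nucleus_id, nucleus_x = nucleus_pos[1],
             nucleus_y = nucleus_pos[2], golgi_x = golgi_pos[1],
             golgi_y = golgi_pos[2], phi = phi, phi_signed = phis,
             pcp_index = idx)
}

flow_unit <- function(flow_direction) {
  if (length(flow_direction) == 1) {
    a <- flow_direction * pi / 180
    c(cos(a), sin(a))
  } else {
    n <- sqrt(sum(flow_direction^2))
    if (n == 0) stop("flow direction must be non-zero")
    flow_direction / n
  }
}

#' Full PCP pipeline over detected point sets
#'
#' Voronoi-assigns Golgi to nuclei, combines fragments by
#' [weighted_golgi_position()] and computes the per-cell PCP record.
#' Nuclei without any assigned Golgi are dropped from the table and
#' counted in the `dropped` attribute (quality control), as are cells
#' whose weighted Golgi coincides with the nucleus.
#'
#' @inheritParams voronoi_assign
#' @param flow_direction flow direction (angle in degrees or 2-vector).
#' @param delta guard distance of the fragment weighting, micrometres.
#' @return A data frame of PCP records (see [pcp_index()]) plus `n_golgi`,
#'   with attributes `dropped` (count) and `mean_index`.
#' @export
pcp_table <- function(nuclei, golgi, flow_direction = 0, delta = 0.1) {
  assign <- voronoi_assign(nuclei, golgi)
  rows <- list(); dropped <- 0L
  for (k in seq_len(nrow(nuclei))) {
    idx <- assign[[as.character(nuclei$id[k])]]
    if (length(idx) == 0) { dropped <- dropped + 1L; next }
    np <- c(nuclei$x[k], nuclei$y[k])
    gp <- weighted_golgi_position(np, cbind(golgi$x[idx], golgi$y[idx]),
                                  delta)
    rec <- pcp_index(np, gp, flow_direction, nucleus_id = nuclei$id[k])
    if (!is.finite(rec$pcp_index)) { dropped <- dropped + 1L; next }
    rec$n_golgi <- length(idx)
    rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(0), nucleus_x = numeric(0),
               nucleus_y = numeric(0), golgi_x = numeric(0),
               golgy_y = numeric(0), phi = numeric(0),
               phi_signed = numeric(0), pcp_index = numeric(0),
               n_golgi = integer(0))
  attr(out, "dropped") <- dropped
  attr(out, "mean_index") <- if (nrow(out)) mean(out$pcp_index) else NA_real_
  out
}

#' Radial distribution of PCP angles
#'
#' Histogram of the signed nucleus-to-Golgi vector angles over
#' `[0, 360)` degrees (full-circle version, suitable for rose plots);
#' counts sum to the number of records.
#'
#' @param records a [pcp_table()] result (uses its `phi_signed` column) or
#'   a numeric vector of signed angles in degrees.
#' @param bins number of angular bins.
#' @return A data frame (`bin_center`, `count`, `frequency`).
#' @export
pcp_distribution <- function(records, bins = 12) {
  phi <- if (is.data.frame(records)) records$phi_signed else records
  phi <- phi[is.finite(phi)]
  if (length(phi) == 0) stop("no finite PCP angles")
  stopifnot(bins >= 1)
  phi <- phi %% 360
  width <- 360 / bins
  bin <- pmin(floor(phi / width), bins - 1)
  count <- tabulate(bin + 1L, nbins = bins)
  data.frame(bin_center = (seq_len(bins) - 0.5) * width, count = count,
             frequency = count / length(phi))
}
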