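#' Cell outline
#'
#' An ordered planar polygon (micrometres) describing one segmented cell.
#'
#' @param vertices two-column numeric matrix (x, y) of ordered vertices;
#'   at least three, finite, enclosing positive area.  Do not repeat the
#'   first vertex at the end.
#' @param cell_id identifier.
#' @return An object of class `cell_outline`.
#' @export
cell_outline <- function(vertices, cell_id = NA) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || !all(is.finite(vertices)))
    stop("'vertices' must be a finite n x 2 matrix with n >= 3")
  if (abs(polygon_area(vertices)) < .Machine$double.eps * 100)
    stop("degenerate polygon: zero area")
  structure(list(vertices = vertices, cell_id = cell_id),
            class = "cell_outline")
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# Exact area, centroid and second central moments of a simple polygon
# (Green's theorem).  Returns the normalised central moment (covariance)
# matrix, valid for either vertex orientation.
polygon_moments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  A <- 0.5 * sum(cross)
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  ixx <- sum((x^2 + x * xn + xn^2) * cross) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cross) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  cov <- matrix(c(ixx / A - cx^2, ixy / A - cx * cy,
                  ixy / A - cx * cy, iyy / A - cy^2), 2, 2)
  list(area = abs(A), centroid = c(cx, cy), cov = cov)
}

#' Equivalent-ellipse fit of a cell outline
#'
#' Fits the ellipse with the same area and the same normalised second
#' central moments as the polygon, computed exactly from the vertices
#' (no rasterisation).  For an ellipse the covariance eigenvalues are
#' \eqn{a^2/4} and \eqn{b^2/4}; the fitted semi-axes take their ratio from
#' the moments and are rescaled to match the polygon area.
#'
#' @param outline a [cell_outline()] (or bare n x 2 vertex matrix).
#' @return An object of class `ellipse_fit` with fields `centroid`,
#'   `major` (semi-axis a), `minor` (semi-axis b), `angle` (major-axis
#'   direction, degrees in `[0, 180)`), `area` and `cell_id`.
#' @export
fit_ellipse <- function(outline) {
  if (!inherits(outline, "cell_outline")) outline <- cell_outline(outline)
  m <- polygon_moments(outline$vertices)
  e <- eigen(m$cov, symmetric = TRUE)
  if (e$values[2] <= 0)
    stop("degenerate polygon: collinear vertices")
  a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
  s <- sqrt(m$area / (pi * a * b))  # same-area normalisation
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  ang <- ang %% 180
  structure(list(centroid = m$centroid, major = a * s, minor = b * s,
                 angle = ang, area = m$area, cell_id = outline$cell_id),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "Ellipse fit: centre (%.2f, %.2f), a = %.3f, b = %.3f, angle = %.2f deg\n",
    x$centroid[1], x$centroid[2], x$major, x$minor, x$angle))
  invisible(x)
}

#' Cell aspect ratio
#'
#' Major over minor semi-axis of the fitted ellipse: 1 for a perfect
#' circle, larger for elongated cells.
#'
#' @param fit an [fit_ellipse()] result.
#' @return Ratio >= 1.
#' @export
aspect_ratio <- function(fit) {
  stopifnot(inherits(fit, "ellipse_fit"))
  fit$major / fit$minor
}

#' Orientation angle against a reference direction
#'
#' Acute angle between the fitted major axis and the reference direction,
#' folded to `[0, 90]` degrees (nematic head-tail symmetry): 0 for perfect
#' alignment, 90 for orthogonal alignment.  Circle-degenerate fits (no
#' defined major axis) return `NA`.
#'
#' @param fit an [fit_ellipse()] result.
#' @param reference reference direction in degrees (for flow experiments,
#'   the flow direction; for static samples, the horizontal axis).
#' @param tol relative axis-ratio tolerance below which the fit counts as
#'   circular.
#' @return Angle in degrees in `[0, 90]`, or `NA` for a circular fit.
#' @export
orientation_angle <- function(fit, reference = 0, tol = 1e-9) {
  stopifnot(inherits(fit, "ellipse_fit"))
  if (fit$major / fit$minor - 1 < tol) return(NA_real_)
  fold_angle(fit$angle - reference)
}

#' Fold an angle to the acute nematic range
#'
#' @param angle angle(s) in degrees.
#' @return Equivalent angle(s) in `[0, 90]` under 180-degree (head-tail)
#'   symmetry.
#' @export
fold_angle <- function(angle) {
  a <- angle %% 180
  pmin(a, 180 - a)
}

#' Experimental nematic order parameter
#'
#' \eqn{S = \langle\cos^2\theta\rangle - 1/3} over the measured orientation
#' angles; ranges from \eqn{-1/3} (all orthogonal) through \eqn{1/6}
#' (2D-isotropic) to \eqn{2/3} (all aligned).
#'
#' @param angles orientation angles in degrees (any fold; the statistic is
#'   invariant under `theta -> 180 - theta`).
#' @return The scalar order parameter.
#' @export
order_parameter <- function(angles) {
  if (length(angles) == 0) stop("'angles' must be non-empty")
  if (!all(is.finite(angles))) stop("'angles' must be finite")
  mean(cos(angles * pi / 180)^2) - 1 / 3
}

#' Summary of folded orientation angles
#'
#' Arithmetic mean and standard deviation of angles folded to `[0, 90]`
#' degrees.  For isotropic (randomly oriented) monolayers the mean
#' converges to 45 degrees; deviations flag collective alignment along
#' (towards 0) or across (towards 90) the reference.
#'
#' @param angles orientation angles in degrees.
#' @return A list with `mean`, `sd` and `n`.
#' @export
orientation_summary <- function(angles) {
  if (length(angles) == 0) stop("'angles' must be non-empty")
  a <- fold_angle(angles[is.finite(angles)])
  if (length(a) == 0) stop("'angles' contains no finite values")
  list(mean = mean(a), sd = if (length(a) > 1) sd(a) else 0,
       n = length(a))
}

#' Per-cell shape metrics table
#'
#' Runs [fit_ellipse()] over a collection of outlines and tabulates
#' centroid, aspect ratio and orientation angle.
#'
#' @param outlines list of [cell_outline()] objects.
#' @param reference reference direction in degrees.
#' @return A data frame (cell_id, centroid_x, centroid_y, area,
#'   aspect_ratio, orientation_deg) with a `summary` attribute holding the
#'   orientation mean/sd and order parameter.
#' @export
monolayer_metrics <- function(outlines, reference = 0) {
  stopifnot(length(outlines) > 0)
  rows <- lapply(outlines, function(o) {
    f <- fit_ellipse(o)
    data.frame(cell_id = as.character(f$cell_id),
               centroid_x = f$centroid[1], centroid_y = f$centroid[2],
               area = f$area, aspect_ratio = aspect_ratio(f),
               orientation_deg = orientation_angle(f, reference))
  })
  out <- do.call(rbind, rows)
  ang <- out$orientation_deg[is.finite(out$orientation_deg)]
  smry <- orientation_summary(ang)
  smry$S <- order_parameter(ang)
  attr(out, "summary") <- smry
  out
}
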