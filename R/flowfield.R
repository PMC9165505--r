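#' Gridded 2D vector field
#'
#' Container for per-node vector data on a regular grid: velocity
#' (micrometres per hour), traction (Pa) or displacement (micrometres).
#' `NA` nodes form a mask that is propagated by all operations.
#'
#' @param u,v component matrices of equal dimension.
#' @param dx grid spacing in micrometres.
#' @param kind one of `"velocity"`, `"traction"`, `"displacement"`.
#' @return An object of class `vector_field2d`.
#' @export
vector_field2d <- function(u, v, dx,
                           kind = c("velocity", "traction",
                                    "displacement")) {
  kind <- match.arg(kind)
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == dim(v))) stop("'u' and 'v' must have the same shape")
  if (!is.numeric(dx) || length(dx) != 1 || dx <= 0)
    stop("'dx' must be a positive grid spacing (micrometres)")
  structure(list(u = u, v = v, dx = dx, kind = kind),
            class = "vector_field2d")
}

#' @export
print.vector_field2d <- function(x, ...) {
  cat(sprintf("%s field: %d x %d nodes, dx = %g um (%d NA nodes)\n",
              x$kind, nrow(x$u), ncol(x$u), x$dx,
              sum(is.na(x$u) | is.na(x$v))))
  invisible(x)
}

#' Per-node vector magnitude
#'
#' \eqn{M = \sqrt{u^2 + v^2}} at every grid node; `NA` nodes propagate.
#'
#' @param field a [vector_field2d()].
#' @return Matrix of magnitudes.
#' @export
magnitude <- function(field) {
  stopifnot(inherits(field, "vector_field2d"))
  sqrt(field$u^2 + field$v^2)
}

#' Remove mean drift from a velocity field
#'
#' Subtracts the component-wise mean over non-`NA` nodes, removing any
#' rigid drift bias before correlation analysis.
#'
#' @param field a [vector_field2d()].
#' @return The drift-free field (component means are zero).
#' @export
subtract_drift <- function(field) {
  stopifnot(inherits(field, "vector_field2d"))
  ok <- !(is.na(field$u) | is.na(field$v))
  if (!any(ok)) stop("field is entirely NA")
  field$u <- field$u - mean(field$u[ok])
  field$v <- field$v - mean(field$v[ok])
  field
}

#' Spatial velocity autocorrelation
#'
#' Isotropically binned two-point correlation
#' \deqn{C_{vv}(r) = \frac{\langle \delta v(x)\cdot\delta v(x + r)\rangle}
#'                        {\langle |\delta v|^2 \rangle},}
#' averaged over all node pairs at separation distance r (no periodicity
#' assumed); \eqn{C_{vv}(0) = 1} by construction.  Supply a
#' drift-subtracted field (see [subtract_drift()]).
#'
#' The `"fft"` method computes the pair sums by zero-padded FFT
#' cross-correlation with mask normalisation (handles `NA` nodes); the
#' `"direct"` method is the quadratic-time reference sum used as its test
#' oracle.
#'
#' @param field a [vector_field2d()] (drift-subtracted velocity).
#' @param max_r largest separation in micrometres (default: half the
#'   smaller grid extent).
#' @param bin_width radial bin width in micrometres (default: one grid
#'   spacing).
#' @param method `"fft"` or `"direct"`.
#' @return A data frame (`r`, `C_vv`, `n_pairs`); bin centres at integer
#'   multiples of `bin_width` starting from 0.
#' @export
velocity_correlation <- function(field, max_r = NULL, bin_width = NULL,
                                 method = c("fft", "direct")) {
  stopifnot(inherits(field, "vector_field2d"))
  method <- match.arg(method)
  dx <- field$dx
  if (is.null(bin_width)) bin_width <- dx
  if (is.null(max_r)) max_r <- dx * (min(dim(field$u)) - 1) / 2
  ok <- !(is.na(field$u) | is.na(field$v))
  if (sum(ok) < 2) stop("need at least 2 non-NA nodes")
  u <- ifelse(ok, field$u, 0); v <- ifelse(ok, field$v, 0)
  norm <- sum(u^2 + v^2) / sum(ok)
  if (norm == 0) stop("zero field has no correlation structure")
  nb <- floor(max_r / bin_width + 0.5) + 1L
  num <- numeric(nb); cnt <- numeric(nb)

  if (method == "direct") {
    nx <- nrow(u); ny <- ncol(u)
    id <- which(ok, arr.ind = TRUE)
    val <- cbind(u[ok], v[ok])
    n <- nrow(id)
    for (a in seq_len(n)) {
      dxs <- (id[, 1] - id[a, 1]) * dx
      dys <- (id[, 2] - id[a, 2]) * dx
      r <- sqrt(dxs^2 + dys^2)
      k <- floor(r / bin_width + 0.5) + 1L
      keep <- k <= nb
      s <- val[, 1] * val[a, 1] + val[, 2] * val[a, 2]
      num_a <- tapply(s[keep], k[keep], sum)
      cnt_a <- tapply(rep(1, sum(keep)), k[keep], sum)
      ki <- as.integer(names(num_a))
      num[ki] <- num[ki] + num_a
      cnt[ki] <- cnt[ki] + cnt_a
    }
  } else {
    cor2 <- function(m) {
      nx <- nrow(m); ny <- ncol(m)
      px <- stats::nextn(2 * nx - 1); py <- stats::nextn(2 * ny - 1)
      pad <- matrix(0, px, py); pad[1:nx, 1:ny] <- m
      ft <- stats::fft(pad)
      Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / (px * py)
    }
    suu <- cor2(u) + cor2(v)
    cts <- cor2(ok + 0)
    px <- nrow(suu); py <- ncol(suu)
    # displacement (di, dj) lives at wrapped index; enumerate |di|,|dj|
    nx <- nrow(u); ny <- ncol(u)
    dmax <- floor(max_r / dx + 1)
    for (di in 0:min(nx - 1, dmax)) for (dj in (-min(ny - 1, dmax)):
                                           min(ny - 1, dmax)) {
      if (di == 0 && dj < 0) next  # (0,-dj) duplicates (0,dj)
      r <- sqrt(di^2 + dj^2) * dx
      k <- floor(r / bin_width + 0.5) + 1L
      if (k > nb) next
      ii <- di + 1L
      jj <- if (dj >= 0) dj + 1L else py + dj + 1L
      w <- if (di == 0 && dj == 0) 1 else 2  # count (d) and (-d)
      num[k] <- num[k] + w * suu[ii, jj]
      cnt[k] <- cnt[k] + w * round(cts[ii, jj])
    }
  }
  keep <- cnt > 0
  data.frame(r = (seq_len(nb)[keep] - 1) * bin_width,
             C_vv = (num[keep] / cnt[keep]) / norm,
             n_pairs = cnt[keep])
}

#' Velocity correlation length
#'
#' Nonlinear least-squares fit of \eqn{f(r) = e^{-r/C_L}} to the binned
#' correlation over \eqn{r > 0} (the r = 0 point is excluded; the model is
#' pinned to 1 there by construction).  The single parameter is located by
#' golden-section minimisation of the residual sum of squares on the
#' correlation values directly (no log transform), which is robust to
#' near-zero tail values.
#'
#' @param r separations in micrometres (>= 3 values including r = 0).
#' @param C_vv correlation values; `C_vv[r == 0]` should be ~1.
#' @return A list with `C_L` (micrometres) and `residual` (RMS of fit
#'   residuals over the fitted range).
#' @export
correlation_length <- function(r, C_vv) {
  stopifnot(length(r) == length(C_vv), length(r) >= 3)
  pos <- r > 0 & is.finite(C_vv)
  if (sum(pos) < 2) stop("need at least 2 positive-r bins")
  rr <- r[pos]; cc <- C_vv[pos]
  if (mean(cc) > 0.99)
    stop("correlation does not decay over the sampled range; cannot fit")
  sse <- function(cl) sum((cc - exp(-rr / cl))^2)
  opt <- stats::optimize(sse, interval = c(min(rr) / 100, max(rr) * 100),
                         tol = 1e-10)
  if (opt$minimum > max(rr) * 50)
    stop("correlation does not decay over the sampled range; cannot fit")
  list(C_L = opt$minimum,
       residual = sqrt(opt$objective / length(rr)))
}

#' Stationary-cell classification
#'
#' Cells moving slower than the migration detection limit (10 micrometres
#' per hour) are considered stationary; the threshold itself counts as
#' migrating (strictly below).
#'
#' @param speeds speeds in micrometres per hour.
#' @param threshold detection limit, micrometres per hour.
#' @return Logical vector: `TRUE` where stationary.
#' @export
classify_stationary <- function(speeds, threshold = 10) {
  stopifnot(is.numeric(speeds), all(is.finite(speeds)))
  speeds < threshold
}

#' Substrate strain energy
#'
#' Total elastic energy stored in the substrate,
#' \deqn{U = \frac{1}{2}\int T \cdot u \, dA
#'         \approx \frac{1}{2}\sum (T\cdot u)\, dx^2,}
#' with tractions in Pa, displacements in micrometres and grid spacing in
#' micrometres; the result is converted to joules
#' (1 Pa um^3 = 1e-18 J).  The one-half prefactor of the elastic-energy
#' formulation can be disabled for sensitivity checks.
#'
#' @param traction a [vector_field2d()] of kind `"traction"` (Pa).
#' @param displacement a [vector_field2d()] of kind `"displacement"`
#'   (micrometres), same grid.
#' @param half logical; include the 1/2 prefactor (default `TRUE`).
#' @return Strain energy in joules.
#' @export
strain_energy <- function(traction, displacement, half = TRUE) {
  stopifnot(inherits(traction, "vector_field2d"),
            inherits(displacement, "vector_field2d"))
  if (!all(dim(traction$u) == dim(displacement$u)))
    stop("traction and displacement grids do not match")
  if (traction$dx != displacement$dx)
    stop("traction and displacement grid spacings do not match")
  dot <- traction$u * displacement$u + traction$v * displacement$v
  U <- sum(dot, na.rm = TRUE) * traction$dx^2 * 1e-18
  if (half) U <- U / 2
  U
}
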