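## Seeded generators with known ground truth, standing in for unreleased
## microscopy data.  All randomness flows through R's RNG from the spec
## seed, so every generator is a pure function of its spec.

# mean resultant length A(kappa) = I1(kappa)/I0(kappa) of a von Mises
# distribution, computed with exponentially scaled Bessel functions.
vm_mean_resultant <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# concentration giving a prescribed mean resultant length rho in [0, 1)
vm_solve_kappa <- function(rho) {
  stopifnot(rho >= 0, rho < 1)
  if (rho == 0) return(0)
  if (rho > vm_mean_resultant(5e3)) return(Inf)
  uniroot(function(k) vm_mean_resultant(k) - rho, c(1e-8, 5e3),
          tol = 1e-12)$root
}

# Best-Fisher rejection sampler for von Mises(0, kappa) on (-pi, pi]
vm_sample <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[got + seq_len(k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  out
}

# jittered square lattice of n points in [0, L]^2 (row-major site order)
jittered_lattice <- function(n, L, jitter = 0.25) {
  m <- ceiling(sqrt(n))
  sp <- L / m
  gx <- rep(seq_len(m) - 0.5, times = m) * sp
  gy <- rep(seq_len(m) - 0.5, each = m) * sp
  x <- gx + runif(m * m, -jitter, jitter) * sp
  y <- gy + runif(m * m, -jitter, jitter) * sp
  list(x = x[seq_len(n)], y = y[seq_len(n)], all_x = x, all_y = y,
       spacing = sp)
}

# Voronoi cell of generator k among points (px, py), clipped to
# [0, L]^2: successive half-plane (perpendicular bisector) clipping of
# the bounding square against every other generator within reach.
voronoi_cell <- function(k, px, py, L) {
  poly <- matrix(c(0, 0, L, 0, L, L, 0, L), ncol = 2, byrow = TRUE)
  d2 <- (px - px[k])^2 + (py - py[k])^2
  ord <- order(d2)
  for (j in ord) {
    if (j == k) next
    # keep the side of the bisector containing generator k:
    # (p - mid) . (gen_j - gen_k) <= 0
    nx <- px[j] - px[k]; ny <- py[j] - py[k]
    if (sqrt(nx^2 + ny^2) > 2 * sqrt(max(
      (poly[, 1] - px[k])^2 + (poly[, 2] - py[k])^2))) break
    mx <- (px[j] + px[k]) / 2; my <- (py[j] + py[k]) / 2
    s <- (poly[, 1] - mx) * nx + (poly[, 2] - my) * ny
    if (all(s <= 0)) next
    nv <- nrow(poly)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nv)) {
      i2 <- if (i == nv) 1L else i + 1L
      in1 <- s[i] <= 0; in2 <- s[i2] <= 0
      if (in1) out <- rbind(out, poly[i, ])
      if (xor(in1, in2)) {
        t <- s[i] / (s[i] - s[i2])
        out <- rbind(out, poly[i, ] + t * (poly[i2, ] - poly[i, ]))
      }
    }
    poly <- out
    if (nrow(poly) < 3) break
    s <- NULL
  }
  poly
}

#' Specification of a synthetic monolayer
#'
#' @param n_cells number of cells.
#' @param target_order target nematic order parameter
#'   \eqn{S^* = E[\cos^2\theta] - 1/3}, in `[0, 2/3]`.  Note that
#'   \eqn{S^* = 0} does not mean uniformly random angles (2D-uniform
#'   angles give \eqn{S = 1/6}); the generator solves for the wrapped
#'   distribution whose expectation matches the request exactly.
#' @param mean_aspect_ratio target cell aspect ratio, >= 1.
#' @param reference_deg reference (flow) direction in degrees.
#' @param field_size side of the square field of view, micrometres.
#' @param seed RNG seed.
#' @return An object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(n_cells = 400, target_order = 0.3,
                           mean_aspect_ratio = 1.8, reference_deg = 0,
                           field_size = 400, seed = 1L) {
  stopifnot(n_cells >= 1, mean_aspect_ratio >= 1, field_size > 0)
  if (target_order < 0 || target_order > 2 / 3)
    stop("'target_order' must lie in [0, 2/3]")
  structure(list(n_cells = as.integer(n_cells),
                 target_order = target_order,
                 mean_aspect_ratio = mean_aspect_ratio,
                 reference_deg = reference_deg, field_size = field_size,
                 seed = as.integer(seed)),
            class = "monolayer_spec")
}

# orientation distribution realising E[cos^2 theta] - 1/3 = S*:
# theta = mu + psi/2 with psi ~ von Mises(0, kappa) (nematic symmetry),
# so E[cos 2 theta] = A(kappa) cos(2 mu) and S = 1/6 + A(kappa) cos(2mu)/2.
monolayer_angle_params <- function(S_star) {
  tgt <- 2 * S_star - 1 / 3  # required A(kappa) * cos(2 mu)
  mu <- if (tgt >= 0) 0 else 90
  list(mu = mu, kappa = vm_solve_kappa(min(abs(tgt), 1 - 1e-12)),
       degenerate = abs(tgt) >= 1 - 1e-9)
}

#' Generate a synthetic monolayer of cell outlines
#'
#' Voronoi-tessellates a jittered lattice and gives every cell a
#' prescribed orientation and aspect ratio: cell i's polygon is first
#' whitened (its own moment ellipse mapped to a circle, area preserved)
#' and then stretched by \eqn{\sqrt{AR}} along an angle \eqn{\theta_i}
#' drawn from a von Mises distribution on \eqn{2\theta} whose
#' concentration is solved so that
#' \eqn{E[\cos^2\theta] - 1/3 = S^*}.  Because the equivalent-ellipse fit
#' is moment-based, the fitted orientation of each cell equals
#' \eqn{\theta_i} exactly and the achieved order differs from the target
#' only by sampling error.
#'
#' @param spec a [monolayer_spec()].
#' @return A list with `outlines` (list of [cell_outline()]),
#'   `true_angles` (degrees), `true_aspect_ratios` and the `spec`.
#' @export
make_monolayer <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  set.seed(spec$seed)
  L <- spec$field_size
  lat <- jittered_lattice(spec$n_cells, L)
  ap <- monolayer_angle_params(spec$target_order)
  psi <- vm_sample(spec$n_cells, ap$kappa)
  theta <- (ap$mu + psi * 90 / pi) + spec$reference_deg  # degrees
  ar <- spec$mean_aspect_ratio *
    exp(rnorm(spec$n_cells, 0, 0.08))  # mild cell-to-cell variability
  ar <- pmax(ar, 1 + 1e-6)
  outlines <- vector("list", spec$n_cells)
  for (k in seq_len(spec$n_cells)) {
    poly <- voronoi_cell(k, lat$all_x, lat$all_y, L)
    m <- polygon_moments(poly)
    e <- eigen(m$cov, symmetric = TRUE)
    # whitening: map the moment ellipse to a circle of equal area
    W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors) *
      sqrt(sqrt(prod(e$values)))
    a <- theta[k] * pi / 180
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    Sm <- Rm %*% diag(c(sqrt(ar[k]), 1 / sqrt(ar[k]))) %*% t(Rm)
    Tm <- Sm %*% W
    ctr <- matrix(m$centroid, nrow(poly), 2, byrow = TRUE)
    v <- (poly - ctr) %*% t(Tm) + ctr
    outlines[[k]] <- cell_outline(v, cell_id = k)
  }
  list(outlines = outlines, true_angles = theta %% 180,
       true_aspect_ratios = ar, spec = spec)
}

#' Specification of synthetic PCP point sets
#'
#' @param n_cells number of nuclei.
#' @param polarization_bias target mean PCP index
#'   \eqn{\beta = E[\cos\phi]}, in `[-1, 1]`; negative values model the
#'   physiological upstream polarisation.
#' @param angular_noise_kappa optional von Mises concentration of the
#'   polarity angles.  When `NULL` (default) the concentration is solved
#'   from `polarization_bias` with the mean angle on the flow axis; when
#'   given, the mean angle is rotated off-axis instead to keep
#'   \eqn{E[\cos\phi] = \beta} (requires
#'   \eqn{|\beta| \le A(\kappa)}).
#' @param golgi_fragments_per_cell detected Golgi fragments per cell.
#' @param fragment_scatter fragment scatter radius as a fraction of the
#'   nucleus spacing (0 = fragments exactly at the polarity point).
#' @param flow_deg flow direction in degrees.
#' @param field_size field of view side, micrometres.
#' @param seed RNG seed.
#' @return An object of class `pcp_spec`.
#' @export
pcp_spec <- function(n_cells = 400, polarization_bias = -0.5,
                     angular_noise_kappa = NULL,
                     golgi_fragments_per_cell = 3,
                     fragment_scatter = 0.05, flow_deg = 0,
                     field_size = 400, seed = 1L) {
  if (abs(polarization_bias) > 1)
    stop("'polarization_bias' must lie in [-1, 1]")
  stopifnot(n_cells >= 1, golgi_fragments_per_cell >= 1,
            fragment_scatter >= 0)
  structure(list(n_cells = as.integer(n_cells),
                 polarization_bias = polarization_bias,
                 angular_noise_kappa = angular_noise_kappa,
                 golgi_fragments_per_cell =
                   as.integer(golgi_fragments_per_cell),
                 fragment_scatter = fragment_scatter, flow_deg = flow_deg,
                 field_size = field_size, seed = as.integer(seed)),
            class = "pcp_spec")
}

#' Generate nucleus and Golgi point sets with known polarity bias
#'
#' Nuclei sit on a jittered lattice; each cell's true polarity angle
#' \eqn{\phi_i} (vs. flow) is drawn from a von Mises distribution
#' calibrated so that \eqn{E[\cos\phi] = \beta}, and
#' `golgi_fragments_per_cell` fragments are scattered isotropically about
#' the displaced polarity point.
#'
#' @param spec a [pcp_spec()].
#' @return A list with `nuclei` and `golgi` ([point_set()]s),
#'   `true_phi` (degrees vs flow) and the `spec`.
#' @export
make_pcp_points <- function(spec) {
  stopifnot(inherits(spec, "pcp_spec"))
  set.seed(spec$seed)
  lat <- jittered_lattice(spec$n_cells, spec$field_size, jitter = 0.15)
  beta <- spec$polarization_bias
  if (is.null(spec$angular_noise_kappa)) {
    mu <- if (beta >= 0) 0 else pi
    kappa <- vm_solve_kappa(min(abs(beta), 1 - 1e-12))
    if (abs(beta) >= 1 - 1e-9) kappa <- Inf
  } else {
    kappa <- spec$angular_noise_kappa
    rho <- vm_mean_resultant(kappa)
    if (abs(beta) > rho + 1e-12)
      stop("|polarization_bias| exceeds the mean resultant of ",
           "'angular_noise_kappa'; unreachable bias")
    mu <- acos(beta / rho)
  }
  phi <- mu + vm_sample(spec$n_cells, kappa)  # radians vs flow
  d0 <- 0.3 * lat$spacing
  aflow <- spec$flow_deg * pi / 180
  px <- lat$x + d0 * cos(aflow + phi)
  py <- lat$y + d0 * sin(aflow + phi)
  nfrag <- spec$golgi_fragments_per_cell
  sig <- spec$fragment_scatter * lat$spacing
  gx <- rep(px, each = nfrag) + rnorm(spec$n_cells * nfrag, 0, sig)
  gy <- rep(py, each = nfrag) + rnorm(spec$n_cells * nfrag, 0, sig)
  list(nuclei = point_set(lat$x, lat$y, label = "nucleus"),
       golgi = point_set(gx, gy, label = "golgi"),
       true_phi = (phi * 180 / pi) %% 360, spec = spec)
}

#' Specification of a correlated random vector field
#'
#' @param grid_n grid nodes per side, >= 32.
#' @param dx grid spacing, micrometres.
#' @param lambda target exponential correlation length, micrometres;
#'   must be at least `2 * dx` to be resolvable.
#' @param rms target root-mean-square vector magnitude.
#' @param seed RNG seed.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(grid_n = 256, dx = 2, lambda = 20, rms = 20,
                       seed = 1L) {
  stopifnot(grid_n >= 32, dx > 0, rms >= 0)
  if (lambda < 2 * dx)
    stop("'lambda' below 2 * dx cannot be resolved on the grid")
  structure(list(grid_n = as.integer(grid_n), dx = dx, lambda = lambda,
                 rms = rms, seed = as.integer(seed)),
            class = "field_spec")
}

# one scalar Gaussian field with isotropic exp(-r/lambda) correlation,
# synthesised by circulant embedding: the eigenvalues of the wrapped
# (minimum-image) exponential covariance on the periodic grid are its 2D
# DFT, so filtering white noise with their square root realises that
# covariance exactly (up to clipping of slightly negative eigenvalues).
correlated_scalar_field <- function(n, dx, lambda) {
  d1 <- pmin(0:(n - 1), n - 0:(n - 1)) * dx
  dmat <- sqrt(outer(d1^2, d1^2, "+"))
  ev <- Re(stats::fft(exp(-dmat / lambda)))
  ev[ev < 0] <- 0
  amp <- sqrt(ev)
  w <- matrix(rnorm(n * n), n, n)
  Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (n * n)
}

#' Generate a Gaussian random velocity field with known correlation length
#'
#' Each component is an independent Gaussian random field with isotropic
#' exponential spatial correlation \eqn{e^{-r/\lambda}}, synthesised by
#' circulant embedding on the periodic grid; the pair is jointly rescaled
#' so the empirical rms vector magnitude matches the request exactly.
#'
#' @param spec a [field_spec()].
#' @return A [vector_field2d()] of kind `"velocity"` with attribute
#'   `"lambda_true"`.
#' @export
make_correlated_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  u <- correlated_scalar_field(spec$grid_n, spec$dx, spec$lambda)
  v <- correlated_scalar_field(spec$grid_n, spec$dx, spec$lambda)
  u <- u - mean(u); v <- v - mean(v)
  s <- sqrt(mean(u^2 + v^2))
  if (s > 0 && spec$rms > 0) {
    u <- u * spec$rms / s; v <- v * spec$rms / s
  } else { u[] <- 0; v[] <- 0 }
  f <- vector_field2d(u, v, spec$dx, kind = "velocity")
  attr(f, "lambda_true") <- spec$lambda
  f
}

#' Generate a traction/displacement pair with closed-form strain energy
#'
#' Draws a smooth random traction field (rms `amplitude`, in Pa) and sets
#' the displacement proportional to it, \eqn{u = c\,T} with a known
#' compliance c (micrometres per Pa), so the strain energy
#' \eqn{U = \frac{1}{2}\sum c |T|^2 dx^2} is known in closed form.
#'
#' @param grid_n grid nodes per side.
#' @param dx grid spacing, micrometres.
#' @param amplitude rms traction, Pa.
#' @param seed RNG seed.
#' @param compliance scalar c in micrometres per Pa.
#' @param lambda spatial correlation length of the traction pattern,
#'   micrometres.
#' @return A list with `traction`, `displacement` ([vector_field2d()]s)
#'   and `strain_energy_true` in joules.
#' @export
make_traction_pair <- function(grid_n = 64, dx = 5, amplitude = 100,
                               seed = 1L, compliance = 0.01,
                               lambda = 30) {
  stopifnot(grid_n >= 32, amplitude >= 0, compliance > 0)
  f <- make_correlated_field(field_spec(grid_n, dx, lambda, amplitude,
                                        seed))
  traction <- vector_field2d(f$u, f$v, dx, kind = "traction")
  displacement <- vector_field2d(compliance * f$u, compliance * f$v, dx,
                                 kind = "displacement")
  U <- 0.5 * compliance * sum(f$u^2 + f$v^2) * dx^2 * 1e-18
  list(traction = traction, displacement = displacement,
       strain_energy_true = U)
}
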