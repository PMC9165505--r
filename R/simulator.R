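#' Simulation configuration for the lattice Q-tensor model
#'
#' Collects every knob of the 2D Landau-de Gennes relaxation: lattice
#' geometry, Landau bulk coefficients, elastic constant, driving field,
#' time stepping, dielectric model and the rod-like/disk-like mixture.
#'
#' The bulk free-energy density per site is
#' \deqn{f = \frac{A}{2}\mathrm{tr}Q^2 + \frac{B}{3}\mathrm{tr}Q^3 +
#'   \frac{C}{4}(\mathrm{tr}Q^2)^2 + \frac{R_1}{2}|\nabla Q|^2 -
#'   \frac{\Delta\varepsilon(\omega)}{2}\,E^\top Q E,}
#' with the cubic sign \eqn{B = -1} on rod-like (healthy, flow-responsive)
#' sites and \eqn{B = +1} on disk-like (senescent) sites.  Defaults:
#' \eqn{A = -0.3}, \eqn{C = 2.1}, \eqn{R_1 = 1}, \eqn{E = (1, 0, 0)},
#' \eqn{\Gamma = 1}, \eqn{dt = 0.05}; the quartic coefficient is chosen so
#' the zero-field uniaxial minimiser \eqn{S^* \approx 0.60} stays inside
#' the physical range of the scalar order parameter
#' (\eqn{S = \langle\cos^2\theta\rangle - 1/3 \in [-1/3, 2/3]}).
#'
#' @param grid_nx,grid_ny lattice dimensions (sites); >= 1 (1x1 reduces the
#'   dynamics to a single-site ODE, useful for verification).
#' @param dx lattice spacing, model units.
#' @param A_coef,C_coef Landau quadratic and quartic coefficients; `C_coef`
#'   must be positive for a bounded free energy.
#' @param B_rod,B_disk cubic coefficient of rod-like / disk-like sites.
#' @param R1 one-constant elastic modulus.
#' @param E_vec field vector `c(Ex, Ey, Ez)`; `Ez` must be 0 (planar model).
#' @param dt forward-Euler time step, model time units.
#' @param Gamma kinetic constant of the gradient flow.
#' @param dielectric a [dielectric_params()] object mapping the drive
#'   frequency to the coupling \eqn{\Delta\varepsilon(\omega)}.
#' @param seed RNG seed controlling the random initial condition and the
#'   placement of disk-like sites.
#' @param disk_fraction fraction in `[0, 1]` of disk-like (senescent) sites.
#' @param coupling_mode `"full"` (elastic bonds between all neighbours) or
#'   `"decoupled"` (bonds between unlike species removed).
#' @param S_init initial per-site scalar order of the random state.
#' @param boundary `"periodic"` or `"neumann"`.
#' @param trace_every interval (model time) between scalar trace records.
#' @param heatmap_every interval (model time) between order-parameter
#'   heatmap snapshots.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_nx = 64, grid_ny = 64, dx = 1,
                       A_coef = -0.3, C_coef = 2.1,
                       B_rod = -1, B_disk = 1, R1 = 1,
                       E_vec = c(1, 0, 0), dt = 0.05, Gamma = 1,
                       dielectric = dielectric_params(), seed = 1L,
                       disk_fraction = 0, coupling_mode = c("full",
                                                            "decoupled"),
                       S_init = 0.05, boundary = c("periodic", "neumann"),
                       trace_every = 1, heatmap_every = 50) {
  coupling_mode <- match.arg(coupling_mode)
  boundary <- match.arg(boundary)
  stopifnot(grid_nx >= 1, grid_ny >= 1, dx > 0, dt > 0, Gamma > 0, R1 > 0,
            length(E_vec) == 3, is.numeric(E_vec),
            trace_every > 0, heatmap_every > 0)
  if (C_coef <= 0) stop("'C_coef' must be positive (bounded free energy)")
  if (disk_fraction < 0 || disk_fraction > 1)
    stop("'disk_fraction' must lie in [0, 1]")
  if (E_vec[3] != 0) stop("planar model: 'E_vec[3]' (Ez) must be 0")
  stopifnot(inherits(dielectric, "dielectric_params"))
  structure(
    list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
         dx = dx, A_coef = A_coef, C_coef = C_coef, B_rod = B_rod,
         B_disk = B_disk, R1 = R1, E_vec = as.numeric(E_vec), dt = dt,
         Gamma = Gamma, dielectric = dielectric, seed = as.integer(seed),
         disk_fraction = disk_fraction, coupling_mode = coupling_mode,
         S_init = S_init, boundary = boundary, trace_every = trace_every,
         heatmap_every = heatmap_every),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Q-tensor simulation config: %d x %d lattice, dt = %g\n",
              x$grid_nx, x$grid_ny, x$dt))
  cat(sprintf("  A = %g, C = %g, B(rod/disk) = %g/%g, R1 = %g, Gamma = %g\n",
              x$A_coef, x$C_coef, x$B_rod, x$B_disk, x$R1, x$Gamma))
  cat(sprintf("  E = [%g, %g, %g], disk fraction = %g (%s coupling), %s BC\n",
              x$E_vec[1], x$E_vec[2], x$E_vec[3], x$disk_fraction,
              x$coupling_mode, x$boundary))
  invisible(x)
}

new_qtensor_field <- function(q, b, time, config) {
  structure(list(q = q, b_site = b, time = time,
                 dx = config$dx, boundary = config$boundary),
            class = "qtensor_field")
}

#' Random weakly nematic initial state
#'
#' Builds a per-site uniaxial Q tensor from independent uniformly random
#' in-plane director angles at small initial order `S_init`, and assigns
#' `round(disk_fraction * N)` disk-like sites uniformly at random.  The
#' same seed reproduces the field exactly.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `qtensor_field` with elements `q`
#'   (`nx x ny x 5` array of qxx, qxy, qxz, qyy, qyz), `b_site`
#'   (matrix of cubic signs) and `time`.
#' @export
init_random <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nx <- config$grid_nx; ny <- config$grid_ny; N <- nx * ny
  set.seed(config$seed)
  theta <- runif(N, 0, pi)
  S <- config$S_init
  q <- array(0, dim = c(nx, ny, 5))
  # uniaxial in-plane: Q = S (n n^T - I/3), n = (cos, sin, 0)
  q[, , 1] <- matrix(S * (cos(theta)^2 - 1 / 3), nx, ny)
  q[, , 2] <- matrix(S * cos(theta) * sin(theta), nx, ny)
  q[, , 4] <- matrix(S * (sin(theta)^2 - 1 / 3), nx, ny)
  b <- matrix(config$B_rod, nx, ny)
  n_disk <- round(config$disk_fraction * N)
  if (n_disk > 0) b[sample.int(N, n_disk)] <- config$B_disk
  new_qtensor_field(q, b, 0, config)
}

#' Reconstruct the full 3x3 tensor at one lattice site
#'
#' @param field a `qtensor_field`.
#' @param i,j lattice indices.
#' @return A symmetric traceless 3x3 matrix.
#' @export
qtensor_at <- function(field, i, j) {
  qc <- field$q[i, j, ]
  matrix(c(qc[1], qc[2], qc[3],
           qc[2], qc[4], qc[5],
           qc[3], qc[5], -qc[1] - qc[4]), 3, 3)
}

#' Total Landau-de Gennes free energy
#'
#' Sums bulk, elastic (forward-difference bonds) and dielectric
#' contributions over the lattice; the dielectric coupling is
#' \eqn{\Delta\varepsilon(\omega)} evaluated from the config's dielectric
#' model.  This discretisation is the exact Lyapunov functional of
#' [step()]: at fixed \eqn{\omega} the energy is non-increasing along the
#' relaxation.
#'
#' @param field a `qtensor_field`.
#' @param config a [sim_config()] object.
#' @param omega drive angular frequency, \eqn{s^{-1}}.
#' @return Total free energy (model units).
#' @export
free_energy <- function(field, config, omega) {
  stopifnot(inherits(field, "qtensor_field"), inherits(config, "sim_config"))
  deps <- delta_eps(config$dielectric, omega)
  cpp_free_energy(field$q, field$b_site, config$A_coef, config$C_coef,
                  config$R1, config$dx, deps, config$E_vec[1],
                  config$E_vec[2], config$boundary == "neumann",
                  config$coupling_mode == "decoupled")
}

#' Advance the relaxation dynamics
#'
#' Forward-Euler steps of the gradient flow
#' \eqn{\partial_t Q = \Gamma H}, where \eqn{H} is the symmetric traceless
#' molecular field (negative variational derivative of the free energy).
#' The 5-component storage keeps Q exactly symmetric and traceless.
#'
#' @inheritParams free_energy
#' @param nsteps number of Euler steps to take.
#' @return The updated `qtensor_field`.
#' @export
step <- function(field, config, omega, nsteps = 1) {
  stopifnot(inherits(field, "qtensor_field"), inherits(config, "sim_config"))
  deps <- delta_eps(config$dielectric, omega)
  q <- cpp_step_n(field$q, field$b_site, as.integer(nsteps), config$A_coef,
                  config$C_coef, config$R1, config$dx, config$dt,
                  config$Gamma, deps, config$E_vec[1], config$E_vec[2],
                  config$boundary == "neumann",
                  config$coupling_mode == "decoupled")
  field$q <- q
  field$time <- field$time + nsteps * config$dt
  field
}

#' Per-site scalar order parameter and director
#'
#' Eigen-decomposes the tensor at every site.  The reported scalar order is
#' \eqn{S = \frac{3}{2}\lambda}, with \eqn{\lambda} the largest-magnitude
#' eigenvalue, the convention under which a uniaxial
#' \eqn{Q = S(nn^\top - I/3)} round-trips exactly; disk-like (oblate)
#' states therefore carry negative S.  The director is the corresponding
#' eigenvector, reported as an angle (degrees) folded to `[0, 90]` against
#' the x (field) axis; it is `NA` where the tensor is degenerate (S = 0)
#' or the distinguished axis points out of plane.
#'
#' @param field a `qtensor_field`.
#' @return A list with matrices `S` and `angle` (degrees, possibly `NA`).
#' @export
site_order <- function(field) {
  stopifnot(inherits(field, "qtensor_field"))
  if (max(abs(field$q[, , c(3, 5)])) > 1e-12) {
    # general (out-of-plane) tensors: fall back to dense eigendecomposition
    nx <- dim(field$q)[1]; ny <- dim(field$q)[2]
    S <- matrix(0, nx, ny); ang <- matrix(NA_real_, nx, ny)
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      e <- eigen(qtensor_at(field, i, j), symmetric = TRUE)
      k <- which.max(abs(e$values))
      S[i, j] <- 1.5 * e$values[k]
      v <- e$vectors[, k]
      if (abs(e$values[k]) > 1e-14 && sqrt(v[1]^2 + v[2]^2) > 1e-8) {
        th <- atan2(v[2], v[1]) * 180 / pi
        th <- th %% 180
        ang[i, j] <- min(th, 180 - th)
      }
    }
    return(list(S = S, angle = ang))
  }
  cpp_site_order(field$q, field$b_site)
}

#' Lattice-mean director angle
#'
#' Angle (degrees, folded to `[0, 90]` vs the x axis) of the principal
#' in-plane eigenvector of the lattice-averaged Q tensor — the standard
#' nematic average, insensitive to the head-tail ambiguity of individual
#' directors.
#'
#' @param field a `qtensor_field`.
#' @return Angle in degrees, or `NA` for a degenerate mean tensor.
#' @export
mean_director_angle <- function(field) {
  m1 <- mean(field$q[, , 1]); m2 <- mean(field$q[, , 2])
  m4 <- mean(field$q[, , 4])
  if (sqrt(0.25 * (m1 - m4)^2 + m2^2) < 1e-14) return(NA_real_)
  abs(0.5 * atan2(2 * m2, m1 - m4) * 180 / pi)
}

omega_preset <- function(dielectric, which = c("omega_0", "omega_L",
                                               "omega_H")) {
  switch(match.arg(which),
         omega_0 = zero_crossing(dielectric),
         omega_L = 1.1,
         omega_H = 6.3)
}

#' Canned frequency-switch protocols
#'
#' Returns the schedule (piecewise-constant drive frequency) of the named
#' protocol as a data frame with columns `omega` and `end_time`:
#' \describe{
#'   \item{fig3a}{equilibrate at \eqn{\omega_0} to t = 100, then
#'     \eqn{\omega_L} (parallel alignment) to t = 250.}
#'   \item{fig3b}{as fig3a but switching to \eqn{\omega_H} (perpendicular).}
#'   \item{fig4a}{\eqn{\omega_0} to 100, \eqn{\omega_L} to 250, then
#'     \eqn{\omega_H} to 400 (parallel state forced perpendicular).}
#'   \item{fig4b}{mirror of fig4a (\eqn{\omega_H} then \eqn{\omega_L}).}
#' }
#'
#' @param name protocol name.
#' @param dielectric a [dielectric_params()] object (supplies
#'   \eqn{\omega_0}).
#' @param omega_L,omega_H low / high drive frequencies, \eqn{s^{-1}}.
#' @return A data frame schedule for [run_protocol()].
#' @export
protocol_schedule <- function(name = c("fig3a", "fig3b", "fig4a", "fig4b"),
                              dielectric = dielectric_params(),
                              omega_L = 1.1, omega_H = 6.3) {
  name <- match.arg(name)
  w0 <- zero_crossing(dielectric)
  switch(name,
    fig3a = data.frame(omega = c(w0, omega_L), end_time = c(100, 250)),
    fig3b = data.frame(omega = c(w0, omega_H), end_time = c(100, 250)),
    fig4a = data.frame(omega = c(w0, omega_L, omega_H),
                       end_time = c(100, 250, 400)),
    fig4b = data.frame(omega = c(w0, omega_H, omega_L),
                       end_time = c(100, 250, 400)))
}

#' Run a frequency-switch relaxation protocol
#'
#' Initialises a random field from the config seed and relaxes it under a
#' piecewise-constant drive frequency, recording the lattice-mean scalar
#' order, total free energy and mean director angle at `trace_every`
#' intervals, plus per-site order heatmaps at `heatmap_every` intervals.
#'
#' @param config a [sim_config()] object.
#' @param schedule either a protocol name accepted by
#'   [protocol_schedule()] or a data frame with columns `omega` and
#'   `end_time` (strictly increasing end times).
#' @param field optional starting `qtensor_field`; defaults to
#'   [init_random()] from the config seed.
#' @return An object of class `sim_trace`: a list with `trace` (data frame
#'   `time`, `mean_S`, `free_energy`, `director_angle`), `heatmap_times`,
#'   `heatmaps` (list of per-site S matrices), the final `field`, the
#'   `schedule` and the `config`.
#' @export
run_protocol <- function(config, schedule = "fig3a", field = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(schedule))
    schedule <- protocol_schedule(schedule, config$dielectric)
  if (!is.data.frame(schedule) || nrow(schedule) == 0 ||
      !all(c("omega", "end_time") %in% names(schedule)))
    stop("'schedule' must be a non-empty data frame (omega, end_time)")
  if (is.null(field)) field <- init_random(config)
  t0 <- field$time
  bounds <- c(t0, schedule$end_time)
  if (any(diff(bounds) <= 0))
    stop("schedule end times must be strictly increasing")
  seg_steps <- as.integer(round(diff(bounds) / config$dt))
  seg_deps <- delta_eps(config$dielectric, schedule$omega)
  res <- cpp_run(field$q, field$b_site, config$A_coef, config$C_coef,
                 config$R1, config$dx, config$dt, config$Gamma,
                 config$E_vec[1], config$E_vec[2], seg_deps, seg_steps,
                 max(1L, as.integer(round(config$trace_every / config$dt))),
                 max(1L, as.integer(round(config$heatmap_every / config$dt))),
                 t0, config$boundary == "neumann",
                 config$coupling_mode == "decoupled")
  field$q <- res$q
  field$time <- t0 + sum(seg_steps) * config$dt
  structure(
    list(trace = data.frame(time = res$time, mean_S = res$mean_S,
                            free_energy = res$free_energy,
                            director_angle = res$director_angle),
         heatmap_times = res$heatmap_times, heatmaps = res$heatmaps,
         field = field, schedule = schedule, config = config),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  tr <- x$trace
  cat(sprintf(
    "Q-tensor relaxation trace: %d records over t = [%g, %g]\n",
    nrow(tr), min(tr$time), max(tr$time)))
  n <- nrow(tr)
  cat(sprintf("  final mean S = %.4f, director angle = %.2f deg, F = %.4g\n",
              tr$mean_S[n], tr$director_angle[n], tr$free_energy[n]))
  invisible(x)
}

#' @export
plot.sim_trace <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$time, tr$mean_S, type = "l", xlab = "time",
                 ylab = "mean S", ...)
  graphics::plot(tr$time, tr$free_energy, type = "l", xlab = "time",
                 ylab = "free energy", ...)
  invisible(x)
}

#' Steady-state mean order of a trace
#'
#' Average of the lattice-mean scalar order over the trailing `window`
#' model-time units of a trace.
#'
#' @param trace a `sim_trace`.
#' @param window trailing window length, model time units.
#' @return Numeric scalar.
#' @export
steady_state_order <- function(trace, window = 10) {
  tr <- trace$trace
  mean(tr$mean_S[tr$time >= max(tr$time) - window])
}

#' Sweep the senescent (disk-like) fraction
#'
#' For each fraction p the lattice is equilibrated at \eqn{\omega_0} (zero
#' coupling) and then driven at `omega`, and the steady-state lattice-mean
#' order is recorded over `replicates` seeds.  With full elastic coupling
#' the steady order decreases with p; in `"decoupled"` mode the two species
#' relax independently, so the mean order is the population-weighted
#' mixture of the pure-species values.
#'
#' @param config a [sim_config()] template (its `disk_fraction` and `seed`
#'   are overridden per run).
#' @param fractions disk fractions p in `[0, 1]`.
#' @param omega drive frequency after equilibration, \eqn{s^{-1}}.
#' @param replicates seeds per fraction.
#' @param t_equil,t_end equilibration end time and total run time.
#' @return A data frame with columns `p`, `mean_S`, `sd_S`, `n`.
#' @export
senescence_sweep <- function(config, fractions = c(0, 0.3, 0.7, 1),
                             omega = 1.1, replicates = 3,
                             t_equil = 100, t_end = 250) {
  stopifnot(all(fractions >= 0 & fractions <= 1), replicates >= 1)
  w0 <- zero_crossing(config$dielectric)
  out <- lapply(fractions, function(p) {
    ss <- vapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$disk_fraction <- p
      cfg$seed <- config$seed + 1000L * (r - 1L)
      sched <- data.frame(omega = c(w0, omega),
                          end_time = c(t_equil, t_end))
      steady_state_order(run_protocol(cfg, sched))
    }, numeric(1))
    data.frame(p = p, mean_S = mean(ss),
               sd_S = if (replicates > 1) sd(ss) else NA_real_,
               n = replicates)
  })
  do.call(rbind, out)
}
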