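# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: dense 3x3 matrix algebra instead of the packed
# 5-component kernel, rasterised image moments instead of exact polygon
# moments, quadratic-time searches instead of FFTs.

# scalar bulk free-energy density of a uniaxial state,
# from tr(Q^2) = 2S^2/3 and tr(Q^3) = 2S^3/9
f_bulk_scalar <- function(S, A, B, C) {
  A * S^2 / 3 + 2 * B * S^3 / 27 + C * S^4 / 9
}

# positive uniaxial minimiser of the scalar bulk energy
bulk_minimiser <- function(A, B, C) {
  optimize(function(S) f_bulk_scalar(S, A, B, C), c(1e-6, 1.5),
           tol = 1e-12)$minimum
}

# single-site gradient-flow integrator in dense 3x3 matrix form
ode_oracle_step <- function(Q, A, B, C, deps, E, dt, gamma) {
  I3 <- diag(3)
  tr2 <- sum(diag(Q %*% Q))
  G <- A * Q + B * (Q %*% Q - I3 * tr2 / 3) + C * Q * tr2
  hf <- deps / 2 * (outer(E, E) - I3 * sum(E^2) / 3)
  Q + dt * gamma * (-G + hf)
}

# uniaxial Q from scalar order S and in-plane director angle (radians)
uniaxial_Q <- function(S, angle) {
  n <- c(cos(angle), sin(angle), 0)
  S * (outer(n, n) - diag(3) / 3)
}

# pack a list of per-site 3x3 tensors (single site here) into the field
# structure used by the package
single_site_field <- function(Q, config, b = config$B_rod) {
  q <- array(0, dim = c(1, 1, 5))
  q[1, 1, ] <- c(Q[1, 1], Q[1, 2], Q[1, 3], Q[2, 2], Q[2, 3])
  structure(list(q = q, b_site = matrix(b, 1, 1), time = 0,
                 dx = config$dx, boundary = config$boundary),
            class = "qtensor_field")
}

# rasterised image-moment ellipse oracle: fills the polygon on a fine
# pixel grid and computes moments of the filled mask
raster_moments <- function(v, res = 400) {
  xr <- range(v[, 1]); yr <- range(v[, 2])
  pad <- 0.02 * max(diff(xr), diff(yr))
  xs <- seq(xr[1] - pad, xr[2] + pad, length.out = res)
  ys <- seq(yr[1] - pad, yr[2] + pad, length.out = res)
  px <- rep(xs, times = res); py <- rep(ys, each = res)
  # even-odd ray casting
  inside <- rep(FALSE, length(px))
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  x <- px[inside]; y <- py[inside]
  cov <- cbind(c(mean(x^2) - mean(x)^2, mean(x * y) - mean(x) * mean(y)),
               c(mean(x * y) - mean(x) * mean(y), mean(y^2) - mean(y)^2))
  e <- eigen(cov, symmetric = TRUE)
  list(centroid = c(mean(x), mean(y)),
       aspect = sqrt(e$values[1] / e$values[2]),
       angle = (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180)
}

# random simple (star-shaped) polygon around the origin; jittered regular
# angles keep every angular gap below pi, which guarantees simplicity
random_polygon <- function(nv = 12, r_mean = 10, irregular = 0.5) {
  ang <- 2 * pi * (seq_len(nv) - 1 + 0.9 * runif(nv)) / nv
  r <- r_mean * (1 + irregular * (runif(nv) - 0.5))
  cbind(r * cos(ang), r * sin(ang))
}

# brute-force nearest-nucleus assignment with the lowest-id tie rule
nn_assign_oracle <- function(nuclei, golgi) {
  out <- setNames(rep(list(integer(0)), nrow(nuclei)),
                  as.character(nuclei$id))
  for (g in seq_len(nrow(golgi))) {
    best <- Inf; best_id <- NA
    for (k in seq_len(nrow(nuclei))) {
      d <- (nuclei$x[k] - golgi$x[g])^2 + (nuclei$y[k] - golgi$y[g])^2
      if (d < best || (d == best && nuclei$id[k] < best_id)) {
        best <- d; best_id <- nuclei$id[k]
      }
    }
    key <- as.character(best_id)
    out[[key]] <- c(out[[key]], g)
  }
  out
}

# small standard configs for simulator tests
tiny_config <- function(...) {
  sim_config(grid_nx = 16, grid_ny = 16, ...)
}
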