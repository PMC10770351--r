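#' Prestressed elastic medium
#'
#' Material description for the reduced two-dimensional shear-wave model.
#' Out-of-plane displacement u(x, z, t) obeys
#' \deqn{\rho u_{tt} = \mu (u_{xx} + u_{zz}) + \beta \sigma u_{xx}
#'       - \rho \gamma u_t + f(x, z, t)}
#' so the lateral (x, cranial-caudal) propagation speed is
#' \eqn{c_{eff} = \sqrt{(\mu + \beta\sigma)/\rho}}: squared wave speed is
#' linear in the axial tensile prestress, the acoustoelastic relationship the
#' tensography calibration exploits. `beta = 1` is the ideal stretched-
#' membrane coupling; smaller values emulate stiffer tissue models where
#' tension converts to wave speed less efficiently.
#'
#' @param rho Density, kg/m^3.
#' @param mu Shear modulus, Pa. The default gives a relaxed shear-wave speed
#'   of 1.39 m/s at rho = 1000.
#' @param sigma Axial tensile prestress, Pa (>= 0).
#' @param beta Dimensionless acoustoelastic coupling (>= 0).
#' @param gamma Viscous damping rate, 1/s (>= 0).
#' @return Object of class `elastic_medium`.
#' @export
elastic_medium <- function(rho = 1000, mu = 1932.1, sigma = 0,
                           beta = 1, gamma = 0) {
  check_scalar(rho, "rho", lower = 0, strict_lower = TRUE)
  check_scalar(mu, "mu", lower = 0, strict_lower = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(beta, "beta", lower = 0)
  check_scalar(gamma, "gamma", lower = 0)
  m <- structure(list(rho = rho, mu = mu, sigma = sigma, beta = beta,
                      gamma = gamma),
                 class = "elastic_medium")
  if (!is.finite(effective_speed(m)) || effective_speed(m) <= 0)
    stop("invalid medium: effective lateral speed is not positive and finite")
  m
}

#' Effective lateral shear-wave speed of a prestressed medium
#'
#' @param medium An [elastic_medium()].
#' @return \eqn{\sqrt{(\mu + \beta\sigma)/\rho}} in m/s.
#' @export
effective_speed <- function(medium) {
  stopifnot(inherits(medium, "elastic_medium"))
  sqrt((medium$mu + medium$beta * medium$sigma) / medium$rho)
}

#' @export
print.elastic_medium <- function(x, ...) {
  cat(sprintf(paste0("Prestressed elastic medium: rho = %g kg/m^3, ",
                     "mu = %g Pa, sigma = %g Pa, beta = %g, gamma = %g /s\n"),
              x$rho, x$mu, x$sigma, x$beta, x$gamma))
  cat(sprintf("  effective lateral speed: %.4g m/s\n", effective_speed(x)))
  invisible(x)
}

#' Simulation grid
#'
#' Uniform finite-difference grid for the reduced wave model. x spans
#' `[-extent_x/2, extent_x/2]` (lateral, cranial-caudal; the push axis at
#' x = 0), z spans `[0, extent_z]` (depth). Graded-damping sponge layers of
#' `sponge_width` nodes absorb outgoing waves at all four edges.
#'
#' @param extent_x,extent_z Physical extents in m.
#' @param h Node spacing in m (default 0.2 mm, matching the region-of-
#'   interest element size of the reference finite-element setup).
#' @param duration Simulated propagation period in s (default 2.3 ms).
#' @param cfl_safety Courant safety factor in (0, 1).
#' @param sponge_width Absorbing-layer width in nodes.
#' @return Object of class `sim_grid`.
#' @export
sim_grid <- function(extent_x = 30e-3, extent_z = 20e-3, h = 0.2e-3,
                     duration = 2.3e-3, cfl_safety = 0.9, sponge_width = 20) {
  check_scalar(extent_x, "extent_x", lower = 0, strict_lower = TRUE)
  check_scalar(extent_z, "extent_z", lower = 0, strict_lower = TRUE)
  check_scalar(h, "h", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(cfl_safety, "cfl_safety", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(sponge_width, "sponge_width", lower = 0)
  structure(list(extent_x = extent_x, extent_z = extent_z, h = h,
                 duration = duration, cfl_safety = cfl_safety,
                 sponge_width = as.integer(sponge_width)),
            class = "sim_grid")
}

# node coordinates; x symmetric about 0 so a centred beam sees a mirror grid
grid_axes <- function(grid) {
  nx <- round(grid$extent_x / grid$h) + 1L
  nz <- round(grid$extent_z / grid$h) + 1L
  list(x = (seq_len(nx) - (nx + 1L) / 2) * grid$h,
       z = (seq_len(nz) - 1L) * grid$h)
}

#' Stable explicit time step
#'
#' Courant-limited step for the 2D explicit central-difference scheme,
#' `cfl_safety * h / (c_eff * sqrt(2))`.
#'
#' @param medium An [elastic_medium()].
#' @param grid A [sim_grid()].
#' @return Time step in s.
#' @export
stable_timestep <- function(medium, grid) {
  stopifnot(inherits(medium, "elastic_medium"), inherits(grid, "sim_grid"))
  grid$cfl_safety * grid$h / (effective_speed(medium) * sqrt(2))
}

#' Simulate a shear-wave push in a prestressed medium
#'
#' Explicit central-difference time integration of the reduced 2D model (see
#' [elastic_medium()]) driven by the acoustic-radiation-force field of
#' `beam`. The push is a rectangular gate of length `beam$tau`; partial
#' overlap of the gate with a time step is weighted so the injected impulse
#' is independent of the step size. Waves are absorbed in graded sponge
#' layers; the outermost nodes are held at zero.
#'
#' @param medium An [elastic_medium()].
#' @param grid A [sim_grid()].
#' @param beam A [push_beam()].
#' @param output_every Store every k-th time step (default 1, every step).
#' @return Object of class `taut_field`: list with `u` (nx x nz x nt array
#'   of out-of-plane displacement, m), axes `x`, `z`, `t`, and the `medium`,
#'   `grid`, `beam` used.
#' @export
simulate_push <- function(medium, grid, beam, output_every = 1L) {
  stopifnot(inherits(medium, "elastic_medium"), inherits(grid, "sim_grid"),
            inherits(beam, "push_beam"))
  output_every <- max(1L, as.integer(output_every))
  ax <- grid_axes(grid)
  nx <- length(ax$x); nz <- length(ax$z)
  dt <- stable_timestep(medium, grid)
  nt <- ceiling(grid$duration / dt)

  ff <- force_field(beam, grid)
  accel_push <- ff$map / medium$rho              # m/s^2 at full gate
  cx2 <- (medium$mu + medium$beta * medium$sigma) / medium$rho * dt^2 / grid$h^2
  cz2 <- medium$mu / medium$rho * dt^2 / grid$h^2

  # graded sponge: quadratic ramp of extra damping toward the edges
  eta <- matrix(medium$gamma, nx, nz)
  w <- grid$sponge_width
  if (w > 0) {
    gmax <- 4 * effective_speed(medium) / (w * grid$h)
    ramp <- function(idx, n) {
      d <- pmin(idx - 1L, n - idx)                # nodes from nearest edge
      pmax(0, (w - d) / w)^2
    }
    eta <- eta + gmax * pmax(outer(ramp(seq_len(nx), nx), rep(1, nz)),
                             outer(rep(1, nx), ramp(seq_len(nz), nz)))
  }
  damp_minus <- 1 - eta * dt / 2
  damp_plus  <- 1 + eta * dt / 2

  u_prev <- matrix(0, nx, nz)
  u_cur  <- matrix(0, nx, nz)
  keep <- unique(c(seq(1L, nt, by = output_every), nt))
  frames <- array(0, dim = c(nx, nz, length(keep) + 1L))
  times <- c(0, keep * dt)
  fi <- 2L
  ii <- 2:(nx - 1); jj <- 2:(nz - 1)
  max_push_amp <- 0
  guard <- Inf

  for (n in seq_len(nt)) {
    t_n <- (n - 1) * dt
    gate <- min(1, max(0, (beam$tau - t_n) / dt))  # fraction of step pushed
    lap_x <- u_cur[ii - 1L, jj] - 2 * u_cur[ii, jj] + u_cur[ii + 1L, jj]
    lap_z <- u_cur[ii, jj - 1L] - 2 * u_cur[ii, jj] + u_cur[ii, jj + 1L]
    u_next <- matrix(0, nx, nz)
    u_next[ii, jj] <- (2 * u_cur[ii, jj] - damp_minus[ii, jj] * u_prev[ii, jj] +
                       cx2 * lap_x + cz2 * lap_z +
                       dt^2 * gate * accel_push[ii, jj]) / damp_plus[ii, jj]
    amp <- max(abs(u_next))
    if (gate > 0) {
      max_push_amp <- max(max_push_amp, amp)
      guard <- 1e6 * max(max_push_amp, .Machine$double.xmin)
    }
    if (!is.finite(amp) || amp > guard)
      stop(sprintf("simulation diverged at step %d (t = %.3g ms): |u| = %g",
                   n, t_n * 1e3, amp))
    u_prev <- u_cur
    u_cur <- u_next
    if (fi <= length(keep) + 1L && n == keep[fi - 1L]) {
      frames[, , fi] <- u_cur
      fi <- fi + 1L
    }
  }

  structure(list(u = frames, x = ax$x, z = ax$z, t = times, dt = dt,
                 medium = medium, grid = grid, beam = beam),
            class = "taut_field")
}

#' @export
print.taut_field <- function(x, ...) {
  cat(sprintf("Shear-wave displacement field: %d x %d nodes, %d frames\n",
              dim(x$u)[1], dim(x$u)[2], dim(x$u)[3]))
  cat(sprintf("  extent %g x %g mm (h = %g mm), t in [0, %.3g] ms\n",
              diff(range(x$x)) * 1e3, diff(range(x$z)) * 1e3,
              (x$x[2] - x$x[1]) * 1e3, max(x$t) * 1e3))
  cat(sprintf("  peak |u| = %.3g m\n", max(abs(x$u))))
  invisible(x)
}

#' Run a tensile load sweep through the simulator
#'
#' For each load (grams across the cord cross-section) the axial prestress
#' is set via [grams_to_stress()], a push is simulated, and the lateral SWV
#' is estimated by the time-to-peak method at the focal depth. The result is
#' a tension sweep ready for [fit_squared_swv()].
#'
#' @param medium_base An [elastic_medium()]; its `sigma` is replaced per load.
#' @param grid A [sim_grid()].
#' @param beam A [push_beam()].
#' @param loads Numeric vector of loads in grams (>= 0).
#' @param cord_radius Cord radius in m used for the load-to-stress
#'   conversion (default 5 mm).
#' @param offsets,depth,signal Tracking options passed to
#'   [wavefront_trace()].
#' @return A `taut_sweep` data frame with columns `load_g`, `replicate`,
#'   `swv_mps` and attribute `source = "simulation"`.
#' @export
run_load_sweep <- function(medium_base, grid, beam, loads,
                           cord_radius = 5e-3, offsets = NULL, depth = NULL,
                           signal = "velocity") {
  stopifnot(inherits(medium_base, "elastic_medium"))
  if (any(loads < 0)) stop("invalid parameter: loads must be nonnegative")
  swv <- vapply(loads, function(g) {
    med <- medium_base
    med$sigma <- grams_to_stress(g, cord_radius)
    fld <- simulate_push(med, grid, beam)
    tr <- wavefront_trace(fld, depth = depth, offsets = offsets,
                          signal = signal)
    time_to_peak_swv(tr)$swv
  }, numeric(1))
  as_taut_sweep(data.frame(load_g = loads, replicate = 1L, swv_mps = swv),
                source = "simulation")
}
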