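#' Acoustic radiation force push beam
#'
#' Parametric description of a focused ultrasound push: a separable Gaussian
#' focal intensity profile (lateral and axial standard deviations) applied as
#' a rectangular temporal gate. The absorbed beam exerts a body force on
#' tissue through the standard acoustic-radiation-force relation
#' \eqn{F = 2 \alpha I / c_L}.
#'
#' @param intensity Spatial-peak intensity \eqn{I_0} at the focus, W/m^2
#'   (default 1e7, i.e. 1000 W/cm^2).
#' @param focal_depth Focal depth \eqn{z_f} in m.
#' @param sigma_x,sigma_z Gaussian standard deviations of the focal spot in
#'   the lateral (x) and axial (z) directions, m.
#' @param tau Push duration in s (rectangular gate starting at t = 0).
#' @param alpha Acoustic absorption in Np/m. See [attenuation_np_per_m()]
#'   to convert from the conventional dB/cm/MHz form.
#' @param c_l Longitudinal (compressional) sound speed in m/s.
#' @return An object of class `push_beam`.
#' @examples
#' b <- push_beam()
#' intensity_at(b, 0, b$focal_depth)  # equals b$intensity at the focus
#' @export
push_beam <- function(intensity = 1e7, focal_depth = 10e-3,
                      sigma_x = 0.5e-3, sigma_z = 2e-3,
                      tau = 200e-6, alpha = attenuation_np_per_m(0.5, 5),
                      c_l = 1540) {
  check_scalar(intensity, "intensity", lower = 0)
  check_scalar(focal_depth, "focal_depth")
  check_scalar(sigma_x, "sigma_x", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_z, "sigma_z", lower = 0, strict_lower = TRUE)
  check_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0)
  check_scalar(c_l, "c_l", lower = 0, strict_lower = TRUE)
  structure(list(intensity = intensity, focal_depth = focal_depth,
                 sigma_x = sigma_x, sigma_z = sigma_z, tau = tau,
                 alpha = alpha, c_l = c_l),
            class = "push_beam")
}

#' @export
print.push_beam <- function(x, ...) {
  cat("Acoustic push beam\n")
  cat(sprintf("  peak intensity : %g W/m^2 (%g W/cm^2)\n",
              x$intensity, x$intensity / 1e4))
  cat(sprintf("  focus          : z = %g mm (sigma_x = %g mm, sigma_z = %g mm)\n",
              x$focal_depth * 1e3, x$sigma_x * 1e3, x$sigma_z * 1e3))
  cat(sprintf("  gate           : %g us rectangular\n", x$tau * 1e6))
  cat(sprintf("  absorption     : %g Np/m, c_L = %g m/s\n", x$alpha, x$c_l))
  invisible(x)
}

#' Convert acoustic attenuation from dB/cm/MHz to Np/m
#'
#' @param db_per_cm_per_mhz Attenuation coefficient in dB/cm/MHz.
#' @param freq_mhz Centre frequency in MHz.
#' @return Absorption in Np/m (1 dB = ln(10)/20 Np).
#' @export
attenuation_np_per_m <- function(db_per_cm_per_mhz, freq_mhz) {
  check_scalar(db_per_cm_per_mhz, "db_per_cm_per_mhz", lower = 0)
  check_scalar(freq_mhz, "freq_mhz", lower = 0)
  db_per_cm_per_mhz * freq_mhz * 100 * log(10) / 20
}

#' Focal intensity profile
#'
#' Gaussian intensity of the push beam at lateral position `x` (relative to
#' the beam axis) and depth `z`. The maximum, `beam$intensity`, sits on the
#' axis at the focal depth.
#'
#' @param beam A [push_beam()].
#' @param x,z Coordinates in m (vectorised).
#' @return Intensity in W/m^2.
#' @export
intensity_at <- function(beam, x, z) {
  stopifnot(inherits(beam, "push_beam"))
  beam$intensity * exp(-x^2 / (2 * beam$sigma_x^2) -
                       (z - beam$focal_depth)^2 / (2 * beam$sigma_z^2))
}

#' Acoustic radiation body force density
#'
#' The body force exerted on an absorbing medium by a plane travelling wave,
#' \eqn{F = 2 \alpha I / c_L}, in N/m^3. Linear in both the absorption and
#' the intensity.
#'
#' @param intensity Acoustic intensity in W/m^2 (vectorised).
#' @param alpha Absorption in Np/m.
#' @param c_l Longitudinal sound speed in m/s; must be positive.
#' @return Force density in N/m^3.
#' @export
body_force_density <- function(intensity, alpha, c_l) {
  check_scalar(alpha, "alpha", lower = 0)
  check_scalar(c_l, "c_l", lower = 0, strict_lower = TRUE)
  2 * alpha * intensity / c_l
}

#' Sample the push body-force field on a simulation grid
#'
#' Evaluates the radiation-force density of `beam` at every grid node and
#' attaches the rectangular temporal gate. The beam axis is at x = 0 (the
#' grid centre).
#'
#' @param beam A [push_beam()].
#' @param grid A [sim_grid()].
#' @return A list of class `force_field` with elements `map` (nx-by-nz
#'   matrix, N/m^3), `gate` (push duration, s) and the grid axes.
#' @export
force_field <- function(beam, grid) {
  stopifnot(inherits(beam, "push_beam"), inherits(grid, "sim_grid"))
  ax <- grid_axes(grid)
  if (beam$focal_depth < min(ax$z) || beam$focal_depth > max(ax$z) ||
      min(ax$x) > 0 || max(ax$x) < 0)
    warning("push focus lies outside the simulation grid; beam truncated")
  map <- outer(ax$x, ax$z, function(x, z)
    body_force_density(intensity_at(beam, x, z), beam$alpha, beam$c_l))
  structure(list(map = map, gate = beam$tau, x = ax$x, z = ax$z),
            class = "force_field")
}
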