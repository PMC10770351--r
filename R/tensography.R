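#' Convert a load in grams to axial stress (and back)
#'
#' A mass hung across the cord cross-section of radius `cord_radius` exerts
#' an axial stress \eqn{m g_0 / (\pi r^2)} with \eqn{g_0} = 9.80665 m/s^2.
#' On a 5 mm radius cord, 4 kPa stress increments correspond to 32 g load
#' increments, up to 32 kPa at 256 g.
#'
#' @param mass_g Load in grams (>= 0, vectorised).
#' @param cord_radius Cord radius in m (default 5 mm).
#' @return `grams_to_stress`: stress in Pa.
#' @export
grams_to_stress <- function(mass_g, cord_radius = 5e-3) {
  check_scalar(cord_radius, "cord_radius", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(mass_g)) || any(mass_g < 0))
    stop("invalid parameter: mass_g must be nonnegative")
  mass_g / 1000 * 9.80665 / (pi * cord_radius^2)
}

#' @rdname grams_to_stress
#' @param stress Axial stress in Pa (vectorised).
#' @param exact If `FALSE` (default) round to the nearest gram for display;
#'   `TRUE` returns the exact inverse.
#' @return `stress_to_grams`: load in grams.
#' @export
stress_to_grams <- function(stress, cord_radius = 5e-3, exact = FALSE) {
  check_scalar(cord_radius, "cord_radius", lower = 0, strict_lower = TRUE)
  g <- stress * pi * cord_radius^2 / 9.80665 * 1000
  if (exact) g else round(g)
}

#' Acoustoelastic coupling for a target calibration slope
#'
#' The reduced wave model predicts a squared-SWV-per-gram slope of
#' \eqn{\beta g_0 / (\rho \pi r^2 \times 1000)}; inverting it gives the
#' coupling `beta` that reproduces a given calibration slope — e.g. a slope
#' of 0.058 m^2 s^-2 g^-1 on a 5 mm cord corresponds to beta of about 0.46,
#' roughly half the ideal stretched-membrane coupling of 1.
#'
#' @param slope Target slope in m^2 s^-2 per gram.
#' @param rho Density in kg/m^3.
#' @param cord_radius Cord radius in m.
#' @return Dimensionless beta.
#' @export
beta_for_slope <- function(slope, rho = 1000, cord_radius = 5e-3) {
  check_scalar(slope, "slope", lower = 0, strict_lower = TRUE)
  slope * rho / (grams_to_stress(1, cord_radius))
}

#' Coerce a data frame to a tension sweep
#'
#' A tension sweep is the (load, SWV) calibration table: one row per
#' acquisition, columns `load_g`, `replicate`, `swv_mps`. Replicates are
#' kept as individual rows and enter the calibration fit as individual
#' points.
#'
#' @param x Data frame with columns `load_g` and `swv_mps` (`replicate`
#'   added as 1 if absent).
#' @param source Provenance tag: `"simulation"`, `"cadaver-synthetic"` or
#'   `"file"`.
#' @return A `taut_sweep` data frame.
#' @export
as_taut_sweep <- function(x, source = "file") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("load_g", "swv_mps"), names(x))
  if (length(miss))
    stop("sweep table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  if (any(x$load_g < 0)) stop("sweep loads must be nonnegative")
  if (any(x$swv_mps <= 0)) stop("sweep SWV values must be positive")
  x <- x[, c("load_g", "replicate", "swv_mps")]
  attr(x, "source") <- match.arg(source,
                                 c("simulation", "cadaver-synthetic", "file"))
  class(x) <- c("taut_sweep", "data.frame")
  x
}

#' Fit the squared-SWV versus tension calibration
#'
#' The tensography core: ordinary least squares of squared shear wave
#' velocity (m^2/s^2) on load (grams). Under acoustoelasticity the squared
#' speed is linear in tension, so the intercept is the squared zero-tension
#' baseline speed and the slope converts wave-speed measurements to load.
#'
#' @param sweep A `taut_sweep` (see [as_taut_sweep()]) or any data frame
#'   with `load_g` and `swv_mps` columns; at least 3 distinct loads.
#' @return An object of class `taut_fit` with components `slope`
#'   (m^2 s^-2 g^-1), `intercept` (v0^2, m^2/s^2), `r2`, `residual_se`, `n`,
#'   `mean_load`, `sxx`, `baseline_swv` (sqrt of the intercept; `NA` with
#'   `baseline_valid = FALSE` if the intercept is negative), the underlying
#'   `lm` fit and the data. Supports `print`, `summary`, `coef`, `predict`,
#'   `plot`, `residuals`, `confint` and `simulate` methods.
#' @examples
#' sw <- generate_tension_sweep(sweep_spec(noise_sd = 0, seed = 1))
#' fit <- fit_squared_swv(sw)
#' coef(fit)
#' @export
fit_squared_swv <- function(sweep) {
  if (!inherits(sweep, "taut_sweep")) sweep <- as_taut_sweep(sweep)
  if (length(unique(sweep$load_g)) < 3L)
    stop("insufficient data: calibration needs at least 3 distinct loads")
  d <- data.frame(load_g = sweep$load_g, v2 = sweep$swv_mps^2)
  fit <- stats::lm(v2 ~ load_g, data = d)
  # noiseless sweeps are legitimate input; silence the perfect-fit notice
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(fit)
  v0_sq <- unname(co[1])
  structure(list(
    slope = unname(co[2]),
    intercept = v0_sq,
    r2 = sm$r.squared,
    residual_se = sm$sigma,
    n = nrow(d),
    mean_load = mean(d$load_g),
    sxx = sum((d$load_g - mean(d$load_g))^2),
    baseline_swv = if (v0_sq >= 0) sqrt(v0_sq) else NA_real_,
    baseline_valid = v0_sq >= 0,
    lm = fit,
    data = sweep,
    source = attr(sweep, "source") %||% "file"
  ), class = "taut_fit")
}

#' @export
print.taut_fit <- function(x, digits = 4, ...) {
  cat("Squared-SWV vs tension calibration (OLS)\n")
  cat(sprintf("  v^2 = %.*g + %.*g * load_g   [m^2/s^2, load in g]\n",
              digits, x$intercept, digits, x$slope))
  cat(sprintf("  R^2 = %.3f, residual SE = %.*g m^2/s^2, n = %d (%s)\n",
              x$r2, digits, x$residual_se, x$n, x$source))
  if (x$baseline_valid)
    cat(sprintf("  zero-tension baseline SWV: %.3f m/s\n", x$baseline_swv))
  else
    cat("  zero-tension baseline SWV: invalid (negative intercept)\n")
  invisible(x)
}

#' @export
summary.taut_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(fit = object, coef_table = s$coefficients,
              slope_ci = stats::confint(object$lm)["load_g", ],
              intercept_ci = stats::confint(object$lm)["(Intercept)", ])
  class(out) <- "summary.taut_fit"
  out
}

#' @export
print.summary.taut_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coef_table)
  cat(sprintf("\n95%% CI slope:     [%.4g, %.4g] m^2 s^-2 g^-1\n",
              x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("95%% CI intercept: [%.4g, %.4g] m^2 s^-2\n",
              x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' @export
coef.taut_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.taut_fit <- function(object, ...) stats::residuals(object$lm)

#' Predict squared SWV at new loads
#'
#' @param object A [fit_squared_swv()] fit.
#' @param loads Loads in grams.
#' @param interval `"none"`, `"prediction"` or `"confidence"`.
#' @param level Interval level in (0, 1).
#' @param ... Unused.
#' @return Fitted squared SWV (m^2/s^2); with an interval, a matrix with
#'   columns `fit`, `lwr`, `upr`.
#' @export
predict.taut_fit <- function(object, loads = NULL,
                             interval = c("none", "prediction", "confidence"),
                             level = 0.95, ...) {
  interval <- match.arg(interval)
  loads <- loads %||% sort(unique(object$data$load_g))
  nd <- data.frame(load_g = loads)
  if (interval == "none")
    return(unname(stats::predict(object$lm, newdata = nd)))
  check_scalar(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  unname(stats::predict(object$lm, newdata = nd, interval = interval,
                        level = level))
}

#' 95% prediction band of the calibration
#'
#' Interval expected to contain a new squared-SWV observation at the given
#' load: \eqn{\hat y \pm t_{(1+level)/2,\,n-2}\, s \sqrt{1 + 1/n +
#' (load - \bar x)^2 / S_{xx}}}.
#'
#' @param fit A [fit_squared_swv()] fit.
#' @param load Loads in grams (vectorised).
#' @param level Band level in (0, 1), default 0.95.
#' @return Matrix with columns `fit`, `lower`, `upper` in m^2/s^2.
#' @export
prediction_band <- function(fit, load, level = 0.95) {
  stopifnot(inherits(fit, "taut_fit"))
  check_scalar(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  yhat <- fit$intercept + fit$slope * load
  tq <- stats::qt((1 + level) / 2, df = fit$n - 2)
  half <- tq * fit$residual_se *
    sqrt(1 + 1 / fit$n + (load - fit$mean_load)^2 / fit$sxx)
  cbind(fit = yhat, lower = yhat - half, upper = yhat + half)
}

#' Invert a calibration: SWV to tension
#'
#' Inverts the fitted linear model, \eqn{T = (v^2 - v_0^2)/k}. A speed below
#' the fitted baseline implies no tension under the model; such values are
#' clamped to 0 g and flagged through the `out_of_calibration` attribute.
#'
#' @param fit A [fit_squared_swv()] fit with positive slope.
#' @param swv Shear wave velocity in m/s (vectorised).
#' @return Tension in grams, with logical attribute `out_of_calibration`
#'   marking clamped entries.
#' @export
invert_tension <- function(fit, swv) {
  stopifnot(inherits(fit, "taut_fit"))
  if (!is.finite(fit$slope) || fit$slope <= 0)
    stop("non-invertible fit: slope must be positive to invert tension")
  tg <- (swv^2 - fit$intercept) / fit$slope
  clamped <- tg < 0
  tg[clamped] <- 0
  structure(tg, out_of_calibration = clamped)
}

#' @export
plot.taut_fit <- function(x, level = 0.95, ...) {
  loads <- seq(min(x$data$load_g), max(x$data$load_g), length.out = 100)
  band <- prediction_band(x, loads, level = level)
  graphics::plot(x$data$load_g, x$data$swv_mps^2,
                 xlab = "load (g)", ylab = expression(SWV^2 ~ (m^2 / s^2)),
                 main = "Squared SWV vs tension", ...)
  graphics::lines(loads, band[, "fit"], col = "magenta", lwd = 2)
  graphics::lines(loads, band[, "lower"], col = "magenta", lty = 2)
  graphics::lines(loads, band[, "upper"], col = "magenta", lty = 2)
  invisible(x)
}

#' Simulate new sweeps from a fitted calibration
#'
#' Draws `nsim` synthetic tension sweeps at the fitted slope and intercept
#' with Gaussian noise on squared SWV at the residual standard error, on the
#' same load schedule as the fitted data — the parametric-bootstrap
#' counterpart of [generate_tension_sweep()].
#'
#' @param object A [fit_squared_swv()] fit.
#' @param nsim Number of sweeps.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List of `taut_sweep` data frames.
#' @export
simulate.taut_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      spec <- sweep_spec(loads = object$data$load_g, replicates = 1,
                         slope = object$slope, intercept = object$intercept,
                         noise_sd = object$residual_se, seed = NULL)
      generate_tension_sweep(spec)
    })
  })
}
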