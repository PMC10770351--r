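#' Specification of a synthetic tension sweep
#'
#' Describes a benchtop-style calibration experiment: a load schedule, a
#' number of acquisitions per load, and a ground-truth linear model for
#' squared SWV with Gaussian noise on the squared scale (which keeps the
#' linear calibration model exact in expectation). The default schedule is
#' the cadaver-style protocol: baselines at 0 and 1 g, then 5 to 250 g in
#' 5 g increments, three acquisitions per load (156 rows). The default
#' slope/intercept give a 250 g SWV of about 5.09 m/s, and the default noise
#' level puts the calibration R^2 near 0.95 on that schedule.
#'
#' @param loads Load schedule in grams.
#' @param replicates Acquisitions per load (>= 1).
#' @param slope True slope k in m^2 s^-2 g^-1.
#' @param intercept True intercept v0^2 in m^2 s^-2.
#' @param noise_sd Gaussian noise SD on squared SWV, m^2 s^-2.
#' @param seed Optional RNG seed.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(loads = c(0, 1, seq(5, 250, by = 5)), replicates = 3,
                       slope = 0.053, intercept = 12.658, noise_sd = 0.9,
                       seed = NULL) {
  if (any(loads < 0)) stop("invalid parameter: loads must be nonnegative")
  check_scalar(replicates, "replicates", lower = 1)
  check_scalar(slope, "slope")
  check_scalar(intercept, "intercept")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(loads = loads, replicates = as.integer(replicates),
                 slope = slope, intercept = intercept, noise_sd = noise_sd,
                 seed = seed),
            class = "sweep_spec")
}

#' Generate a synthetic tension sweep
#'
#' Draws SWV acquisitions \eqn{v = \sqrt{v_0^2 + k\,load + \epsilon}},
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}, independently per replicate.
#' Draws whose squared speed lands at or below zero are redrawn (with a
#' warning); at the default parameters this is astronomically rare.
#'
#' @param spec A [sweep_spec()].
#' @return A `taut_sweep` data frame (`load_g`, `replicate`, `swv_mps`)
#'   with `source = "cadaver-synthetic"`.
#' @export
generate_tension_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  with_seed(spec$seed, {
    load_g <- rep(spec$loads, each = spec$replicates)
    replicate <- rep(seq_len(spec$replicates), times = length(spec$loads))
    v2 <- spec$intercept + spec$slope * load_g +
      stats::rnorm(length(load_g), 0, spec$noise_sd)
    bad <- which(v2 <= 0)
    if (length(bad)) {
      warning(sprintf("%d draw(s) gave non-positive squared SWV; redrawn (truncation)",
                      length(bad)))
      for (i in bad) {
        repeat {
          v2[i] <- spec$intercept + spec$slope * load_g[i] +
            stats::rnorm(1, 0, spec$noise_sd)
          if (v2[i] > 0) break
        }
      }
    }
    as_taut_sweep(data.frame(load_g = load_g, replicate = replicate,
                             swv_mps = sqrt(v2)),
                  source = "cadaver-synthetic")
  })
}

#' Specification of a synthetic intraoperative case series
#'
#' Describes a clinical-style series: `n_cases` patients, each imaged at the
#' PRE (tethered), MID (partly shortened) and FULL (fully shortened)
#' checkpoints, with 3-6 ultrasound acquisitions per checkpoint and tens to
#' hundreds of SWV sub-samples per acquisition. Sub-sample SWV is Normal
#' (optionally lognormal) around a checkpoint mean; the PRE mean must sit
#' above the POST mean unless `allow_overlap`. A configurable fraction of
#' cases (the last ones in the series, emulating cases E/F of a six-case
#' series) receives FULL-checkpoint curvature above the exclusion threshold
#' so that MID serves as the treated (POST) state.
#'
#' @param n_cases Number of cases (labelled A, B, ...).
#' @param images_range Range (min, max) of acquisitions per checkpoint.
#' @param subsamples_range Range of sub-samples per acquisition.
#' @param pre_mean,pre_sd,mid_mean,mid_sd,full_mean,full_sd Sub-sample SWV
#'   distribution (m/s) per checkpoint.
#' @param curv_mean,curv_sd Named 3-vectors (PRE, MID, FULL) of per-image
#'   relative curvature distribution, percent.
#' @param high_curv_fraction Fraction of cases whose FULL checkpoint is
#'   high-curvature (excluded); default 1/3.
#' @param high_curv_mean,high_curv_sd,high_curv_min High-curvature FULL
#'   distribution (percent); truncated below at `high_curv_min` so these
#'   checkpoints always trip the exclusion rule.
#' @param family `"normal"` or `"lognormal"` sub-sample noise.
#' @param fig_counts Optional explicit sub-sample counts: a list with
#'   entries `PRE` and `MID`, applied to the first case (its image count at
#'   those checkpoints follows the lengths). Use
#'   `series_fig_counts()` for the published ten-image fixture.
#' @param allow_overlap Permit `pre_mean <= full_mean`.
#' @param seed Optional RNG seed.
#' @return Object of class `series_spec`.
#' @export
series_spec <- function(n_cases = 6, images_range = c(3, 6),
                        subsamples_range = c(40, 120),
                        pre_mean = 2.3, pre_sd = 0.25,
                        mid_mean = 1.55, mid_sd = 0.25,
                        full_mean = 1.45, full_sd = 0.25,
                        curv_mean = c(PRE = 2, MID = 3, FULL = 2.5),
                        curv_sd = c(PRE = 1, MID = 1, FULL = 1),
                        high_curv_fraction = 1 / 3,
                        high_curv_mean = 10, high_curv_sd = 2,
                        high_curv_min = 6,
                        family = c("normal", "lognormal"),
                        fig_counts = NULL, allow_overlap = FALSE,
                        seed = NULL) {
  check_scalar(n_cases, "n_cases", lower = 1)
  stopifnot(length(images_range) == 2L, images_range[1] >= 1,
            images_range[2] >= images_range[1],
            length(subsamples_range) == 2L, subsamples_range[1] >= 1)
  for (nm in c("pre_sd", "mid_sd", "full_sd"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(high_curv_fraction, "high_curv_fraction", lower = 0, upper = 1)
  if (!allow_overlap && pre_mean <= full_mean)
    stop("PRE mean must exceed POST (FULL) mean; set allow_overlap = TRUE to override")
  structure(list(n_cases = as.integer(n_cases),
                 images_range = as.integer(images_range),
                 subsamples_range = as.integer(subsamples_range),
                 means = c(PRE = pre_mean, MID = mid_mean, FULL = full_mean),
                 sds = c(PRE = pre_sd, MID = mid_sd, FULL = full_sd),
                 curv_mean = curv_mean, curv_sd = curv_sd,
                 high_curv_fraction = high_curv_fraction,
                 high_curv_mean = high_curv_mean, high_curv_sd = high_curv_sd,
                 high_curv_min = high_curv_min,
                 family = match.arg(family),
                 fig_counts = fig_counts, seed = seed),
            class = "series_spec")
}

#' Published per-image sub-sample counts fixture
#'
#' The ten sub-sample counts of the worked single-case example (five PRE and
#' five MID acquisitions), for use as `fig_counts` in [series_spec()].
#'
#' @return List with integer vectors `PRE` and `MID`.
#' @export
series_fig_counts <- function() {
  list(PRE = c(76L, 60L, 72L, 84L, 76L), MID = c(116L, 72L, 64L, 96L, 112L))
}

#' Generate a synthetic intraoperative case series
#'
#' @param spec A [series_spec()].
#' @return A `case_series` data frame in the acquisition-table schema:
#'   `case_id`, `checkpoint`, `image_index`, `subsample_index`, `swv_mps`,
#'   `in_plane`, `curvature_pct` (curvature constant within an image).
#' @examples
#' series <- generate_case_series(series_spec(seed = 7))
#' table(series$case_id, series$checkpoint)[, c("PRE", "MID", "FULL")]
#' @export
generate_case_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  with_seed(spec$seed, {
    n_high <- ceiling(spec$high_curv_fraction * spec$n_cases)
    high_cases <- if (n_high > 0)
      seq.int(spec$n_cases - n_high + 1L, spec$n_cases) else integer(0)
    rows <- list()
    for (ci in seq_len(spec$n_cases)) {
      case_id <- make_case_id(ci)
      for (cp in c("PRE", "MID", "FULL")) {
        counts <- NULL
        if (ci == 1L && !is.null(spec$fig_counts) &&
            cp %in% names(spec$fig_counts))
          counts <- as.integer(spec$fig_counts[[cp]])
        n_img <- if (!is.null(counts)) length(counts) else
          sample(spec$images_range[1]:spec$images_range[2], 1L)
        for (im in seq_len(n_img)) {
          n_sub <- if (!is.null(counts)) counts[im] else
            sample(spec$subsamples_range[1]:spec$subsamples_range[2], 1L)
          mu <- spec$means[[cp]]; sd <- spec$sds[[cp]]
          swv <- if (spec$family == "normal") {
            v <- stats::rnorm(n_sub, mu, sd)
            while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, sd)
            v
          } else {
            s2 <- log(1 + (sd / mu)^2)
            stats::rlnorm(n_sub, log(mu) - s2 / 2, sqrt(s2))
          }
          curv <- if (cp == "FULL" && ci %in% high_cases) {
            max(spec$high_curv_min,
                stats::rnorm(1, spec$high_curv_mean, spec$high_curv_sd))
          } else {
            max(0, stats::rnorm(1, spec$curv_mean[[cp]], spec$curv_sd[[cp]]))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = case_id, checkpoint = cp, image_index = im,
            subsample_index = seq_len(n_sub), swv_mps = swv,
            in_plane = TRUE, curvature_pct = curv)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("case_series", "data.frame")
    out
  })
}

make_case_id <- function(i) {
  if (i <= 26L) LETTERS[i] else paste0(LETTERS[(i - 1L) %/% 26L], LETTERS[(i - 1L) %% 26L + 1L])
}

#' Constructed translating-pulse field
#'
#' Builds a `taut_field` containing a Gaussian pulse moving laterally at
#' exactly the given speed — the ground-truth fixture for the time-to-peak
#' estimator.
#'
#' @param speed Pulse speed in m/s (> 0).
#' @param grid A [sim_grid()].
#' @param width Lateral Gaussian width (SD) of the pulse, m.
#' @param depth_width Axial envelope SD, m.
#' @param n_frames Number of stored time frames.
#' @param amplitude Peak displacement, m.
#' @return A `taut_field` (with `beam = NULL`; tracking defaults to the
#'   grid mid-depth).
#' @export
generate_translating_pulse <- function(speed, grid = sim_grid(),
                                       width = 1e-3, depth_width = 3e-3,
                                       n_frames = 128, amplitude = 1e-6) {
  check_scalar(speed, "speed", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(grid, "sim_grid"))
  ax <- grid_axes(grid)
  tt <- seq(0, grid$duration, length.out = n_frames)
  zc <- stats::median(ax$z)
  env_z <- exp(-(ax$z - zc)^2 / (2 * depth_width^2))
  u <- array(0, dim = c(length(ax$x), length(ax$z), n_frames))
  for (k in seq_len(n_frames)) {
    prof_x <- amplitude * exp(-(ax$x - speed * tt[k])^2 / (2 * width^2))
    u[, , k] <- outer(prof_x, env_z)
  }
  structure(list(u = u, x = ax$x, z = ax$z, t = tt, dt = tt[2] - tt[1],
                 medium = NULL, grid = grid, beam = NULL),
            class = "taut_field")
}
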