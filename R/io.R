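#' Read and write pipeline tables
#'
#' Delimited-text (CSV) interchange for the three table schemas the
#' pipeline consumes: tension sweeps (`load_g, replicate, swv_mps`),
#' acquisition tables (`case_id, checkpoint, image_index, subsample_index,
#' swv_mps, in_plane, curvature_pct`) and centerlines (`x_mm, y_mm`).
#' Numeric values are written with 17 significant digits so a write/read
#' round trip preserves values to better than 1e-12 relative error.
#' Malformed input fails with an error naming the file, line and column.
#'
#' @param path File path.
#' @param sweep,series,line Objects to write.
#' @name taut_io
NULL

sweep_cols <- c(load_g = "numeric", replicate = "integer",
                swv_mps = "numeric")
acq_cols <- c(case_id = "character", checkpoint = "character",
              image_index = "integer", subsample_index = "integer",
              swv_mps = "numeric", in_plane = "logical",
              curvature_pct = "numeric")
line_cols <- c(x_mm = "numeric", y_mm = "numeric")

fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_taut_table <- function(df, path, cols) {
  out <- df[, names(cols), drop = FALSE]
  for (j in seq_along(out)) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_taut_table <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(names(cols), names(df))
  if (length(miss))
    stop(sprintf("parse error in %s: missing column(s) %s", path,
                 paste(sQuote(miss), collapse = ", ")))
  df <- df[, names(cols), drop = FALSE]
  for (nm in names(cols)) {
    raw <- df[[nm]]
    conv <- switch(cols[[nm]],
                   numeric = suppressWarnings(as.numeric(raw)),
                   integer = suppressWarnings(as.integer(raw)),
                   logical = parse_logical(raw),
                   character = raw)
    bad <- which(is.na(conv) & !(raw %in% c("NA", "")))
    if (cols[[nm]] != "character" && length(bad))
      stop(sprintf("parse error in %s, line %d, column '%s': cannot parse '%s'",
                   path, bad[1] + 1L, nm, raw[bad[1]]))
    df[[nm]] <- conv
  }
  df
}

parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  out
}

#' @rdname taut_io
#' @export
write_sweep <- function(sweep, path) {
  if (!inherits(sweep, "taut_sweep")) sweep <- as_taut_sweep(sweep)
  write_taut_table(sweep, path, sweep_cols)
}

#' @rdname taut_io
#' @export
read_sweep <- function(path) {
  as_taut_sweep(read_taut_table(path, sweep_cols), source = "file")
}

#' @rdname taut_io
#' @export
write_acquisitions <- function(series, path) {
  write_taut_table(series, path, acq_cols)
}

#' @rdname taut_io
#' @export
read_acquisitions <- function(path) {
  out <- read_taut_table(path, acq_cols)
  class(out) <- c("case_series", "data.frame")
  out
}

#' @rdname taut_io
#' @export
write_centerline <- function(line, path) {
  df <- as.data.frame(as.matrix(line))
  names(df) <- c("x_mm", "y_mm")
  write_taut_table(df, path, line_cols)
}

#' @rdname taut_io
#' @export
read_centerline <- function(path) {
  as.matrix(read_taut_table(path, line_cols))
}

#' Run configuration
#'
#' Assembles (and validates) the structured configuration of a pipeline
#' run: physical simulation settings, load schedule, decision thresholds,
#' statistics options and seeds. `read_run_config()` accepts JSON or YAML
#' (by file extension); unknown keys anywhere in the file are rejected with
#' a message naming them.
#'
#' @param medium,grid,beam Named lists of overrides for
#'   [elastic_medium()], [sim_grid()] and [push_beam()] arguments (beam
#'   keys may also use the config-file aliases `intensity_w_per_m2`,
#'   `focal_depth_m`, `sigma_x_m`, `sigma_z_m`, `tau_s`, `alpha_np_per_m`,
#'   `c_l_m_per_s`).
#' @param loads Load schedule in grams.
#' @param thresholds Named list: `diagnosis_swv` (m/s), `curvature_pct`,
#'   `min_subsamples`.
#' @param stats Named list: `roc_ci` ("delong"/"bootstrap"),
#'   `alpha_welch`, `alpha_anova`, `alpha_tukey`.
#' @param seed Integer seed or `NULL`.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(medium = list(), grid = list(), beam = list(),
                       loads = seq(0, 256, by = 32),
                       thresholds = list(), stats = list(),
                       seed = NULL, out_dir = ".") {
  beam <- rename_keys(beam, c(intensity_w_per_m2 = "intensity",
                              focal_depth_m = "focal_depth",
                              sigma_x_m = "sigma_x", sigma_z_m = "sigma_z",
                              tau_s = "tau", alpha_np_per_m = "alpha",
                              c_l_m_per_s = "c_l"))
  check_keys(medium, names(formals(elastic_medium)), "medium")
  check_keys(grid, names(formals(sim_grid)), "grid")
  check_keys(beam, names(formals(push_beam)), "beam")
  th <- utils::modifyList(list(diagnosis_swv = 1.76, curvature_pct = 5,
                               min_subsamples = 30), thresholds)
  check_keys(th, c("diagnosis_swv", "curvature_pct", "min_subsamples"),
             "thresholds")
  st <- utils::modifyList(list(roc_ci = "delong", alpha_welch = 0.001,
                               alpha_anova = 0.05, alpha_tukey = 0.001),
                          stats)
  check_keys(st, c("roc_ci", "alpha_welch", "alpha_anova", "alpha_tukey"),
             "stats")
  structure(list(medium = do.call(elastic_medium, medium),
                 grid = do.call(sim_grid, grid),
                 beam = do.call(push_beam, beam),
                 loads = loads, thresholds = th, stats = st,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

rename_keys <- function(x, map) {
  hit <- names(x) %in% names(map)
  names(x)[hit] <- map[names(x)[hit]]
  x
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s config: %s (allowed: %s)", where,
                 paste(sQuote(bad), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' @rdname run_config
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration file
#'   with any of the top-level keys `medium`, `grid`, `beam`, `loads`,
#'   `thresholds`, `stats`, `seed`, `out_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yml = ,
                yaml = yaml::read_yaml(path),
                stop("unsupported config format '", ext,
                     "' (use .json, .yml or .yaml)"))
  check_keys(raw, names(formals(run_config)), "top-level")
  do.call(run_config, raw)
}

#' Write a structured run report
#'
#' Serializes a [run_case_pipeline()] report as JSON next to a
#' human-readable text rendering, together with a run log (package version,
#' seed, configuration hash and record-keeping counts, with the
#' quality-control discard reasons itemized). Re-running with identical
#' inputs reproduces the files byte for byte.
#'
#' @param report A `taut_report`.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to hash into the log.
#' @param seed Seed to record in the log.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, config = NULL, seed = NULL) {
  stopifnot(inherits(report, "taut_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  log <- list(package = "tautr",
              version = as.character(utils::packageVersion("tautr")),
              seed = seed,
              config_hash = if (!is.null(config)) config_hash(config),
              records = report$qc[c("n_images_read", "n_images_kept",
                                    "n_images_discarded")],
              discards = report$qc$discard_reasons)
  payload <- list(log = log, params = report$params,
                  cases = lapply(report$cases, case_json),
                  pooled = report$pooled,
                  roc = if (!is.null(report$roc))
                    report$roc[c("auc", "auc_ci", "youden_threshold",
                                 "youden_j", "n_pre", "n_post")],
                  qc = report$qc)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

case_json <- function(cs) {
  list(case_id = cs$case_id, status = cs$status,
       post_checkpoint = cs$post_checkpoint,
       checkpoint_curvature = as.list(cs$checkpoint_curvature),
       pre_medians = cs$pre_medians, post_medians = cs$post_medians,
       welch = if (!is.null(cs$welch)) unclass(cs$welch))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else unclass(x)
}

#' Export a wave field to a portable container
#'
#' Writes the displacement history as a JSON header (axes, layout,
#' metadata) plus a flat CSV of frames, and optionally per-frame grayscale
#' PNG images for visual inspection. The array layout is documented in the
#' header: values are stored frame by frame, each frame in column-major
#' (x fastest) order.
#'
#' @param field A `taut_field`.
#' @param dir Output directory.
#' @param png Also write per-frame grayscale PNGs (default FALSE).
#' @return Invisibly, the directory.
#' @export
export_field <- function(field, dir, png = FALSE) {
  stopifnot(inherits(field, "taut_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(layout = "frames x (z-major rows, x fastest)",
              nx = length(field$x), nz = length(field$z),
              nt = length(field$t),
              x_m = field$x, z_m = field$z, t_s = field$t)
  jsonlite::write_json(hdr, file.path(dir, "field.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- t(matrix(field$u, ncol = length(field$t)))
  utils::write.table(format(flat, digits = 8),
                     file.path(dir, "field.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (png) {
    rng <- max(abs(field$u)) %||% 1
    if (rng == 0) rng <- 1
    for (k in seq_along(field$t)) {
      img <- t(field$u[, , k])[length(field$z):1, , drop = FALSE]
      grDevices::png(file.path(dir, sprintf("frame_%04d.png", k)),
                     width = length(field$x), height = length(field$z))
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::image(t(img), col = grDevices::gray.colors(256),
                      zlim = c(-rng, rng), axes = FALSE)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
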