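#' Relative curvature of a cord centerline
#'
#' Slackness metric for an imaged spinal cord: the excess (indirect) length
#' that the centerline travels from its first to its last point, as a
#' percentage of the direct end-to-end distance,
#' \eqn{(arc/chord - 1) \times 100}. A straight cord scores 0; slack
#' (curved) cords score higher. Invariant under rigid motions and uniform
#' scaling of the coordinates.
#'
#' @param line Centerline: a 2-column matrix or data frame of ordered planar
#'   coordinates (mm or any consistent unit), at least 2 points,
#'   consecutive points distinct.
#' @return Object of class `curvature_result`: list with
#'   `relative_curvature` (percent), `arc_length` and `chord_length` (input
#'   units).
#' @examples
#' th <- seq(0, pi, length.out = 100)
#' relative_curvature(cbind(cos(th), sin(th)))  # semicircle: ~57.1%
#' @export
relative_curvature <- function(line) {
  line <- as.matrix(line)
  if (!is.numeric(line) || ncol(line) != 2L || nrow(line) < 2L)
    stop("centerline must be a numeric 2-column matrix with at least 2 points")
  if (any(!is.finite(line))) stop("centerline contains non-finite coordinates")
  seg <- sqrt(rowSums((line[-1L, , drop = FALSE] -
                       line[-nrow(line), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct")
  chord <- sqrt(sum((line[nrow(line), ] - line[1L, ])^2))
  if (chord == 0)
    stop("undefined chord: centerline endpoints coincide")
  arc <- sum(seg)
  structure(list(relative_curvature = (arc / chord - 1) * 100,
                 arc_length = arc, chord_length = chord),
            class = "curvature_result")
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf("Relative curvature: %.2f%% (arc %.4g, chord %.4g)\n",
              x$relative_curvature, x$arc_length, x$chord_length))
  invisible(x)
}

#' Select the post-intervention checkpoint by curvature exclusion
#'
#' Shear waves are tracked linearly, so a slack, highly curved cord degrades
#' acquisition quality. The treated (POST) state of a case is the FULL
#' checkpoint when its relative curvature is at or below the exclusion
#' threshold; otherwise the MID checkpoint is used as POST.
#'
#' @param case_curvatures Named numeric vector or list mapping checkpoint
#'   (`"MID"`, `"FULL"`) to relative curvature in percent. `FULL` must be
#'   present; `MID` must be present if FULL is excluded.
#' @param threshold Exclusion threshold in percent (default 5).
#' @return `"FULL"` or `"MID"`.
#' @export
select_post_checkpoint <- function(case_curvatures, threshold = 5) {
  check_scalar(threshold, "threshold", lower = 0)
  cc <- unlist(case_curvatures)
  if (!"FULL" %in% names(cc))
    stop("FULL checkpoint curvature is required")
  if (cc[["FULL"]] <= threshold) return("FULL")
  if (!"MID" %in% names(cc))
    stop(sprintf(
      "no valid POST checkpoint: FULL curvature %.2f%% exceeds %.2f%% and no MID is available",
      cc[["FULL"]], threshold))
  "MID"
}
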