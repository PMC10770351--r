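#' Run the intraoperative tensography pipeline on a case series
#'
#' Full analysis of a PRE/MID/FULL acquisition table: per-image pooling
#' (median of in-plane sub-samples, quality discard below
#' `min_subsamples`), curvature-based selection of the treated (POST)
#' checkpoint, per-case Welch tests on the pooled sub-sample datapoints,
#' image-level stretched/relaxed classification against the SWV threshold,
#' pooled diagnostic accuracy, checkpoint-average accuracy, and an
#' empirical ROC on the image medians. Cases that fail quality control are
#' reported, not silently dropped. With the default (DeLong) confidence
#' interval the report is fully deterministic.
#'
#' @param series A `case_series` (see [generate_case_series()]) or any data
#'   frame in the acquisition-table schema: `case_id`, `checkpoint`
#'   (PRE/MID/FULL), `image_index`, `subsample_index`, `swv_mps`,
#'   `in_plane`, `curvature_pct`.
#' @param threshold Diagnosis threshold in m/s (default 1.76).
#' @param curvature_threshold FULL-checkpoint exclusion threshold in
#'   percent (default 5).
#' @param min_subsamples Image quality cutoff (default 30).
#' @param alpha Per-case Welch significance level (default 0.001). No
#'   multiple-testing adjustment is applied across cases; per-case p-values
#'   are reported raw.
#' @param roc_ci `"delong"` or `"bootstrap"` (see [empirical_roc()]).
#' @param seed Seed for the bootstrap CI, if selected.
#' @return Object of class `taut_report`: list with `cases` (per-case
#'   summaries), `images` (per-image medians, QC status and labels),
#'   `pooled` (accuracy/sensitivity/specificity on single images and on
#'   checkpoint averages), `roc`, `qc` (read/kept/discarded counts and
#'   itemized discard reasons) and `params`.
#' @export
run_case_pipeline <- function(series, threshold = 1.76,
                              curvature_threshold = 5, min_subsamples = 30,
                              alpha = 0.001,
                              roc_ci = c("delong", "bootstrap"),
                              seed = NULL) {
  roc_ci <- match.arg(roc_ci)
  need <- c("case_id", "checkpoint", "image_index", "subsample_index",
            "swv_mps", "in_plane", "curvature_pct")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("acquisition table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(series$checkpoint %in% c("PRE", "MID", "FULL")))
    stop("checkpoint must be one of PRE, MID, FULL")
  if (any(series$swv_mps <= 0)) stop("sub-sample SWV values must be positive")

  # per-image pooling
  key <- interaction(series$case_id, series$checkpoint, series$image_index,
                     drop = TRUE)
  img_list <- lapply(split(series, key), function(d) {
    p <- pool_acquisition(d$swv_mps, d$in_plane, min_subsamples)
    data.frame(case_id = d$case_id[1], checkpoint = d$checkpoint[1],
               image_index = d$image_index[1], n_subsamples = p$n,
               median_swv = p$median, discarded = p$discarded,
               reason = p$reason, curvature_pct = d$curvature_pct[1])
  })
  images <- do.call(rbind, img_list)
  images <- images[order(images$case_id, images$checkpoint,
                         images$image_index), ]
  rownames(images) <- NULL

  cases <- list()
  for (cid in unique(images$case_id)) {
    ci <- images[images$case_id == cid, ]
    curv <- tapply(ci$curvature_pct, ci$checkpoint, mean)
    res <- list(case_id = cid, checkpoint_curvature = curv,
                post_checkpoint = NA_character_, status = "ok",
                welch = NULL, pre_medians = numeric(0),
                post_medians = numeric(0))
    post_cp <- tryCatch(
      select_post_checkpoint(curv[intersect(c("MID", "FULL"), names(curv))],
                             curvature_threshold),
      error = function(e) conditionMessage(e))
    if (!post_cp %in% c("MID", "FULL")) {
      res$status <- post_cp            # failure message
      cases[[cid]] <- res
      next
    }
    res$post_checkpoint <- post_cp
    keep <- ci[!ci$discarded, ]
    pre_img <- keep[keep$checkpoint == "PRE", ]
    post_img <- keep[keep$checkpoint == post_cp, ]
    if (nrow(pre_img) == 0 || nrow(post_img) == 0) {
      res$status <- "no retained images at PRE or POST after quality control"
      cases[[cid]] <- res
      next
    }
    res$pre_medians <- pre_img$median_swv
    res$post_medians <- post_img$median_swv
    sub <- series[series$case_id == cid & as.logical(series$in_plane), ]
    retained <- function(cp, imgs) sub$checkpoint == cp &
      sub$image_index %in% imgs$image_index
    res$welch <- welch_t_test(sub$swv_mps[retained("PRE", pre_img)],
                              sub$swv_mps[retained(post_cp, post_img)],
                              alpha = alpha)
    cases[[cid]] <- res
  }

  ok <- vapply(cases, function(x) x$status == "ok", logical(1))
  pre_all <- unlist(lapply(cases[ok], `[[`, "pre_medians"))
  post_all <- unlist(lapply(cases[ok], `[[`, "post_medians"))

  pooled <- NULL
  roc <- NULL
  if (length(pre_all) && length(post_all)) {
    pred <- classify_image(c(pre_all, post_all), threshold)
    truth <- rep(c("stretched", "relaxed"),
                 c(length(pre_all), length(post_all)))
    single <- diagnostic_accuracy(pred, truth)
    cp_means <- c(vapply(cases[ok], function(x) mean(x$pre_medians),
                         numeric(1)),
                  vapply(cases[ok], function(x) mean(x$post_medians),
                         numeric(1)))
    cp_truth <- rep(c("stretched", "relaxed"), each = sum(ok))
    averaged <- diagnostic_accuracy(classify_image(cp_means, threshold),
                                    cp_truth)
    pooled <- list(single_image = single, checkpoint_average = averaged,
                   n_images = length(truth), n_checkpoints = length(cp_truth))
    roc <- empirical_roc(pre_all, post_all, ci_method = roc_ci, seed = seed)
  }

  structure(list(
    cases = cases, images = images, pooled = pooled, roc = roc,
    qc = list(n_images_read = nrow(images),
              n_images_kept = sum(!images$discarded),
              n_images_discarded = sum(images$discarded),
              discard_reasons = images[images$discarded,
                                       c("case_id", "checkpoint",
                                         "image_index", "reason")],
              failed_cases = names(cases)[!ok]),
    params = list(threshold = threshold,
                  curvature_threshold = curvature_threshold,
                  min_subsamples = min_subsamples, alpha = alpha,
                  roc_ci = roc_ci)
  ), class = "taut_report")
}

#' @export
print.taut_report <- function(x, ...) {
  cat("Intraoperative tensography report\n")
  cat(sprintf("  threshold %.3g m/s | curvature cutoff %.3g%% | min sub-samples %d\n",
              x$params$threshold, x$params$curvature_threshold,
              x$params$min_subsamples))
  cat(sprintf("  images: %d read, %d kept, %d discarded\n",
              x$qc$n_images_read, x$qc$n_images_kept,
              x$qc$n_images_discarded))
  for (cs in x$cases) {
    if (cs$status != "ok") {
      cat(sprintf("  case %s: FAILED QC — %s\n", cs$case_id, cs$status))
      next
    }
    cat(sprintf(
      "  case %s: POST = %s | PRE median %.2f (n=%d) vs POST %.2f (n=%d) | Welch p = %.3g%s\n",
      cs$case_id, cs$post_checkpoint, mean(cs$pre_medians),
      length(cs$pre_medians), mean(cs$post_medians),
      length(cs$post_medians), cs$welch$p_value,
      if (cs$welch$p_value < cs$welch$alpha) " *" else ""))
  }
  if (!is.null(x$pooled)) {
    s <- x$pooled$single_image; a <- x$pooled$checkpoint_average
    cat(sprintf("  single-image: accuracy %.1f%%, sens %.1f%%, spec %.1f%% (n = %d)\n",
                s$accuracy, s$sensitivity, s$specificity, x$pooled$n_images))
    cat(sprintf("  checkpoint-average: accuracy %.1f%% (n = %d)\n",
                a$accuracy, x$pooled$n_checkpoints))
    cat(sprintf("  ROC AUC %.3f [%.3f, %.3f], Youden threshold %.3f m/s\n",
                x$roc$auc, x$roc$auc_ci[1], x$roc$auc_ci[2],
                x$roc$youden_threshold))
  }
  invisible(x)
}
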