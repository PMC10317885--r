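#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. When both masks are empty the DSC is
#' undefined and `NA` is returned; summaries exclude such cases.
#'
#' @param mask_a,mask_b logical (or 0/1) arrays on the same grid.
#' @return DSC in \[0, 1\], or `NA` if both masks are empty.
#' @export
dsc <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("masks are on different grids")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

target_mask <- function(labels, target) {
  arr <- if (inherits(labels, "label_map")) labels$labels else labels
  switch(target,
         primary = arr == 1L,
         ln = arr == 2L,
         union = arr == 1L | arr == 2L,
         stop("unknown target: ", target))
}

#' Cohort and per-patient Dice report
#'
#' For each delineation target — primary tumor (class 1), LN metastases
#' (class 2), and their union — computes the cohort DSC (voxel counts pooled
#' over all patients before the ratio), the per-patient DSC distribution with
#' mean, median and central 50% interval (25th–75th percentile), and the
#' number of failed delineations (patients with a non-empty reference and
#' DSC = 0). Patients where both reference and prediction are empty for a
#' target have undefined DSC and are excluded from that target's summaries.
#'
#' @param ref_labels,pred_labels equal-length lists of [label_map()]s
#'   (reference and predicted), paired by patient.
#' @return An object of class `dsc_report`: per-target list with `cohort`,
#'   `individual`, `mean`, `median`, `ci50`, `n_failed`, `n_defined`.
#' @export
dsc_report <- function(ref_labels, pred_labels) {
  if (length(ref_labels) != length(pred_labels)) {
    stop("reference and prediction lists differ in length")
  }
  targets <- c("primary", "ln", "union")
  out <- lapply(targets, function(tg) {
    inter <- 0; size <- 0
    indiv <- numeric(length(ref_labels))
    failed <- logical(length(ref_labels))
    for (i in seq_along(ref_labels)) {
      a <- target_mask(ref_labels[[i]], tg)
      b <- target_mask(pred_labels[[i]], tg)
      inter <- inter + sum(a & b)
      size <- size + sum(a) + sum(b)
      indiv[i] <- dsc(a, b)
      failed[i] <- sum(a) > 0 && !is.na(indiv[i]) && indiv[i] == 0
    }
    defined <- indiv[!is.na(indiv)]
    list(cohort = if (size > 0) 2 * inter / size else NA_real_,
         individual = indiv,
         mean = mean(defined),
         median = stats::median(defined),
         ci50 = stats::quantile(defined, c(0.25, 0.75), names = FALSE),
         n_failed = sum(failed),
         n_defined = length(defined))
  })
  names(out) <- targets
  structure(out, class = "dsc_report")
}

#' @export
print.dsc_report <- function(x, ...) {
  cat("Target      cohort   mean  median  50% CI          failed\n")
  for (tg in names(x)) {
    r <- x[[tg]]
    cat(sprintf("%-10s  %6.3f  %5.3f  %6.3f  [%5.3f, %5.3f]  %d\n",
                tg, r$cohort, r$mean, r$median, r$ci50[1], r$ci50[2],
                r$n_failed))
  }
  invisible(x)
}

#' Voxel-level lesion classification contingency
#'
#' Restricted to voxels delineated as lesion by both the reference and the
#' prediction (labels in \{1, 2\} on both sides), counts correctly and
#' incorrectly classified voxels: `T_PT` (ref 1, pred 1), `F_LN` (ref 1,
#' pred 2), `T_LN` (ref 2, pred 2), `F_PT` (ref 2, pred 1), and derives
#' `TPR_PT = T_PT / (T_PT + F_LN)`, `TPR_LN = T_LN / (T_LN + F_PT)` and
#' `ACC = (T_PT + T_LN) / total`.
#'
#' @param ref,pred a [label_map()] pair, or equal-length lists of them whose
#'   voxel counts are pooled before the rates are computed.
#' @return list with `counts` (named vector `t_pt`, `f_pt`, `t_ln`, `f_ln`),
#'   `n` (total contingency voxels), `tpr_pt`, `tpr_ln`, `acc`.
#' @export
voxel_classification <- function(ref, pred) {
  if (inherits(ref, "label_map")) { ref <- list(ref); pred <- list(pred) }
  if (length(ref) != length(pred)) stop("paired lists differ in length")
  counts <- c(t_pt = 0, f_pt = 0, t_ln = 0, f_ln = 0)
  for (i in seq_along(ref)) {
    ra <- if (inherits(ref[[i]], "label_map")) ref[[i]]$labels else ref[[i]]
    pa <- if (inherits(pred[[i]], "label_map")) pred[[i]]$labels else pred[[i]]
    if (!identical(dim(ra), dim(pa))) stop("grids differ for pair ", i)
    sel <- ra > 0L & pa > 0L
    r <- ra[sel]; p <- pa[sel]
    counts["t_pt"] <- counts["t_pt"] + sum(r == 1L & p == 1L)
    counts["f_ln"] <- counts["f_ln"] + sum(r == 1L & p == 2L)
    counts["t_ln"] <- counts["t_ln"] + sum(r == 2L & p == 2L)
    counts["f_pt"] <- counts["f_pt"] + sum(r == 2L & p == 1L)
  }
  c(list(counts = counts, n = sum(counts)),
    classification_rates(counts["t_pt"], counts["f_pt"], counts["t_ln"],
                         counts["f_ln"]))
}

#' Classification rates from contingency counts
#'
#' `TPR_PT = T_PT / (T_PT + F_LN)`, `TPR_LN = T_LN / (T_LN + F_PT)`,
#' `ACC = (T_PT + T_LN) / (T_PT + F_PT + T_LN + F_LN)`. Accepts raw counts or
#' any proportional quantities (e.g. a contingency table normalized to 100%).
#'
#' @param t_pt,f_pt,t_ln,f_ln contingency entries: true/false primary-tumor
#'   and LN voxel counts.
#' @return list with `tpr_pt`, `tpr_ln`, `acc`.
#' @export
classification_rates <- function(t_pt, f_pt, t_ln, f_ln) {
  list(tpr_pt = unname(t_pt / (t_pt + f_ln)),
       tpr_ln = unname(t_ln / (t_ln + f_pt)),
       acc = unname((t_pt + t_ln) / (t_pt + f_pt + t_ln + f_ln)))
}

#' Structure-wise detection rates from lesion counts
#'
#' `TPR_str = TP_man / (TP_man + FN)` and `PPV_str = TP_cnn / (TP_cnn + FP)`.
#'
#' @param tp_man reference lesions covered at least 50% by the prediction.
#' @param tp_cnn predicted structures covered more than 50% by the reference.
#' @param fn missed reference lesions; `fp` spurious predicted structures.
#' @param fp see `fn`.
#' @return list with `tpr_str`, `ppv_str`.
#' @export
structure_rates <- function(tp_man, tp_cnn, fn, fp) {
  list(tpr_str = if (tp_man + fn > 0) tp_man / (tp_man + fn) else NA_real_,
       ppv_str = if (tp_cnn + fp > 0) tp_cnn / (tp_cnn + fp) else NA_real_)
}

#' Structure-wise lesion detection analysis
#'
#' Matches individual lesions (connected components) between reference and
#' prediction by coverage fraction. A reference lesion covered at least 50%
#' by the prediction for the same target counts as detected (`TP_man`),
#' otherwise as missed (`FN`); a predicted structure covered more than 50% by
#' the reference counts as `TP_cnn`, otherwise as a false positive (`FP`).
#' The asymmetric boundary treatment (>= 0.5 for reference lesions, > 0.5
#' for predicted structures) follows the analysis definition exactly. Rates:
#' `TPR_str = TP_man / (TP_man + FN)`, `PPV_str = TP_cnn / (TP_cnn + FP)`.
#' For the `union` target the masks are treated classlessly, so a primary
#' predicted as LN still covers the union lesion.
#'
#' @param ref,pred a [label_map()] pair or equal-length lists (pooled counts).
#' @param target `"primary"`, `"ln"`, or `"union"`.
#' @param connectivity component connectivity, 26 (default) or 6.
#' @return list with `tp_man`, `tp_cnn`, `fn`, `fp`, `tpr_str`, `ppv_str`,
#'   and per-lesion `ref_coverage` / `pred_coverage` fractions.
#' @export
structure_match <- function(ref, pred, target = c("union", "primary", "ln"),
                            connectivity = 26L) {
  target <- match.arg(target)
  if (inherits(ref, "label_map")) { ref <- list(ref); pred <- list(pred) }
  if (length(ref) != length(pred)) stop("paired lists differ in length")
  tp_man <- 0L; fn <- 0L; tp_cnn <- 0L; fp <- 0L
  ref_cov <- numeric(0); pred_cov <- numeric(0)
  for (i in seq_along(ref)) {
    a <- target_mask(ref[[i]], target)
    b <- target_mask(pred[[i]], target)
    if (!identical(dim(a), dim(b))) stop("grids differ for pair ", i)
    ca <- connected_components(a, connectivity)
    cb <- connected_components(b, connectivity)
    if (max(ca) > 0) for (k in seq_len(max(ca))) {
      lesion <- ca == k
      cov <- sum(lesion & b) / sum(lesion)
      ref_cov <- c(ref_cov, cov)
      if (cov >= 0.5) tp_man <- tp_man + 1L else fn <- fn + 1L
    }
    if (max(cb) > 0) for (k in seq_len(max(cb))) {
      strct <- cb == k
      cov <- sum(strct & a) / sum(strct)
      pred_cov <- c(pred_cov, cov)
      if (cov > 0.5) tp_cnn <- tp_cnn + 1L else fp <- fp + 1L
    }
  }
  c(list(tp_man = tp_man, tp_cnn = tp_cnn, fn = fn, fp = fp,
         ref_coverage = ref_cov, pred_coverage = pred_cov),
    structure_rates(tp_man, tp_cnn, fn, fp))
}

#' Total tumor burden of a label map
#'
#' Volume in ml of all voxels labeled as lesion (class 1 or 2). Apply
#' [filter_small_rois()] first if the analysis excludes sub-0.1 ml regions.
#'
#' @param labels a [label_map()].
#' @return Volume in ml.
#' @export
ttb <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  voxels_to_ml(sum(labels$labels > 0L), labels$geometry)
}

#' Agreement between manually and automatically derived TTB
#'
#' Rejects the `ceiling(n * outlier_fraction)` pairs with the largest
#' absolute TTB difference (default: the top 1%), then fits an ordinary
#' least-squares line of the automated on the manual values and reports the
#' coefficient of determination, coefficients, mean absolute difference over
#' the retained pairs, and the 95% prediction interval of the fit.
#'
#' @param ttb_man,ttb_cnn paired numeric vectors (ml), length >= 10.
#' @param outlier_fraction fraction of pairs to reject.
#' @return list with `r_squared`, `slope`, `intercept`, `mean_abs_diff`,
#'   `n_used`, `retained` (logical vector), and `prediction_interval`
#'   (data.frame `man`, `fit`, `lwr`, `upr` for the retained pairs).
#' @export
ttb_agreement <- function(ttb_man, ttb_cnn, outlier_fraction = 0.01) {
  n <- length(ttb_man)
  if (length(ttb_cnn) != n) stop("paired vectors differ in length")
  if (n < 10) stop("need at least 10 pairs")
  n_drop <- ceiling(n * outlier_fraction)
  adiff <- abs(ttb_cnn - ttb_man)
  drop_idx <- order(adiff, decreasing = TRUE)[seq_len(n_drop)]
  keep <- !(seq_len(n) %in% drop_idx)
  man <- ttb_man[keep]; cnn <- ttb_cnn[keep]
  if (stats::var(man) == 0) stop("manual TTB values are constant; regression is degenerate")
  fit <- stats::lm(cnn ~ man)
  # the band around the fitted line is reported as a tolerance interval for
  # new observations; evaluating it at the retained points is intentional
  pred <- suppressWarnings(stats::predict(fit, interval = "prediction",
                                          level = 0.95))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       mean_abs_diff = mean(abs(cnn - man)),
       n_used = sum(keep),
       retained = keep,
       prediction_interval = data.frame(man = man, fit = pred[, "fit"],
                                        lwr = pred[, "lwr"],
                                        upr = pred[, "upr"]))
}
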