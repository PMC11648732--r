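# Segmentation evaluation: Dice similarity (DSC), Normalized Surface Dice
# (NSD) at a distance tolerance, Hausdorff surface distance (HSD) and
# Normalized Average Volume Error (NAVE), computed per (case, class) with
# explicit conventions for degenerate cases: samples with empty ground truth
# are excluded as false positives; non-empty ground truth with an empty
# prediction is penalized with fixed worst-case values.
#
# Surface convention: a surface voxel is a foreground voxel with at least one
# background face-neighbour (the outside of the array counts as background);
# distances are Euclidean between surface-voxel centres in mm.

METRICS <- c("DSC", "NSD", "HSD", "NAVE")
METRIC_ORIENTATIONS <- c(DSC = "higher", NSD = "higher",
                         HSD = "lower", NAVE = "lower")

#' Metric conventions for degenerate cases
#'
#' False-negative penalties (non-empty ground truth, empty prediction):
#' DSC and NSD drop to 0.0, HSD is set to 260 mm (the craniocaudal height of
#' a lung, a worst-case surface distance) and NAVE to 20.0. Samples with an
#' empty ground truth (false positives) are excluded from all aggregates.
#'
#' @param nsd_tolerance surface tolerance in mm for NSD (default 1 mm).
#' @param fn_dsc,fn_nsd,fn_hsd,fn_nave false-negative penalty values.
#' @param fp_policy only `"exclude"` is implemented.
#' @param hsd_mode `"max"` (symmetric maximum surface distance) or `"p95"`
#'   (95th percentile of directed surface distances).
#' @param nave_mode normalization of the volume error: `"relative"` divides
#'   |Vpred - Vgt| by Vgt; `"mean"` divides by the mean of both volumes.
#' @return an object of class `fsb_conventions`.
#' @export
metric_conventions <- function(nsd_tolerance = 1.0, fn_dsc = 0.0,
                               fn_nsd = 0.0, fn_hsd = 260.0, fn_nave = 20.0,
                               fp_policy = "exclude",
                               hsd_mode = c("max", "p95"),
                               nave_mode = c("relative", "mean")) {
  abort_if(nsd_tolerance <= 0, "nsd_tolerance must be positive")
  abort_if(!identical(fp_policy, "exclude"),
           "only the exclude policy for empty ground truth is supported")
  structure(list(nsd_tolerance = nsd_tolerance, fn_dsc = fn_dsc,
                 fn_nsd = fn_nsd, fn_hsd = fn_hsd, fn_nave = fn_nave,
                 fp_policy = fp_policy, hsd_mode = match.arg(hsd_mode),
                 nave_mode = match.arg(nave_mode)),
            class = "fsb_conventions")
}

#' @export
print.fsb_conventions <- function(x, ...) {
  cat(sprintf(
    paste0("<metric conventions>: NSD tolerance %g mm; FN penalties ",
           "DSC=%g NSD=%g HSD=%g mm NAVE=%g; empty ground truth %sd; ",
           "HSD mode %s; NAVE mode %s\n"),
    x$nsd_tolerance, x$fn_dsc, x$fn_nsd, x$fn_hsd, x$fn_nave, x$fp_policy,
    x$hsd_mode, x$nave_mode))
  invisible(x)
}

#' Classify a (ground truth, prediction) pair for one class
#'
#' @param gt_mask,pred_mask binary (logical or 0/1 integer) masks of the same
#'   shape.
#' @return `"fp_excluded"` if the ground truth is empty (regardless of the
#'   prediction), `"fn_penalized"` if the ground truth is non-empty but the
#'   prediction is empty, `"computed"` otherwise.
#' @export
classify_case <- function(gt_mask, pred_mask) {
  abort_if(!identical(dim(gt_mask), dim(pred_mask)),
           "ground truth and prediction shapes differ")
  if (!any(gt_mask != 0)) return("fp_excluded")
  if (!any(pred_mask != 0)) return("fn_penalized")
  "computed"
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` over foreground voxels.
#'
#' @inheritParams classify_case
#' @return value in \[0, 1\].
#' @export
dsc <- function(gt_mask, pred_mask) {
  a <- gt_mask != 0
  b <- pred_mask != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

surface_coords_mm <- function(mask, spacing) {
  sv <- surface_voxels(as.integer(mask != 0), dim(mask))
  sweep(matrix(as.numeric(sv), ncol = 3), 2, as.numeric(spacing), `*`)
}

directed_surface_distances <- function(gt_mask, pred_mask, spacing) {
  a <- surface_coords_mm(gt_mask, spacing)
  b <- surface_coords_mm(pred_mask, spacing)
  list(gt_to_pred = nn_distances(a, b), pred_to_gt = nn_distances(b, a))
}

#' Normalized surface Dice
#'
#' Symmetric fraction of surface voxels of each mask lying within
#' `tolerance` mm of the other mask's surface.
#'
#' @inheritParams classify_case
#' @param spacing voxel spacing in mm.
#' @param tolerance distance tolerance in mm (default 1).
#' @return value in \[0, 1\].
#' @export
nsd <- function(gt_mask, pred_mask, spacing, tolerance = 1.0) {
  abort_if(tolerance <= 0, "tolerance must be positive")
  d <- directed_surface_distances(gt_mask, pred_mask, spacing)
  (sum(d$gt_to_pred <= tolerance) + sum(d$pred_to_gt <= tolerance)) /
    (length(d$gt_to_pred) + length(d$pred_to_gt))
}

#' Hausdorff surface distance
#'
#' Symmetric worst-case (or, with `mode = "p95"`, 95th-percentile) distance
#' between the two masks' surfaces, in mm.
#'
#' @inheritParams nsd
#' @param mode `"max"` or `"p95"`.
#' @return nonnegative length in mm.
#' @export
hsd <- function(gt_mask, pred_mask, spacing, mode = c("max", "p95")) {
  mode <- match.arg(mode)
  d <- directed_surface_distances(gt_mask, pred_mask, spacing)
  if (mode == "max") {
    max(max(d$gt_to_pred), max(d$pred_to_gt))
  } else {
    max(quantile(d$gt_to_pred, 0.95, names = FALSE),
        quantile(d$pred_to_gt, 0.95, names = FALSE))
  }
}

#' Normalized average volume error
#'
#' Absolute difference of predicted and annotated physical volumes,
#' normalized by the annotated volume (`mode = "relative"`, the default) or
#' by the mean of the two volumes (`mode = "mean"`). The voxel volume cancels
#' in both, so the value is invariant to uniform spacing changes.
#'
#' @inheritParams nsd
#' @param mode normalization mode.
#' @return nonnegative ratio.
#' @export
nave <- function(gt_mask, pred_mask, spacing, mode = c("relative", "mean")) {
  mode <- match.arg(mode)
  vg <- sum(gt_mask != 0) * prod(spacing)
  vp <- sum(pred_mask != 0) * prod(spacing)
  if (mode == "relative") abs(vp - vg) / vg else
    abs(vp - vg) / ((vp + vg) / 2)
}

# one (case, class) record set over the four metrics
metric_records_one <- function(gt_mask, pred_mask, spacing, conv,
                               site, case, class_name) {
  status <- classify_case(gt_mask, pred_mask)
  vals <- switch(status,
    fp_excluded = rep(NA_real_, 4),
    fn_penalized = c(conv$fn_dsc, conv$fn_nsd, conv$fn_hsd, conv$fn_nave),
    computed = c(dsc(gt_mask, pred_mask),
                 nsd(gt_mask, pred_mask, spacing, conv$nsd_tolerance),
                 hsd(gt_mask, pred_mask, spacing, conv$hsd_mode),
                 nave(gt_mask, pred_mask, spacing, conv$nave_mode)))
  data.frame(site = site, case = case, class = class_name, metric = METRICS,
             value = vals, status = status, stringsAsFactors = FALSE)
}

#' Evaluate predicted masks against ground truth on one site
#'
#' For each test case and each pathology class independently: classify the
#' (ground truth, prediction) pair, then either compute the four metrics,
#' assign the false-negative penalties, or exclude the sample (empty ground
#' truth). Per-metric means are taken over exactly the non-excluded
#' (case, class) records.
#'
#' @param gt_masks list of ground-truth label masks.
#' @param pred_masks list of predicted label masks (same order and shapes).
#' @param spacing voxel spacing in mm of the evaluation grid.
#' @param conventions an [metric_conventions()] object.
#' @param site site id for bookkeeping.
#' @param case_ids optional case ids.
#' @return an object of class `fsb_metric_eval`: `records` (tidy data.frame),
#'   `means` (named per-metric means), `n_test`, `n_classes`, and the
#'   conventions used.
#' @export
evaluate_predictions <- function(gt_masks, pred_masks, spacing,
                                 conventions = metric_conventions(),
                                 site = "site", case_ids = NULL) {
  abort_if(length(gt_masks) != length(pred_masks),
           sprintf("missing prediction: %d ground-truth cases but %d predictions",
                   length(gt_masks), length(pred_masks)))
  if (is.null(case_ids))
    case_ids <- sprintf("%s-%03d", site, seq_along(gt_masks))
  recs <- list()
  for (i in seq_along(gt_masks)) {
    for (cn in names(CLASS_LABELS)) {
      lab <- CLASS_LABELS[[cn]]
      recs[[length(recs) + 1L]] <- metric_records_one(
        gt_masks[[i]] == lab, pred_masks[[i]] == lab, spacing, conventions,
        site, case_ids[i], cn)
    }
  }
  records <- do.call(rbind, recs)
  structure(list(records = records,
                 means = metric_means(records),
                 n_test = length(gt_masks),
                 n_classes = length(CLASS_LABELS),
                 conventions = conventions,
                 site = site),
            class = "fsb_metric_eval")
}

#' Per-metric means over non-excluded records
#'
#' @param records a tidy record data.frame as produced by
#'   [evaluate_predictions()].
#' @return named numeric vector over DSC, NSD, HSD, NAVE.
#' @export
metric_means <- function(records) {
  kept <- records[records$status != "fp_excluded", , drop = FALSE]
  vapply(METRICS, function(m) {
    v <- kept$value[kept$metric == m]
    if (length(v)) mean(v) else NA_real_
  }, 0)
}

#' @export
print.fsb_metric_eval <- function(x, ...) {
  cat(sprintf("<metric evaluation @ site %s>: %d cases x %d classes\n",
              x$site, x$n_test, x$n_classes))
  print(round(x$means, 4))
  ex <- sum(x$records$status == "fp_excluded") / length(METRICS)
  fn <- sum(x$records$status == "fn_penalized") / length(METRICS)
  cat(sprintf("  (%d sample(s) FP-excluded, %d FN-penalized)\n", ex, fn))
  invisible(x)
}

#' Evaluate one benchmark method on a site's test split
#'
#' Assembles the method's probability map per test case from a registry of
#' per-model probability maps, decodes it with [predict_segmentation()], and
#' scores it with [evaluate_predictions()].
#'
#' @param method an `fsb_method_spec` from [build_method_table()].
#' @param test_cases preprocessed test `fsb_site_dataset` of the evaluation
#'   site.
#' @param model_maps_per_case list (one element per test case) of named lists
#'   of `fsb_prob_map`s keyed by model id.
#' @param conventions an [metric_conventions()] object.
#' @return an `fsb_metric_eval`.
#' @export
evaluate_method_on_site <- function(method, test_cases, model_maps_per_case,
                                    conventions = metric_conventions()) {
  preds <- lapply(seq_along(test_cases$volumes), function(i) {
    predict_segmentation(method_prob_map(method, model_maps_per_case[[i]]))
  })
  evaluate_predictions(test_cases$masks, preds,
                       test_cases$preprocessed_spacing %||%
                         test_cases$profile$voxel_spacing,
                       conventions, site = method$evaluation_site,
                       case_ids = test_cases$case_ids)
}
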