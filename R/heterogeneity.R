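# Distributed-data characterization: per-site voxel volumes, shared-bin
# intensity histograms, per-class case prevalence and annotation volumes, and
# connected-component analysis (CCA) of the annotations. CC counts per
# annotation label are the signature separating manual from automatically
# pre-processed annotation styles.

#' Connected components of a binary 3D mask
#'
#' Counts maximal connected foreground components under 26-neighbourhood
#' (default) or 6-neighbourhood (face) connectivity.
#'
#' @param mask binary (logical or 0/1) 3D array.
#' @param connectivity 26 or 6.
#' @return list with `count`, `sizes` (voxels per component, in discovery
#'   order) and `labels` (integer array, 0 = background).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  abort_if(!connectivity %in% c(6L, 26L), "connectivity must be 6 or 26")
  abort_if(length(dim(mask)) != 3, "mask must be a 3D array")
  res <- cc_label3d(as.integer(mask != 0), dim(mask), as.integer(connectivity))
  list(count = res$n_components, sizes = as.integer(res$sizes),
       labels = array(res$labels, dim = dim(mask)))
}

#' Summarize the heterogeneity of multiple site datasets
#'
#' Computes, per site: the voxel volume (mm^3), an intensity histogram over
#' bin edges shared across all sites (mass sums to 1 per site), per-class
#' case prevalence, per-class annotation volumes (mm^3 per case) and
#' per-class connected-component counts per case.
#'
#' @param datasets list of `fsb_site_dataset`s.
#' @param n_bins number of shared intensity-histogram bins.
#' @param connectivity CCA connectivity (26 or 6).
#' @return a list of class `fsb_site_summaries`, one `fsb_site_summary` per
#'   site, with the shared `bin_edges` as an attribute.
#' @export
summarize_sites <- function(datasets, n_bins = 64L, connectivity = 26L) {
  abort_if(length(datasets) < 1L, "need at least one site dataset")
  rng <- range(unlist(lapply(datasets, function(d)
    range(vapply(d$volumes, range, numeric(2))))))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  out <- lapply(datasets, function(d) {
    vv <- prod(d$profile$voxel_spacing)
    counts <- rep(0, n_bins)
    for (v in d$volumes) {
      h <- hist(as.vector(v), breaks = edges, plot = FALSE)
      counts <- counts + h$counts
    }
    prev <- vapply(names(CLASS_LABELS), function(cn)
      mean(case_has_class(d, CLASS_LABELS[[cn]])), 0)
    vols <- lapply(names(CLASS_LABELS), function(cn)
      vapply(d$masks, function(m) sum(m == CLASS_LABELS[[cn]]) * vv, 0))
    ccs <- lapply(names(CLASS_LABELS), function(cn)
      vapply(d$masks, function(m)
        connected_components(m == CLASS_LABELS[[cn]],
                             connectivity)$count, 0L))
    structure(list(
      site_id = d$profile$site_id,
      n_cases = length(d$volumes),
      voxel_volume = vv,
      annotation_style = d$profile$annotation_style,
      intensity_histogram = counts / sum(counts),
      class_prevalence = prev,
      annotation_volumes = setNames(vols, names(CLASS_LABELS)),
      cc_counts = setNames(ccs, names(CLASS_LABELS))
    ), class = "fsb_site_summary")
  })
  structure(setNames(out, vapply(datasets, function(d)
    d$profile$site_id, "")), bin_edges = edges, class = "fsb_site_summaries")
}

#' @export
print.fsb_site_summary <- function(x, ...) {
  cat(sprintf(
    "<site summary '%s'>: %d cases, voxel %.3g mm^3, style %s\n",
    x$site_id, x$n_cases, x$voxel_volume, x$annotation_style))
  cat(sprintf("  prevalence: %s\n",
              paste(sprintf("%s %.2f", names(x$class_prevalence),
                            x$class_prevalence), collapse = ", ")))
  cat(sprintf("  mean CC per case: %s\n",
              paste(sprintf("%s %.1f", names(x$cc_counts),
                            vapply(x$cc_counts, mean, 0)), collapse = ", ")))
  invisible(x)
}

#' @export
print.fsb_site_summaries <- function(x, ...) {
  for (s in x) print(s)
  invisible(x)
}

#' Tabulate site summaries
#'
#' @param summaries an `fsb_site_summaries`.
#' @return a data.frame with one row per site: voxel volume, style, per-class
#'   prevalence, mean annotation volumes and mean CC counts.
#' @export
summaries_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(site = s$site_id, n_cases = s$n_cases,
               voxel_volume_mm3 = s$voxel_volume,
               style = s$annotation_style,
               prev_cons = s$class_prevalence[["cons"]],
               prev_ggo = s$class_prevalence[["ggo"]],
               prev_pe = s$class_prevalence[["pe"]],
               mean_vol_cons_mm3 = mean(s$annotation_volumes$cons),
               mean_vol_ggo_mm3 = mean(s$annotation_volumes$ggo),
               mean_vol_pe_mm3 = mean(s$annotation_volumes$pe),
               mean_cc_cons = mean(s$cc_counts$cons),
               mean_cc_ggo = mean(s$cc_counts$ggo),
               mean_cc_pe = mean(s$cc_counts$pe),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Plot site-heterogeneity panels
#'
#' Four panels: voxel volumes, shared-bin intensity histograms, per-class
#' prevalence and per-class mean connected-component counts.
#'
#' @param summaries an `fsb_site_summaries`.
#' @param file optional PDF path; if `NULL`, plots to the active device.
#' @return invisibly, the summary table.
#' @export
plot_site_summaries <- function(summaries, file = NULL) {
  tb <- summaries_table(summaries)
  if (!is.null(file)) {
    pdf(file, width = 9, height = 7)
    on.exit(dev.off())
  }
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op), add = TRUE)
  graphics::barplot(tb$voxel_volume_mm3, names.arg = tb$site,
                    main = "voxel volume (mm^3)", col = "grey60")
  edges <- attr(summaries, "bin_edges")
  mids <- (head(edges, -1) + edges[-1]) / 2
  graphics::matplot(mids, vapply(summaries, `[[`,
                                 numeric(length(mids)),
                                 "intensity_histogram"),
                    type = "l", lty = 1, xlab = "normalized intensity",
                    ylab = "mass", main = "intensity histograms")
  graphics::matplot(t(as.matrix(tb[, c("prev_cons", "prev_ggo", "prev_pe")])),
                    type = "b", pch = 1, lty = 1, xaxt = "n",
                    ylab = "case prevalence", main = "class prevalence")
  axis(1, at = 1:3, labels = c("cons", "ggo", "pe"))
  graphics::matplot(t(as.matrix(tb[, c("mean_cc_cons", "mean_cc_ggo",
                                       "mean_cc_pe")])),
                    type = "b", pch = 1, lty = 1, xaxt = "n",
                    ylab = "mean CC per case", main = "CCA")
  axis(1, at = 1:3, labels = c("cons", "ggo", "pe"))
  invisible(tb)
}
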