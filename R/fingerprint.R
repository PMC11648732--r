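# Dataset fingerprints and cross-site model configuration. Each site computes
# summary statistics of its *training* cases only; a server-side aggregation
# pools them case-count-weighted into a global fingerprint, from which every
# site derives a byte-identical model configuration (the federated analogue of
# a self-configuring segmentation pipeline).

#' Compute a site's dataset fingerprint
#'
#' Statistics are computed over the supplied cases only, which by convention
#' are the site's training cases: pass the result of
#' `subset_split(dataset, "train")` so test data can never leak into the
#' configuration. Foreground is defined as voxels with mask label > 0.
#'
#' @param train_cases an `fsb_site_dataset` holding the training subset.
#' @return an object of class `fsb_fingerprint`.
#' @export
compute_fingerprint <- function(train_cases) {
  abort_if(!inherits(train_cases, "fsb_site_dataset"), "not a site dataset")
  n <- length(train_cases$volumes)
  abort_if(n < 1L, "fingerprint requires at least one training case")
  fg <- unlist(lapply(seq_len(n), function(i) {
    train_cases$volumes[[i]][train_cases$masks[[i]] > 0]
  }), use.names = FALSE)
  abort_if(length(fg) == 0L, "no foreground voxels in training cases")
  shapes <- vapply(train_cases$volumes, dim, integer(3))
  pc <- quantile(fg, probs = c(0.005, 0.995), names = FALSE, type = 7)
  structure(list(
    site_id = train_cases$profile$site_id,
    n_cases = n,
    spacing_median = train_cases$profile$voxel_spacing,
    intensity_percentiles = pc,
    intensity_mean = mean(fg),
    intensity_sd = if (length(fg) > 1) sd(fg) else 0,
    shape_median = apply(shapes, 1, median)
  ), class = "fsb_fingerprint")
}

#' @export
print.fsb_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<fingerprint '%s'>: %d cases, spacing (%s), intensity %.3f +/- %.3f\n",
    x$site_id, x$n_cases, paste(format(x$spacing_median), collapse = ", "),
    x$intensity_mean, x$intensity_sd))
  invisible(x)
}

#' Aggregate site fingerprints into a global fingerprint
#'
#' Server-side pooling: all statistics are case-count-weighted combinations of
#' the site statistics (weighted mean of means and percentiles; pooled
#' standard deviation via the weighted second moment; weighted means of the
#' per-site median spacings and shapes). The result is a deterministic,
#' order-independent function of the multiset of fingerprints: inputs are
#' sorted by site id before any arithmetic.
#'
#' @param fps list of [compute_fingerprint()] results.
#' @return an object of class `fsb_global_fingerprint`.
#' @export
aggregate_fingerprints <- function(fps) {
  abort_if(length(fps) < 1L, "need at least one fingerprint")
  ids <- vapply(fps, `[[`, "", "site_id")
  abort_if(anyDuplicated(ids) > 0,
           "duplicate site_id among fingerprints")
  fps <- fps[order(ids)]
  w <- vapply(fps, `[[`, 0L, "n_cases")
  wn <- w / sum(w)
  wmean <- function(field) {
    vals <- vapply(fps, function(f) as.numeric(f[[field]]),
                   numeric(length(fps[[1]][[field]])))
    if (is.null(dim(vals))) sum(vals * wn) else as.numeric(vals %*% wn)
  }
  mu <- wmean("intensity_mean")
  second <- sum(wn * vapply(fps, function(f)
    f$intensity_sd^2 + f$intensity_mean^2, 0))
  structure(list(
    contributing_sites = sort(ids),
    n_cases = sum(w),
    spacing_median = wmean("spacing_median"),
    intensity_percentiles = wmean("intensity_percentiles"),
    intensity_mean = mu,
    intensity_sd = sqrt(max(second - mu^2, 0)),
    shape_median = wmean("shape_median")
  ), class = "fsb_global_fingerprint")
}

#' @export
print.fsb_global_fingerprint <- function(x, ...) {
  cat(sprintf("<global fingerprint>: %d cases from sites {%s}\n",
              x$n_cases, paste(x$contributing_sites, collapse = ", ")))
  invisible(x)
}

#' Derive the shared model configuration from a global fingerprint
#'
#' A pure, rule-based mapping: identical global fingerprints yield byte-equal
#' serialized configurations, which is what lets every federated site build
#' the same model without sharing data. The low-resolution regime coarsens the
#' pooled median spacing by a factor of 2. `scale = "paper"` uses the
#' full-scale training schedule (1000 epochs of 250 batches); `scale = "desk"`
#' uses a small schedule suitable for CPU-minutes experiments.
#'
#' @param gfp an `fsb_global_fingerprint`.
#' @param scale `"desk"` or `"paper"`.
#' @return an object of class `fsb_model_config` with a `config_hash` field.
#' @export
configure_model <- function(gfp, scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  abort_if(!inherits(gfp, "fsb_global_fingerprint"),
           "gfp must come from aggregate_fingerprints()")
  target_spacing <- 2 * gfp$spacing_median
  est_shape <- gfp$shape_median * gfp$spacing_median / target_spacing
  cap <- if (scale == "desk") 8L else 32L
  pdim <- max(4L, min(cap, 2L^floor(log2(min(est_shape)))))
  cfg <- list(
    target_spacing = as.numeric(target_spacing),
    patch_size = rep(as.integer(pdim), 3L),
    n_channels_base = if (scale == "desk") 4L else 32L,
    n_classes = 4L,
    normalization = list(
      clip_lo = as.numeric(gfp$intensity_percentiles[1]),
      clip_hi = as.numeric(gfp$intensity_percentiles[2]),
      mean = gfp$intensity_mean,
      sd = max(gfp$intensity_sd, 1e-8)
    ),
    epochs = if (scale == "desk") 5L else 1000L,
    batches_per_epoch = if (scale == "desk") 100L else 250L,
    batch_size = 2L,
    learning_rate = 0.05,
    momentum = 0.8,
    clip_grad_norm = 1.0,
    foreground_oversample = 0.5,
    scale = scale
  )
  cfg$config_hash <- object_digest(as.character(canonical_json(
    cfg[setdiff(names(cfg), "config_hash")])))
  class(cfg) <- "fsb_model_config"
  cfg
}

#' Serialize a model configuration canonically
#'
#' Sorted-key JSON, so that byte equality of the string is a meaningful test
#' of configuration identity across sites.
#'
#' @param config an `fsb_model_config`.
#' @return a JSON character scalar.
#' @export
serialize_config <- function(config) {
  as.character(canonical_json(unclass(config)))
}

#' @export
print.fsb_model_config <- function(x, ...) {
  cat(sprintf(
    paste0("<model config [%s]>: target spacing (%s) mm, patch %s, ",
           "%d base channels, %d epochs x %d batches (hash %s)\n"),
    x$scale, paste(format(round(x$target_spacing, 3)), collapse = ", "),
    paste(x$patch_size, collapse = "x"), x$n_channels_base, x$epochs,
    x$batches_per_epoch, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Resample and normalize one case to the shared configuration
#'
#' The volume is resampled to the configured target spacing with trilinear
#' interpolation and the mask with nearest-label lookup; intensities are then
#' clipped to the configured percentile window and standardized by the
#' configured mean and standard deviation.
#'
#' @param volume 3D numeric array.
#' @param mask 3D integer label array of the same shape.
#' @param spacing the case's voxel spacing in mm.
#' @param config an `fsb_model_config`.
#' @return list with elements `volume`, `mask` and `spacing`
#'   (= `config$target_spacing`).
#' @export
preprocess_case <- function(volume, mask, spacing, config) {
  abort_if(length(spacing) != 3 || any(!is.finite(spacing)) ||
             any(spacing <= 0), "degenerate voxel spacing")
  abort_if(!identical(dim(volume), dim(mask)),
           "volume and mask shapes disagree")
  odim <- pmax(1L, as.integer(round(dim(volume) * spacing /
                                      config$target_spacing)))
  v <- resample_trilinear(volume, dim(volume), as.numeric(spacing),
                          config$target_spacing, odim)
  m <- resample_nearest(as.integer(mask), dim(mask), as.numeric(spacing),
                        config$target_spacing, odim)
  nz <- config$normalization
  v <- pmin(pmax(v, nz$clip_lo), nz$clip_hi)
  v <- (v - nz$mean) / nz$sd
  dim(v) <- odim
  dim(m) <- odim
  list(volume = v, mask = m, spacing = as.numeric(config$target_spacing))
}

#' Preprocess every case of a site dataset
#'
#' @param dataset an `fsb_site_dataset`.
#' @param config an `fsb_model_config`.
#' @return the dataset with volumes/masks resampled and normalized; the
#'   effective spacing is recorded in `preprocessed_spacing`.
#' @export
preprocess_dataset <- function(dataset, config) {
  for (i in seq_along(dataset$volumes)) {
    pc <- preprocess_case(dataset$volumes[[i]], dataset$masks[[i]],
                          dataset$profile$voxel_spacing, config)
    dataset$volumes[[i]] <- pc$volume
    dataset$masks[[i]] <- pc$mask
  }
  dataset$preprocessed_spacing <- as.numeric(config$target_spacing)
  dataset
}
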