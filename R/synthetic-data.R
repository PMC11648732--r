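# Multi-site synthetic 3D segmentation phantoms. Each site generates chest-like
# volumes: an ellipsoidal "lung" region containing blob-shaped lesions of up to
# three pathology classes (1 = consolidation, 2 = ground-glass opacity,
# 3 = pleural effusion), with per-site voxel spacing, intensity shift/noise,
# class prevalence and annotation fragmentation controlling the inter-site
# heterogeneity that real multi-centre cohorts show.

CLASS_LABELS <- c(cons = 1L, ggo = 2L, pe = 3L)

# normalized tissue intensity levels before site shift/noise
.INTENSITY <- c(outside = 0.0, lung = 0.25, cons = 0.65, ggo = 0.45, pe = 0.85)

#' Describe one site of a synthetic federation
#'
#' A site profile fixes everything the generator needs: cohort size, voxel
#' spacing (and hence voxel volume, the dominant scanner difference between
#' sites), an additive intensity shift and noise level in normalized intensity
#' units, per-class prevalence (probability a case contains the class), and the
#' annotation style. Sites with `annotation_style = "auto"` emulate
#' automatically pre-processed annotations by scattering `fragmentation_level`
#' extra small connected components per present class; manual sites have
#' `fragmentation_level = 0`.
#'
#' @param site_id short site label.
#' @param n_cases number of cases to generate.
#' @param voxel_spacing numeric length-3, voxel spacing in mm.
#' @param intensity_shift additive offset in normalized intensity units.
#' @param intensity_noise_sd nonnegative noise standard deviation.
#' @param class_prevalence named or unnamed length-3 probabilities for
#'   (consolidation, ground-glass opacity, pleural effusion). Pleural effusion
#'   is the least prevalent class in the default profiles.
#' @param annotation_style `"manual"` or `"auto"`.
#' @param fragmentation_level nonnegative integer; extra connected components
#'   per present class for auto-style sites. Must be 0 for manual style.
#' @param shape integer length-3 volume shape in voxels.
#' @param rng_seed integer seed making the site reproducible.
#' @return an object of class `fsb_site_profile`.
#' @export
site_profile <- function(site_id, n_cases = 10L,
                         voxel_spacing = c(1, 1, 1),
                         intensity_shift = 0, intensity_noise_sd = 0.04,
                         class_prevalence = c(cons = 0.9, ggo = 0.8, pe = 0.45),
                         annotation_style = c("manual", "auto"),
                         fragmentation_level = 0L,
                         shape = c(48L, 48L, 48L),
                         rng_seed = 1L) {
  annotation_style <- match.arg(annotation_style)
  n_cases <- as.integer(n_cases)
  abort_if(is.na(n_cases) || n_cases < 1L,
           "invalid profile: n_cases must be a positive integer")
  abort_if(length(voxel_spacing) != 3 || any(!is.finite(voxel_spacing)) ||
             any(voxel_spacing <= 0),
           "invalid profile: voxel_spacing must be 3 positive lengths (mm)")
  abort_if(length(class_prevalence) != 3 ||
             any(class_prevalence < 0) || any(class_prevalence > 1),
           "invalid profile: class_prevalence must be 3 probabilities")
  abort_if(intensity_noise_sd < 0,
           "invalid profile: intensity_noise_sd must be nonnegative")
  fragmentation_level <- as.integer(fragmentation_level)
  abort_if(fragmentation_level < 0,
           "invalid profile: fragmentation_level must be nonnegative")
  abort_if(annotation_style == "manual" && fragmentation_level != 0L,
           "invalid profile: manual style requires fragmentation_level = 0")
  abort_if(length(shape) != 3 || any(shape < 8),
           "invalid profile: shape must be 3 dimensions of at least 8 voxels")
  structure(list(
    site_id = as.character(site_id),
    n_cases = n_cases,
    voxel_spacing = as.numeric(voxel_spacing),
    intensity_shift = as.numeric(intensity_shift),
    intensity_noise_sd = as.numeric(intensity_noise_sd),
    class_prevalence = setNames(as.numeric(class_prevalence),
                                names(CLASS_LABELS)),
    annotation_style = annotation_style,
    fragmentation_level = fragmentation_level,
    shape = as.integer(shape),
    rng_seed = as.integer(rng_seed)
  ), class = "fsb_site_profile")
}

#' @export
print.fsb_site_profile <- function(x, ...) {
  cat(sprintf(
    "<site profile '%s'>: %d cases, spacing (%s) mm (voxel %.3g mm^3), %s%s\n",
    x$site_id, x$n_cases, paste(format(x$voxel_spacing), collapse = ", "),
    prod(x$voxel_spacing), x$annotation_style,
    if (x$annotation_style == "auto")
      sprintf(" (fragmentation %d)", x$fragmentation_level) else ""))
  invisible(x)
}

#' Default heterogeneous site profiles
#'
#' Six sites in two annotation-style groups of three: a "manual" trio
#' (A, B, C) and an "auto" trio (D, E, F) with nonzero fragmentation. Voxel
#' volumes span 0.15 mm^3 (site E) to 4.84 mm^3 (site B), pleural effusion is
#' the least prevalent class everywhere, and intensity shift/noise differ
#' mildly between sites.
#'
#' @param n_cases cases per site.
#' @param sites which site labels to return (default: the manual trio,
#'   the default desk-scale federation).
#' @param seed master seed; each site derives its own stream from it.
#' @return a named list of [site_profile()] objects.
#' @export
default_site_profiles <- function(n_cases = 10L,
                                  sites = c("A", "B", "C"),
                                  seed = 20L) {
  # Voxel volumes span 0.15 (site E) to 4.84 mm^3 (site B); intensity
  # shifts are small because normalized intensity distributions are similar
  # across sites; the auto trio carries the annotation fragmentation.
  specs <- list(
    A = list(sp = c(0.8, 0.8, 1.5), shift = 0.00, noise = 0.030,
             style = "manual", frag = 0L,
             prev = c(cons = 0.90, ggo = 0.80, pe = 0.45)),
    B = list(sp = c(2.2, 2.2, 1.0), shift = 0.01, noise = 0.040,
             style = "manual", frag = 0L,
             prev = c(cons = 0.85, ggo = 0.85, pe = 0.50)),
    C = list(sp = c(1.0, 1.0, 1.0), shift = -0.01, noise = 0.035,
             style = "manual", frag = 0L,
             prev = c(cons = 0.90, ggo = 0.75, pe = 0.40)),
    D = list(sp = c(1.2, 1.2, 1.5), shift = 0.01, noise = 0.045,
             style = "auto", frag = 3L,
             prev = c(cons = 0.90, ggo = 0.80, pe = 0.50)),
    E = list(sp = c(0.5, 0.5, 0.6), shift = -0.01, noise = 0.030,
             style = "auto", frag = 4L,
             prev = c(cons = 0.85, ggo = 0.80, pe = 0.45)),
    F = list(sp = c(0.9, 0.9, 1.2), shift = 0.01, noise = 0.040,
             style = "auto", frag = 2L,
             prev = c(cons = 0.90, ggo = 0.85, pe = 0.40))
  )
  abort_if(!all(sites %in% names(specs)),
           "unknown site labels; available sites are A-F")
  out <- lapply(sites, function(s) {
    sp <- specs[[s]]
    site_profile(site_id = s, n_cases = n_cases, voxel_spacing = sp$sp,
                 intensity_shift = sp$shift, intensity_noise_sd = sp$noise,
                 class_prevalence = sp$prev, annotation_style = sp$style,
                 fragmentation_level = sp$frag,
                 rng_seed = derive_seed(seed, "site", s))
  })
  setNames(out, sites)
}

# Smooth random blob field: white noise on a coarse grid (physical correlation
# length `corr_mm`), trilinearly upsampled to the case grid.
blob_field <- function(shape, spacing, corr_mm = 10) {
  extent <- shape * spacing
  cdim <- pmax(2L, as.integer(ceiling(extent / corr_mm)) + 1L)
  coarse <- array(rnorm(prod(cdim)), dim = cdim)
  resample_trilinear(coarse, cdim, rep(corr_mm, 3), spacing, as.integer(shape))
}

# Choose the top `frac` of `field` inside `region`; guarantee >= min_vox voxels
blob_mask <- function(field, region, frac, min_vox = 8L) {
  vals <- field[region]
  if (!length(vals)) return(array(FALSE, dim = dim(field)))
  thr <- quantile(vals, probs = 1 - frac, names = FALSE, type = 7)
  sel <- region & field >= thr
  if (sum(sel) < min_vox) {
    idx <- which(region)
    top <- idx[order(field[idx], decreasing = TRUE)[seq_len(min(min_vox,
                                                                length(idx)))]]
    sel <- array(FALSE, dim = dim(field))
    sel[top] <- TRUE
  }
  sel
}

# One case: lung ellipsoid, per-class blobs, style-dependent fragmentation,
# then intensities. Base anatomy/annotation RNG is independent of the
# fragmentation RNG so that manual/auto twins share the same base masks.
generate_case <- function(profile, case_idx) {
  shape <- profile$shape
  sp <- profile$voxel_spacing
  base_seed <- derive_seed(profile$rng_seed, "case", case_idx, "base")
  mask <- with_seed(base_seed, {
    ax <- seq_len(shape[1]) - (shape[1] + 1) / 2
    ay <- seq_len(shape[2]) - (shape[2] + 1) / 2
    az <- seq_len(shape[3]) - (shape[3] + 1) / 2
    semi <- shape * runif(3, 0.36, 0.42)
    e <- outer(outer((ax / semi[1])^2, (ay / semi[2])^2, `+`),
               (az / semi[3])^2, `+`)
    lung <- e <= 1
    kk <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]),
                dim = shape)
    present <- runif(3) < profile$class_prevalence
    if (!any(present)) { # cohort design: every scan contains pathologies
      pick <- sample.int(3, 1, prob = pmax(profile$class_prevalence, 1e-6))
      present[pick] <- TRUE
    }
    m <- array(0L, dim = shape)
    for (cls in which(present)) {
      if (cls == CLASS_LABELS[["pe"]]) {
        # pleural effusion pools as a contiguous layer in the dependent
        # (bottom) part of the lung
        ks <- range(kk[lung])
        depth <- ks[1] + runif(1, 0.10, 0.30) * (ks[2] - ks[1])
        sel <- lung & kk <= depth
      } else {
        fld <- blob_field(shape, sp)
        sel <- blob_mask(fld, lung, frac = runif(1, 0.04, 0.10))
      }
      m[sel] <- as.integer(cls)
    }
    attr(m, "lung") <- lung
    m
  })
  lung <- attr(mask, "lung")
  attr(mask, "lung") <- NULL
  if (profile$annotation_style == "auto" && profile$fragmentation_level > 0) {
    frag_seed <- derive_seed(profile$rng_seed, "case", case_idx, "frag")
    mask <- with_seed(frag_seed,
                      fragment_mask(mask, lung, profile$fragmentation_level))
  }
  vol_seed <- derive_seed(profile$rng_seed, "case", case_idx, "intensity")
  vol <- with_seed(vol_seed, {
    lev <- array(.INTENSITY[["outside"]], dim = shape)
    lev[lung] <- .INTENSITY[["lung"]]
    lev[mask == CLASS_LABELS[["cons"]]] <- .INTENSITY[["cons"]]
    lev[mask == CLASS_LABELS[["ggo"]]] <- .INTENSITY[["ggo"]]
    lev[mask == CLASS_LABELS[["pe"]]] <- .INTENSITY[["pe"]]
    # scan-to-scan appearance jitter (reconstruction/contrast differences):
    # a per-case multiplicative gain and additive offset on the tissue levels
    gain <- rnorm(1, 1, 0.06)
    offset <- rnorm(1, 0, 0.02)
    lev * gain + offset + profile$intensity_shift +
      array(rnorm(prod(shape), 0, profile$intensity_noise_sd), dim = shape)
  })
  list(volume = vol, mask = mask)
}

# Scatter `level` extra small components per present class: 1-3 voxel specks
# placed in the lung on background voxels not 26-adjacent to that class.
fragment_mask <- function(mask, lung, level) {
  shape <- dim(mask)
  for (cls in sort(unique(mask[mask > 0]))) {
    placed <- 0L
    guard <- 0L
    while (placed < level && guard < 500L) {
      guard <- guard + 1L
      cand <- which(lung & mask == 0L)
      if (!length(cand)) break
      v <- cand[sample.int(length(cand), 1)]
      ijk <- arrayInd(v, shape)
      nb <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
      ni <- pmin(pmax(ijk[1] + nb$i, 1L), shape[1])
      nj <- pmin(pmax(ijk[2] + nb$j, 1L), shape[2])
      nk <- pmin(pmax(ijk[3] + nb$k, 1L), shape[3])
      if (any(mask[cbind(ni, nj, nk)] == cls)) next
      mask[v] <- as.integer(cls)
      # grow the speck by up to 2 face-neighbours (keeps one component)
      extra <- sample.int(3, 1) - 1L
      if (extra > 0) {
        offs <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0,
                         0, -1, 0, 0, 0, 1, 0, 0, -1),
                       ncol = 3, byrow = TRUE)
        offs <- offs[sample.int(6), , drop = FALSE]
        added <- 0L
        for (r in seq_len(6)) {
          if (added >= extra) break
          p <- ijk + offs[r, ]
          if (any(p < 1) || any(p > shape)) next
          if (mask[p[1], p[2], p[3]] != 0L) next
          # the grown voxel must not touch the original class mask either
          ni2 <- pmin(pmax(p[1] + nb$i, 1L), shape[1])
          nj2 <- pmin(pmax(p[2] + nb$j, 1L), shape[2])
          nk2 <- pmin(pmax(p[3] + nb$k, 1L), shape[3])
          touching <- mask[cbind(ni2, nj2, nk2)] == cls
          # adjacent to the speck itself is fine
          if (sum(touching) > 1) next
          mask[p[1], p[2], p[3]] <- as.integer(cls)
          added <- added + 1L
        }
      }
      placed <- placed + 1L
    }
  }
  mask
}

#' Generate one site's synthetic dataset
#'
#' Deterministic for a fixed profile (including its `rng_seed`): the same
#' profile always yields bit-identical volumes and masks. Every case contains
#' at least one non-background voxel, mirroring a cohort in which every scan
#' shows pathology.
#'
#' @param profile a [site_profile()].
#' @return an object of class `fsb_site_dataset` with fields `profile`,
#'   `volumes` (list of 3D numeric arrays), `masks` (list of 3D integer
#'   arrays with labels 0-3) and `split_labels` (unset until
#'   [split_train_test()] is called).
#' @export
generate_site <- function(profile) {
  abort_if(!inherits(profile, "fsb_site_profile"),
           "profile must be created with site_profile()")
  cases <- lapply(seq_len(profile$n_cases),
                  function(i) generate_case(profile, i))
  structure(list(
    profile = profile,
    volumes = lapply(cases, `[[`, "volume"),
    masks = lapply(cases, `[[`, "mask"),
    split_labels = rep(NA_character_, profile$n_cases),
    split_info = NULL
  ), class = "fsb_site_dataset")
}

#' @export
print.fsb_site_dataset <- function(x, ...) {
  ns <- table(factor(x$split_labels, levels = c("train", "test")))
  cat(sprintf("<site dataset '%s'>: %d cases of %s voxels (%d train, %d test)\n",
              x$profile$site_id, length(x$volumes),
              paste(dim(x$volumes[[1]]), collapse = "x"),
              ns[["train"]], ns[["test"]]))
  invisible(x)
}

# binary presence of a class in each case
case_has_class <- function(dataset, label) {
  vapply(dataset$masks, function(m) any(m == label), logical(1))
}

#' Split a site's cases into train and test sets
#'
#' Assigns an 80/20-style split (any fraction), stratified on the presence of
#' the pleural-effusion class so the least common pathology keeps the same
#' ratio to the nearest case. Strata with fewer than 2 cases trigger a
#' warning-level fallback to an unstratified split, recorded in
#' `dataset$split_info`.
#'
#' @param dataset an `fsb_site_dataset`.
#' @param train_fraction fraction of cases assigned to training, in (0, 1).
#' @param seed integer seed; the split is deterministic given it.
#' @return the dataset with `split_labels` filled in.
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  abort_if(!inherits(dataset, "fsb_site_dataset"), "not a site dataset")
  abort_if(!(train_fraction > 0 && train_fraction < 1),
           "train_fraction must be in (0, 1)")
  n <- length(dataset$volumes)
  abort_if(n < 2L, "need at least 2 cases to split")
  pe_pos <- case_has_class(dataset, CLASS_LABELS[["pe"]])
  strata <- list(which(pe_pos), which(!pe_pos))
  stratified <- all(vapply(strata, length, 0L) >= 2L |
                      vapply(strata, length, 0L) == 0L)
  labels <- rep("test", n)
  if (!stratified) {
    warning("a split stratum has fewer than 2 cases; falling back to an ",
            "unstratified split", call. = FALSE)
    k <- round(train_fraction * n)
    tr <- with_seed(seed, sample.int(n, k))
    labels[tr] <- "train"
    info <- list(stratified = FALSE,
                 note = "stratum with fewer than 2 cases; unstratified split")
  } else {
    for (s in seq_along(strata)) {
      idx <- strata[[s]]
      if (!length(idx)) next
      k <- round(train_fraction * length(idx))
      tr <- with_seed(derive_seed(seed, "stratum", s),
                      idx[sample.int(length(idx), k)])
      labels[tr] <- "train"
    }
    info <- list(stratified = TRUE, note = "stratified on PE presence")
  }
  dataset$split_labels <- labels
  dataset$split_info <- c(info, list(train_fraction = train_fraction,
                                     seed = as.integer(seed)))
  dataset
}

#' Take the train or test subset of a site dataset
#'
#' @param dataset a split `fsb_site_dataset`.
#' @param which `"train"` or `"test"`.
#' @return an `fsb_site_dataset` restricted to the subset; case indices of the
#'   parent dataset are kept in `case_ids`.
#' @export
subset_split <- function(dataset, which = c("train", "test")) {
  which <- match.arg(which)
  abort_if(all(is.na(dataset$split_labels)),
           "dataset has no split; call split_train_test() first")
  keep <- which(dataset$split_labels == which)
  out <- dataset
  out$volumes <- dataset$volumes[keep]
  out$masks <- dataset$masks[keep]
  out$split_labels <- dataset$split_labels[keep]
  out$case_ids <- sprintf("%s-%03d", dataset$profile$site_id, keep)
  out$profile$n_cases <- length(keep)
  out
}

#' Validate a dataset's structural integrity
#'
#' Checks every case for unexpected mask labels, image/mask shape mismatches
#' and wrong array rank. Validation never raises: it returns a report, and the
#' dataset passes iff the report contains zero flags.
#'
#' @param dataset an `fsb_site_dataset`.
#' @param expected_labels permitted mask labels (default 0-3).
#' @param expected_rank expected array rank (default 3).
#' @return an object of class `fsb_validation`: a list with `flags`
#'   (data.frame of case/issue) and `pass`.
#' @export
validate_dataset <- function(dataset, expected_labels = 0:3,
                             expected_rank = 3L) {
  flags <- list()
  add <- function(case, issue)
    flags[[length(flags) + 1L]] <<- data.frame(case = case, issue = issue,
                                               stringsAsFactors = FALSE)
  for (i in seq_along(dataset$volumes)) {
    v <- dataset$volumes[[i]]
    m <- dataset$masks[[i]]
    cid <- sprintf("%s-%03d", dataset$profile$site_id, i)
    rv <- length(dim(v) %||% NA)
    rm_ <- length(dim(m) %||% NA)
    if (rv != expected_rank || rm_ != expected_rank) {
      add(cid, sprintf("array rank %d/%d, expected %d", rv, rm_,
                       expected_rank))
      next
    }
    if (!identical(dim(v), dim(m))) {
      add(cid, sprintf("image/mask shape mismatch (%s vs %s)",
                       paste(dim(v), collapse = "x"),
                       paste(dim(m), collapse = "x")))
    }
    bad <- setdiff(unique(as.vector(m)), expected_labels)
    if (length(bad)) {
      add(cid, sprintf("unexpected label %s",
                       paste(sort(bad), collapse = ", ")))
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(case = character(), issue = character(),
               stringsAsFactors = FALSE)
  structure(list(flags = flags, pass = nrow(flags) == 0L,
                 site_id = dataset$profile$site_id),
            class = "fsb_validation")
}

#' @export
print.fsb_validation <- function(x, ...) {
  cat(sprintf("<validation of site '%s'>: %s (%d flag%s)\n", x$site_id,
              if (x$pass) "PASS" else "FAIL", nrow(x$flags),
              if (nrow(x$flags) == 1) "" else "s"))
  if (nrow(x$flags)) print(x$flags, row.names = FALSE)
  invisible(x)
}
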