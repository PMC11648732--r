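# Standard-format I/O: NIfTI volumes/masks (spacing in the header), JSON
# dataset manifests, YAML run configuration. Every artifact directory carries
# the digest of the run configuration that produced it.

#' Write a volume to NIfTI with spacing in the header
#'
#' Values round-trip exactly (double-precision datatype); spacing is stored
#' in the pixdim header field.
#'
#' @param volume 3D numeric or integer array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  attr(volume, "pixdim") <- as.numeric(spacing)
  img <- RNifti::asNifti(volume, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its spacing
#'
#' @param path NIfTI file path.
#' @return list with `volume` (plain array) and `spacing` (mm).
#' @export
read_nifti_volume <- function(path) {
  abort_if(!file.exists(path), sprintf("format error: no file at '%s'", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("format error reading '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  vol <- array(as.numeric(img), dim = dim(img))
  list(volume = vol, spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Write a site dataset to disk as NIfTI plus a JSON manifest
#'
#' One `<case>_img.nii.gz` / `<case>_mask.nii.gz` pair per case and a
#' `manifest.json` recording site id, annotation style, spacing, per-case
#' split membership and the dataset digest.
#'
#' @param dataset an `fsb_site_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_site_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- dataset$profile$voxel_spacing
  ids <- sprintf("%s-%03d", dataset$profile$site_id,
                 seq_along(dataset$volumes))
  for (i in seq_along(dataset$volumes)) {
    write_nifti_volume(dataset$volumes[[i]],
                       file.path(dir, paste0(ids[i], "_img.nii.gz")), sp)
    write_nifti_volume(dataset$masks[[i]],
                       file.path(dir, paste0(ids[i], "_mask.nii.gz")), sp)
  }
  manifest <- list(
    site_id = dataset$profile$site_id,
    annotation_style = dataset$profile$annotation_style,
    voxel_spacing = sp,
    cases = ids,
    split = as.list(setNames(dataset$split_labels, ids)),
    dataset_digest = dataset_digest(dataset)
  )
  path <- file.path(dir, "manifest.json")
  writeLines(as.character(canonical_json(manifest)), path)
  invisible(path)
}

#' Read a site dataset written by [write_site_dataset()]
#'
#' @param dir dataset directory.
#' @return an `fsb_site_dataset` (profile fields limited to what the
#'   manifest stores).
#' @export
read_site_dataset <- function(dir) {
  path <- file.path(dir, "manifest.json")
  abort_if(!file.exists(path), sprintf("no manifest.json in '%s'", dir))
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vols <- list()
  masks <- list()
  for (id in man$cases) {
    vols[[id]] <- read_nifti_volume(
      file.path(dir, paste0(id, "_img.nii.gz")))$volume
    m <- read_nifti_volume(file.path(dir, paste0(id, "_mask.nii.gz")))$volume
    masks[[id]] <- array(as.integer(round(m)), dim = dim(m))
  }
  prof <- site_profile(site_id = man$site_id, n_cases = length(man$cases),
                       voxel_spacing = as.numeric(man$voxel_spacing),
                       annotation_style = man$annotation_style)
  structure(list(profile = prof, volumes = unname(vols),
                 masks = unname(masks),
                 split_labels = as.character(unlist(man$split[man$cases])),
                 split_info = NULL),
            class = "fsb_site_dataset")
}

#' Digest of a dataset's voxel content
#'
#' @param dataset an `fsb_site_dataset`.
#' @return 16-character hex digest of volumes and masks.
#' @export
dataset_digest <- function(dataset) {
  object_digest(list(v = dataset$volumes, m = dataset$masks))
}

#' Default run configuration
#'
#' All defaults at `scale = "paper"` follow the study configuration where it
#' is printed (1000 epochs, 250 batches per epoch, NSD tolerance 1 mm, 80/20
#' split, FN penalty constants); `scale = "desk"` overrides the training
#' schedule to CPU-minutes size (5 rounds of 1 local epoch, 8 batches of 2
#' patches).
#'
#' @param sites site labels of the federation.
#' @param seed master seed.
#' @param scale `"desk"` or `"paper"`.
#' @param n_cases cases per site.
#' @param n_rounds federated communication rounds.
#' @param scenarios scenario ids to run.
#' @return a named list (class `fsb_run_config`).
#' @export
default_run_config <- function(sites = c("A", "B", "C"), seed = 1L,
                               scale = "desk", n_cases = 10L,
                               n_rounds = 5L,
                               scenarios = SCENARIOS) {
  structure(list(
    sites = sites, seed = as.integer(seed), scale = scale,
    n_cases = as.integer(n_cases), n_rounds = as.integer(n_rounds),
    epochs_per_round = 1L, train_fraction = 0.8,
    scenarios = scenarios,
    conventions = unclass(metric_conventions())
  ), class = "fsb_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [default_run_config()] values.
#' @return an `fsb_run_config`.
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), sprintf("no config file at '%s'", path))
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  unknown <- setdiff(names(user), names(cfg))
  abort_if(length(unknown) > 0,
           sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")))
  cfg <- modifyList(cfg, user)
  class(cfg) <- "fsb_run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg an `fsb_run_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
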