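# Comparator predictors: local models Li, the ensemble E of local models,
# federated models FL and their leave-one-site-out variants, and
# specializations Spec(.) that ensemble a collaborative model with the
# evaluated site's local model. All ensembling averages softmax probabilities
# voxel-wise (probability space, not logit space).

#' Average probability maps voxel-wise
#'
#' @param maps list of `fsb_prob_map` arrays of identical shape.
#' @param weights optional nonnegative weights (default equal); normalized to
#'   sum to 1.
#' @return the averaged `fsb_prob_map`.
#' @export
average_prob_maps <- function(maps, weights = NULL) {
  abort_if(length(maps) < 1L, "no maps to average")
  d <- dim(maps[[1]])
  for (m in maps) abort_if(!identical(dim(m), d), "map shapes differ")
  if (is.null(weights)) weights <- rep(1, length(maps))
  weights <- weights / sum(weights)
  acc <- array(0, dim = d)
  for (i in seq_along(maps)) acc <- acc + weights[i] * unclass(maps[[i]])
  structure(acc, class = "fsb_prob_map")
}

#' Ensemble prediction by softmax-probability averaging
#'
#' Runs every model on the volume and takes the voxel-wise unweighted mean of
#' the class-probability maps. The probability-simplex invariant is preserved
#' (a convex combination of distributions is a distribution).
#'
#' @param models list of `fsb_model_weights` sharing a configuration.
#' @param volume preprocessed 3D numeric array.
#' @param config the shared `fsb_model_config`.
#' @param stride optional patch stride passed to [predict_probabilities()].
#' @return an `fsb_prob_map`.
#' @export
ensemble_predict <- function(models, volume, config, stride = NULL) {
  abort_if(length(models) < 1L, "no models to ensemble")
  maps <- lapply(models, predict_probabilities, volume = volume,
                 config = config, stride = stride)
  average_prob_maps(maps)
}

#' Specialize a collaborative model to a site
#'
#' Equal-weight ensembling of exactly the collaborative model and the
#' evaluated site's local model.
#'
#' @param collaborative `fsb_model_weights` of the collaborative model
#'   (federated or ensemble representative).
#' @param local `fsb_model_weights` of the evaluated site's local model.
#' @inheritParams ensemble_predict
#' @return an `fsb_prob_map`.
#' @export
specialize <- function(collaborative, local, volume, config, stride = NULL) {
  ensemble_predict(list(collaborative, local), volume, config, stride)
}

SCENARIOS <- c("personalization", "generalization_no_local",
               "generalization_local")

#' Build the benchmarked method set for a scenario and evaluation site
#'
#' Reproduces the benchmark design: *personalization* compares
#' \{Li, E, FL, Spec(E), Spec(FL)\}; *generalization without local training*
#' compares \{Lj (each other site j), E(-i), FL(-i)\}; *generalization with
#' local training* compares \{Li, E, FL(-i), Spec(E), Spec(FL(-i))\}, where
#' "(-i)" marks a leave-the-evaluation-site-out model. Method specs name
#' their constituent models symbolically (`L_<site>`, `FL`, `FL(-<site>)`);
#' predictions are assembled from a model registry at evaluation time.
#'
#' @param scenario one of `"personalization"`, `"generalization_no_local"`,
#'   `"generalization_local"`.
#' @param sites character vector of all federation sites.
#' @param evaluation_site the site whose test split is evaluated.
#' @return list of `fsb_method_spec` objects.
#' @export
build_method_table <- function(scenario, sites, evaluation_site) {
  abort_if(!scenario %in% SCENARIOS,
           sprintf("unknown scenario '%s'", scenario))
  abort_if(!evaluation_site %in% sites, "evaluation site not among sites")
  i <- evaluation_site
  others <- setdiff(sites, i)
  L <- function(s) paste0("L_", s)
  flv <- paste0("FL(-", i, ")")
  ms <- function(name, type, models, collaborative = NULL, local = NULL) {
    structure(list(name = name, type = type, models = models,
                   collaborative = collaborative, local = local,
                   evaluation_site = i), class = "fsb_method_spec")
  }
  switch(scenario,
    personalization = list(
      ms("Li", "single", L(i)),
      ms("E", "ensemble", vapply(sites, L, "")),
      ms("FL", "single", "FL"),
      ms("Spec(E)", "spec", NULL, collaborative = vapply(sites, L, ""),
         local = L(i)),
      ms("Spec(FL)", "spec", NULL, collaborative = "FL", local = L(i))
    ),
    generalization_no_local = c(
      lapply(others, function(j) ms(L(j), "single", L(j))),
      list(
        ms("E(-i)", "ensemble", vapply(others, L, "")),
        ms("FL(-i)", "single", flv)
      )
    ),
    generalization_local = list(
      ms("Li", "single", L(i)),
      ms("E", "ensemble", vapply(sites, L, "")),
      ms("FL(-i)", "single", flv),
      ms("Spec(E)", "spec", NULL, collaborative = vapply(sites, L, ""),
         local = L(i)),
      ms("Spec(FL(-i))", "spec", NULL, collaborative = flv, local = L(i))
    )
  )
}

#' @export
print.fsb_method_spec <- function(x, ...) {
  const <- switch(x$type,
    single = x$models,
    ensemble = sprintf("mean{%s}", paste(x$models, collapse = ", ")),
    spec = sprintf("(mean{%s} + %s)/2",
                   paste(x$collaborative, collapse = ", "), x$local))
  cat(sprintf("<method '%s' @ site %s>: %s\n", x$name, x$evaluation_site,
              const))
  invisible(x)
}

# All model ids a method needs from the registry
method_model_ids <- function(spec) {
  unique(c(spec$models, spec$collaborative, spec$local))
}

# Predict a method's probability map from cached per-model maps
method_prob_map <- function(spec, model_maps) {
  get_maps <- function(ids) {
    missing <- setdiff(ids, names(model_maps))
    abort_if(length(missing) > 0,
             sprintf("missing predictions for model(s): %s",
                     paste(missing, collapse = ", ")))
    model_maps[ids]
  }
  switch(spec$type,
    single = get_maps(spec$models)[[1]],
    ensemble = average_prob_maps(get_maps(spec$models)),
    spec = average_prob_maps(list(
      average_prob_maps(get_maps(spec$collaborative)),
      get_maps(spec$local)[[1]]
    ))
  )
}
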