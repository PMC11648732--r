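# End-to-end benchmark driver: synthesize a multi-site federation, compute
# fingerprints and the shared configuration, train local / federated /
# leave-one-site-out models, and run the evaluation scenarios.

#' Run the full federated-segmentation benchmark on synthetic sites
#'
#' Pipeline: (1) generate one synthetic dataset per site profile and split it
#' 80/20 stratified on pleural-effusion presence; (2) compute per-site
#' fingerprints on training data only, aggregate them and derive the shared
#' model configuration; (3) train a local model per site, the full
#' federation, and one leave-one-site-out federation per site (when a
#' generalization scenario is requested); (4) evaluate the scenario method
#' sets on each site's test split and rank them.
#'
#' @param run_cfg an [default_run_config()]-style `fsb_run_config`.
#' @param profiles optional named list of [site_profile()]s; defaults to
#'   [default_site_profiles()] for `run_cfg$sites`.
#' @param stride optional inference stride.
#' @param verbose print progress.
#' @return an object of class `fsb_benchmark` with fields `datasets`,
#'   `fingerprints`, `global_fingerprint`, `model_config`, `models`,
#'   `federation` (final state), `loo_states`, `results` (per scenario),
#'   `summaries` and `validation`.
#' @export
run_benchmark <- function(run_cfg = default_run_config(),
                          profiles = NULL, stride = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- run_cfg$seed
  sites <- run_cfg$sites
  if (is.null(profiles))
    profiles <- default_site_profiles(n_cases = run_cfg$n_cases,
                                      sites = sites,
                                      seed = derive_seed(seed, "data"))
  say("generating %d sites x %d cases", length(profiles), run_cfg$n_cases)
  datasets <- lapply(profiles, generate_site)
  datasets <- lapply(datasets, split_train_test,
                     train_fraction = run_cfg$train_fraction,
                     seed = derive_seed(seed, "split"))
  validation <- lapply(datasets, validate_dataset)
  abort_if(!all(vapply(validation, `[[`, TRUE, "pass")),
           "generated data failed validation")
  train_raw <- lapply(datasets, subset_split, "train")
  fps <- lapply(train_raw, compute_fingerprint)
  gfp <- aggregate_fingerprints(fps)
  model_cfg <- configure_model(gfp, scale = run_cfg$scale)
  say("shared config: %s", serialize_config(model_cfg))
  train_data <- lapply(train_raw, preprocess_dataset, config = model_cfg)
  test_data <- lapply(lapply(datasets, subset_split, "test"),
                      preprocess_dataset, config = model_cfg)
  n_epochs <- run_cfg$n_rounds * run_cfg$epochs_per_round
  models <- list()
  for (s in sites) {
    say("training local model at site %s (%d epochs)", s, n_epochs)
    models[[paste0("L_", s)]] <-
      train_local_model(train_data[[s]], model_cfg, n_epochs, seed = seed,
                        site_id = s)
  }
  fed_cfg <- federation_config(sites, n_rounds = run_cfg$n_rounds,
                               epochs_per_round = run_cfg$epochs_per_round,
                               seed = seed)
  say("federated training over {%s}", paste(sites, collapse = ", "))
  fl <- run_federated_training(fed_cfg, train_data, model_cfg)
  models[["FL"]] <- fl$weights
  loo_states <- list()
  need_loo <- any(c("generalization_no_local", "generalization_local") %in%
                    run_cfg$scenarios)
  if (need_loo && length(sites) >= 2) {
    for (s in sites) {
      say("leave-%s-out federation", s)
      cfg_s <- leave_one_out_config(fed_cfg, s)
      fit <- run_federated_training(cfg_s,
                                    train_data[cfg_s$participating_sites],
                                    model_cfg)
      models[[paste0("FL(-", s, ")")]] <- fit$weights
      loo_states[[s]] <- fit$state
    }
  }
  conv <- do.call(metric_conventions, run_cfg$conventions)
  results <- list()
  for (sc in run_cfg$scenarios) {
    say("evaluating scenario '%s'", sc)
    results[[sc]] <- run_scenario(
      sc, test_data, models, model_cfg, conv, stride = stride,
      provenance = list(seed = seed,
                        access_log_digest = object_digest(fl$state$access_log)))
  }
  structure(list(datasets = datasets, fingerprints = fps,
                 global_fingerprint = gfp, model_config = model_cfg,
                 models = models, federation = fl$state,
                 loo_states = loo_states, results = results,
                 summaries = summarize_sites(datasets),
                 validation = validation, run_cfg = run_cfg),
            class = "fsb_benchmark")
}

#' @export
print.fsb_benchmark <- function(x, ...) {
  cat(sprintf("<benchmark>: %d sites, %d models, scenarios {%s}\n",
              length(x$datasets), length(x$models),
              paste(names(x$results), collapse = ", ")))
  for (r in x$results) print(r)
  invisible(x)
}
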