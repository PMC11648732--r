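# In-process federated training. Each round, every participating site trains
# locally from the current global weights; the server then replaces the global
# weights with the non-weighted (equal weight per site, regardless of dataset
# size) arithmetic mean of the site weights and redistributes it. Only model
# weights cross the site boundary; an access log records every (site, case)
# read so data-locality can be audited.

#' Configure a federation
#'
#' @param participating_sites ordered character vector of site ids.
#' @param n_rounds number of communication rounds.
#' @param epochs_per_round local epochs per round (default 1: aggregation
#'   after each local epoch).
#' @param seed master seed; all per-(site, round) RNG streams derive from it.
#' @param checkpoint_every write a checkpoint every this many rounds.
#' @return an object of class `fsb_federation_config`.
#' @export
federation_config <- function(participating_sites, n_rounds,
                              epochs_per_round = 1L, seed = 1L,
                              checkpoint_every = 1L) {
  abort_if(length(participating_sites) < 1L, "need at least one site")
  abort_if(anyDuplicated(participating_sites) > 0, "duplicate site ids")
  abort_if(n_rounds < 1L, "n_rounds must be >= 1")
  abort_if(epochs_per_round < 1L, "epochs_per_round must be >= 1")
  abort_if(checkpoint_every < 1L, "checkpoint_every must be >= 1")
  structure(list(participating_sites = as.character(participating_sites),
                 n_rounds = as.integer(n_rounds),
                 epochs_per_round = as.integer(epochs_per_round),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "fsb_federation_config")
}

#' Derive the leave-one-site-out federation configuration
#'
#' @param cfg an `fsb_federation_config`.
#' @param excluded_site site id to exclude; must be a participating site and
#'   not the only one.
#' @return the configuration without the excluded site; all other fields
#'   unchanged.
#' @export
leave_one_out_config <- function(cfg, excluded_site) {
  abort_if(!excluded_site %in% cfg$participating_sites,
           sprintf("site '%s' does not participate", excluded_site))
  abort_if(length(cfg$participating_sites) < 2L,
           "cannot exclude the only participating site")
  cfg$participating_sites <-
    setdiff(cfg$participating_sites, excluded_site)
  cfg
}

#' Non-weighted federated averaging of model weights
#'
#' Block-wise arithmetic mean with equal weight per entry: the mean is over
#' sites, not cases, so duplicating a site's entry changes the result.
#'
#' @param site_weights list of `fsb_model_weights` sharing configuration hash
#'   and block shapes.
#' @return the averaged `fsb_model_weights`.
#' @export
aggregate_weights <- function(site_weights) {
  abort_if(length(site_weights) < 1L, "nothing to aggregate")
  ref <- site_weights[[1]]
  for (w in site_weights) {
    abort_if(!identical(w$config_hash, ref$config_hash),
             "aggregation error: configuration hashes differ")
    same <- identical(lapply(w$blocks, dim), lapply(ref$blocks, dim)) &&
      identical(lapply(w$blocks, length), lapply(ref$blocks, length))
    abort_if(!same, "aggregation error: block shapes differ")
  }
  n <- length(site_weights)
  out <- ref
  for (nm in names(ref$blocks)) {
    s <- site_weights[[1]]$blocks[[nm]]
    if (n > 1) for (i in 2:n) s <- s + site_weights[[i]]$blocks[[nm]]
    out$blocks[[nm]] <- s / n
  }
  out$trained_sites <-
    sort(unique(unlist(lapply(site_weights, `[[`, "trained_sites"))))
  attr(out, "epoch_loss") <- NULL
  out
}

# --- access log ------------------------------------------------------------

new_access_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

log_access <- function(log, site, case, phase, round = NA_integer_) {
  if (is.null(log)) return(invisible(NULL))
  log$rows[[length(log$rows) + 1L]] <-
    data.frame(site = site, case = case, phase = phase, round = round,
               stringsAsFactors = FALSE)
  invisible(NULL)
}

access_log_df <- function(log) {
  if (is.null(log) || !length(log$rows))
    return(data.frame(site = character(), case = character(),
                      phase = character(), round = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, log$rows)
}

#' Write an access log as JSON lines
#'
#' @param log_df data.frame as found in `state$access_log`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_access_log <- function(log_df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log_df))) {
    writeLines(as.character(jsonlite::toJSON(as.list(log_df[i, ]),
                                             auto_unbox = TRUE)), con)
  }
  invisible(path)
}

# --- orchestration ---------------------------------------------------------

train_site_round <- function(wglob, site, dataset, model_cfg, cfg, t, log) {
  w <- wglob
  for (case in dataset$case_ids %||%
       sprintf("%s-%03d", site, seq_along(dataset$volumes))) {
    log_access(log, site, case, "train", t)
  }
  for (e in seq_len(cfg$epochs_per_round)) {
    w <- train_local_epoch(w, dataset, model_cfg,
                           derive_seed(cfg$seed, "train", site, t, e))
  }
  w
}

federation_loop <- function(state, site_data, model_cfg, checkpoint_dir,
                            stop_after_round) {
  cfg <- state$cfg
  log <- new_access_log()
  if (nrow(state$access_log)) {
    log$rows <- split(state$access_log, seq_len(nrow(state$access_log)))
  }
  t <- state$round
  while (t < cfg$n_rounds) {
    t <- t + 1L
    losses <- numeric(0)
    site_ws <- vector("list", length(cfg$participating_sites))
    names(site_ws) <- cfg$participating_sites
    for (site in cfg$participating_sites) {
      w <- tryCatch(
        train_site_round(state$global_weights, site, site_data[[site]],
                         model_cfg, cfg, t, log),
        error = function(e) {
          stop(sprintf(
            "site '%s' failed during round %d (%s); resume from the last checkpoint",
            site, t, conditionMessage(e)), call. = FALSE)
        })
      losses[site] <- attr(w, "epoch_loss")
      w$trained_sites <- sort(unique(c(w$trained_sites, site)))
      site_ws[[site]] <- w
    }
    state$global_weights <- aggregate_weights(site_ws)
    state$site_weights <- site_ws
    state$round <- t
    state$loss_traces <- rbind(state$loss_traces, losses)
    state$access_log <- access_log_df(log)
    if (!is.null(checkpoint_dir) && t %% cfg$checkpoint_every == 0L) {
      save_checkpoint(state,
                      file.path(checkpoint_dir, sprintf("round-%03d.ckpt", t)))
    }
    if (!is.null(stop_after_round) && t >= stop_after_round) return(state)
  }
  # final distribution: every site holds the final global model
  state$site_weights <- lapply(state$site_weights,
                               function(...) state$global_weights)
  state$access_log <- access_log_df(log)
  state
}

#' Run federated training over in-process sites
#'
#' Each round: every participating site trains `epochs_per_round` local
#' epochs starting from the current global weights; the server aggregates the
#' site weights by non-weighted averaging. Site data never crosses the site
#' boundary in this API (only `fsb_model_weights` objects move); all case
#' reads are recorded in the state's access log. After the final round the
#' global model is distributed once more so every site holds it.
#'
#' @param cfg an `fsb_federation_config`.
#' @param site_data named list (by site id) of preprocessed training
#'   `fsb_site_dataset`s.
#' @param model_cfg the shared `fsb_model_config`.
#' @param checkpoint_dir optional directory for round checkpoints.
#' @param stop_after_round optional round at which to stop early (a
#'   failure-injection hook for resilience testing).
#' @return list with `weights` (final global `fsb_model_weights`) and `state`
#'   (an `fsb_federation_state`).
#' @export
run_federated_training <- function(cfg, site_data, model_cfg,
                                   checkpoint_dir = NULL,
                                   stop_after_round = NULL) {
  abort_if(!all(cfg$participating_sites %in% names(site_data)),
           "site_data must contain every participating site")
  for (site in cfg$participating_sites) {
    abort_if(length(site_data[[site]]$volumes) < 1L,
             sprintf("site '%s' has no training cases", site))
  }
  if (!is.null(checkpoint_dir) &&
      !dir.exists(checkpoint_dir)) dir.create(checkpoint_dir, recursive = TRUE)
  init_w <- init_model(model_cfg, derive_seed(cfg$seed, "init"))
  state <- structure(list(
    round = 0L,
    global_weights = init_w,
    site_weights = setNames(
      rep(list(init_w), length(cfg$participating_sites)),
      cfg$participating_sites),
    loss_traces = NULL,
    access_log = access_log_df(NULL),
    cfg = cfg,
    model_config_hash = model_cfg$config_hash
  ), class = "fsb_federation_state")
  state <- federation_loop(state, site_data, model_cfg, checkpoint_dir,
                           stop_after_round)
  list(weights = state$global_weights, state = state)
}

#' @export
print.fsb_federation_state <- function(x, ...) {
  cat(sprintf("<federation state>: round %d/%d, sites {%s}\n", x$round,
              x$cfg$n_rounds, paste(x$cfg$participating_sites,
                                    collapse = ", ")))
  invisible(x)
}

#' Save a federation checkpoint with an integrity digest
#'
#' The checkpoint captures the round index, global and per-site weights, loss
#' traces and access log. Per-round RNG streams are derived deterministically
#' from the federation seed, so resuming reproduces the uninterrupted
#' trajectory exactly. The file carries a content digest; any corruption is
#' detected at load time.
#'
#' @param state an `fsb_federation_state`.
#' @param path checkpoint file path.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  payload <- serialize(state, NULL, version = 2, xdr = TRUE)
  dig <- fnv1a64(payload)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(dig, "\n")), con)
  writeBin(payload, con)
  invisible(path)
}

#' Load a federation checkpoint, verifying its digest
#'
#' @param path checkpoint file path.
#' @return the stored `fsb_federation_state`.
#' @export
load_checkpoint <- function(path) {
  abort_if(!file.exists(path), sprintf("no checkpoint at '%s'", path))
  raw <- readBin(path, "raw", n = file.size(path))
  abort_if(length(raw) < 18L, "checkpoint integrity error: file truncated")
  dig <- rawToChar(raw[1:16])
  payload <- raw[-(1:17)]
  abort_if(!identical(fnv1a64(payload), dig),
           "checkpoint integrity error: digest mismatch")
  unserialize(payload)
}

#' Resume a federated run from a checkpoint
#'
#' Continues the round loop to `n_rounds`; the resumed trajectory is
#' byte-identical to the uninterrupted one because all per-(site, round)
#' seeds are pure functions of the federation seed.
#'
#' @param checkpoint path to a file written by [save_checkpoint()].
#' @param site_data named list of preprocessed training datasets.
#' @param model_cfg the shared `fsb_model_config`.
#' @param checkpoint_dir optional directory for further checkpoints.
#' @return list with `weights` and `state`, as [run_federated_training()].
#' @export
resume_run <- function(checkpoint, site_data, model_cfg,
                       checkpoint_dir = NULL) {
  state <- load_checkpoint(checkpoint)
  abort_if(!identical(state$model_config_hash, model_cfg$config_hash),
           "checkpoint was written under a different model configuration")
  state <- federation_loop(state, site_data, model_cfg, checkpoint_dir, NULL)
  list(weights = state$global_weights, state = state)
}
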