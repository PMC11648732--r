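# Rank aggregation: per (site, metric) column the benchmarked methods are
# ranked (1 = best, fractional mid-ranks at ties), and a method's overall
# rank r is the mean of its Nsites x Nmetrics ranks.

rank_columns <- function(means, orientations, allow_na = FALSE) {
  dn <- dimnames(means)
  n_methods <- dim(means)[1]
  ranks <- array(NA_real_, dim = dim(means), dimnames = dn)
  for (s in seq_len(dim(means)[2])) {
    for (m in seq_len(dim(means)[3])) {
      v <- means[, s, m]
      if (anyNA(v) && !allow_na)
        stop(sprintf("missing mean for method '%s' at site '%s', metric '%s'",
                     dn[[1]][which(is.na(v))[1]], dn[[2]][s], dn[[3]][m]),
             call. = FALSE)
      keep <- !is.na(v)
      key <- if (orientations[dn[[3]][m]] == "higher") -v[keep] else v[keep]
      ranks[keep, s, m] <- rank(key, ties.method = "average")
    }
  }
  ranks
}

#' Rank benchmark methods across sites and metrics
#'
#' Within each (site, metric) column the methods' mean metric values are
#' ranked with 1 = best (direction per metric: higher is better for DSC and
#' NSD, lower for HSD and NAVE); ties receive fractional mid-ranks, so every
#' column's ranks sum to `Nmethods (Nmethods + 1) / 2`. A method's overall
#' rank `r` is the mean of all its ranks.
#'
#' @param means 3D numeric array `(method, site, metric)` of per-site
#'   per-metric means, with dimnames.
#' @param orientations named character vector over metrics, `"higher"` or
#'   `"lower"`; defaults to the benchmark's four metrics.
#' @return an object of class `fsb_rank_table`: `ranks` (same shape as
#'   `means`), `overall` (named per-method r), `n_sites`, `n_metrics`.
#' @export
rank_methods <- function(means, orientations = METRIC_ORIENTATIONS) {
  abort_if(length(dim(means)) != 3 || is.null(dimnames(means)),
           "means must be a (method, site, metric) array with dimnames")
  abort_if(!all(dimnames(means)[[3]] %in% names(orientations)),
           "every metric needs an orientation")
  ranks <- rank_columns(means, orientations, allow_na = FALSE)
  overall <- apply(ranks, 1, mean)
  structure(list(ranks = ranks, overall = overall,
                 n_sites = dim(means)[2], n_metrics = dim(means)[3],
                 means = means),
            class = "fsb_rank_table")
}

#' @export
print.fsb_rank_table <- function(x, ...) {
  cat(sprintf("<rank table>: %d methods x %d sites x %d metrics\n",
              length(x$overall), x$n_sites, x$n_metrics))
  ord <- order(x$overall)
  df <- data.frame(method = names(x$overall)[ord],
                   overall_rank = round(x$overall[ord], 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run one evaluation scenario end-to-end
#'
#' For each evaluation site i the scenario's method set (see
#' [build_method_table()]) is predicted and scored on site i's test split
#' only; per-site per-metric means are then ranked across methods. Methods
#' whose identity depends on the evaluation site (the other sites' local
#' models in the generalization-without-local-training scenario) are ranked
#' within the sites where they appear, and their overall rank averages the
#' available columns.
#'
#' @param scenario scenario id.
#' @param test_data named list (by site) of preprocessed test
#'   `fsb_site_dataset`s.
#' @param models named registry of `fsb_model_weights` (`L_<site>`, `FL`,
#'   `FL(-<site>)` as required by the scenario).
#' @param config the shared `fsb_model_config`.
#' @param conventions an [metric_conventions()] object.
#' @param stride optional inference stride.
#' @param provenance optional list of run provenance (seeds, digests) echoed
#'   into the result.
#' @return an object of class `fsb_scenario_result` with fields `scenario`,
#'   `rank_table`, `means`, `evals` (per site x method `fsb_metric_eval`) and
#'   `provenance`.
#' @export
run_scenario <- function(scenario, test_data, models, config,
                         conventions = metric_conventions(), stride = NULL,
                         provenance = list()) {
  abort_if(!scenario %in% SCENARIOS,
           sprintf("unknown scenario '%s'", scenario))
  sites <- sort(names(test_data))
  tables <- setNames(lapply(sites, build_method_table, scenario = scenario,
                            sites = sites), sites)
  method_names <- unique(unlist(lapply(tables, function(tb)
    vapply(tb, `[[`, "", "name"))))
  needed <- unique(unlist(lapply(tables, function(tb)
    unlist(lapply(tb, method_model_ids)))))
  missing <- setdiff(needed, names(models))
  abort_if(length(missing) > 0,
           sprintf("scenario '%s' requires untrained model(s): %s",
                   scenario, paste(missing, collapse = ", ")))
  means <- array(NA_real_,
                 dim = c(length(method_names), length(sites),
                         length(METRICS)),
                 dimnames = list(method = method_names, site = sites,
                                 metric = METRICS))
  evals <- list()
  for (si in sites) {
    tb <- tables[[si]]
    ids <- unique(unlist(lapply(tb, method_model_ids)))
    maps_per_case <- lapply(seq_along(test_data[[si]]$volumes), function(i) {
      setNames(lapply(ids, function(id)
        predict_probabilities(models[[id]], test_data[[si]]$volumes[[i]],
                              config, stride)), ids)
    })
    for (spec in tb) {
      ev <- evaluate_method_on_site(spec, test_data[[si]], maps_per_case,
                                    conventions)
      means[spec$name, si, ] <- ev$means
      evals[[paste(si, spec$name, sep = "/")]] <- ev
    }
  }
  complete <- !anyNA(means)
  ranks <- rank_columns(means, METRIC_ORIENTATIONS, allow_na = !complete)
  overall <- apply(ranks, 1, mean, na.rm = TRUE)
  rt <- structure(list(ranks = ranks, overall = overall,
                       n_sites = length(sites), n_metrics = length(METRICS),
                       means = means),
                  class = "fsb_rank_table")
  structure(list(scenario = scenario, rank_table = rt, means = means,
                 evals = evals, conventions = conventions,
                 provenance = c(provenance,
                                list(config_hash = config$config_hash,
                                     sites = sites))),
            class = "fsb_scenario_result")
}

#' @export
print.fsb_scenario_result <- function(x, ...) {
  cat(sprintf("== scenario '%s' ==\n", x$scenario))
  print(x$rank_table)
  invisible(x)
}

records_of_result <- function(result) {
  do.call(rbind, lapply(names(result$evals), function(k) {
    df <- result$evals[[k]]$records
    df$method <- sub("^[^/]+/", "", k)
    df$scenario <- result$scenario
    df
  }))
}

#' Render a benchmark report from scenario results
#'
#' Writes, per scenario, tidy CSVs of the per-site per-metric means, the rank
#' table (with the overall average-rank column) and the raw metric records,
#' plus a rank heatmap (methods x metrics, averaged over sites, with a final
#' average-rank column; darker = better).
#'
#' @param results list of `fsb_scenario_result` objects.
#' @param dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
benchmark_report <- function(results, dir) {
  abort_if(length(results) < 1L, "refusing to render an empty report")
  if (inherits(results, "fsb_scenario_result")) results <- list(results)
  for (r in results)
    abort_if(!inherits(r, "fsb_scenario_result"),
             "results must be fsb_scenario_result objects")
  abort_if(any(vapply(results, function(r) length(r$rank_table$overall),
                      0L) == 0L),
           "refusing to render a report with an empty method list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  for (r in results) {
    base <- file.path(dir, r$scenario)
    mt <- as.data.frame.table(r$means, responseName = "mean",
                              stringsAsFactors = FALSE)
    write.csv(mt, paste0(base, "-means.csv"), row.names = FALSE)
    rk <- as.data.frame.table(r$rank_table$ranks, responseName = "rank",
                              stringsAsFactors = FALSE)
    ov <- data.frame(method = names(r$rank_table$overall),
                     overall_rank = as.numeric(r$rank_table$overall),
                     stringsAsFactors = FALSE)
    write.csv(rk, paste0(base, "-ranks.csv"), row.names = FALSE)
    write.csv(ov, paste0(base, "-overall-rank.csv"), row.names = FALSE)
    write.csv(records_of_result(r), paste0(base, "-records.csv"),
              row.names = FALSE)
    pdf_path <- paste0(base, "-rank-heatmap.pdf")
    pdf(pdf_path, width = 7, height = 4.5)
    plot_rank_heatmap(r)
    dev.off()
    paths[[r$scenario]] <- c(means = paste0(base, "-means.csv"),
                             ranks = paste0(base, "-ranks.csv"),
                             overall = paste0(base, "-overall-rank.csv"),
                             records = paste0(base, "-records.csv"),
                             heatmap = pdf_path)
  }
  invisible(paths)
}

#' Plot a scenario's rank heatmap
#'
#' Methods (rows, best overall rank on top) by metrics (ranks averaged over
#' sites), with a final column showing the overall average rank; darker
#' squares indicate better ranks.
#'
#' @param result an `fsb_scenario_result`.
#' @return invisibly, the plotted matrix.
#' @export
plot_rank_heatmap <- function(result) {
  rk <- apply(result$rank_table$ranks, c(1, 3), mean, na.rm = TRUE)
  mat <- cbind(rk, `avg rank` = result$rank_table$overall)
  ord <- order(result$rank_table$overall, decreasing = TRUE)
  mat <- mat[ord, , drop = FALSE]
  nm <- nrow(mat)
  nc <- ncol(mat)
  pal <- colorRampPalette(c("#08306b", "#f7fbff"))(64)
  op <- par(mar = c(4, 9, 2, 1))
  on.exit(par(op))
  image(seq_len(nc), seq_len(nm), t(mat), col = pal, axes = FALSE,
        xlab = "", ylab = "",
        zlim = range(mat, na.rm = TRUE) + c(-1e-9, 1e-9))
  axis(1, at = seq_len(nc), labels = colnames(mat), las = 2, cex.axis = 0.8)
  axis(2, at = seq_len(nm), labels = rownames(mat), las = 1, cex.axis = 0.8)
  for (i in seq_len(nm)) for (j in seq_len(nc))
    text(j, i, sprintf("%.2f", mat[i, j]), cex = 0.7,
         col = if (mat[i, j] < mean(range(mat, na.rm = TRUE))) "white"
               else "black")
  title(sprintf("Ranks, scenario '%s' (1 = best)", result$scenario))
  invisible(mat)
}
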