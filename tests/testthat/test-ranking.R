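orient <- c(DSC = "higher", NSD = "higher", HSD = "lower", NAVE = "lower")

random_means <- function(n_methods = 4, n_sites = 3, n_metrics = 4,
                         seed = 1) {
  set.seed(seed)
  array(runif(n_methods * n_sites * n_metrics),
        dim = c(n_methods, n_sites, n_metrics),
        dimnames = list(method = paste0("M", seq_len(n_methods)),
                        site = paste0("S", seq_len(n_sites)),
                        metric = c("DSC", "NSD", "HSD", "NAVE")))
}

test_that("a dominant method gets overall rank 1", {
  m <- random_means(seed = 2)
  m["M2", , c("DSC", "NSD")] <- 2   # best everywhere (higher better)
  m["M2", , c("HSD", "NAVE")] <- -1 # best everywhere (lower better)
  rt <- rank_methods(m, orient)
  expect_equal(unname(rt$overall["M2"]), 1.0)
})

test_that("ties receive fractional mid-ranks", {
  m <- array(NA_real_, dim = c(3, 1, 1),
             dimnames = list(method = c("A", "B", "C"), site = "S",
                             metric = "DSC"))
  m[, 1, 1] <- c(0.9, 0.9, 0.1)
  rt <- rank_methods(m, orient["DSC"])
  expect_equal(unname(rt$overall), c(1.5, 1.5, 3.0))
  expect_equal(sum(rt$ranks[, 1, 1]), 3 * 4 / 2)
})

test_that("overall ranks equal the naive counting oracle", {
  for (seed in 1:5) {
    m <- random_means(seed = seed)
    # inject some ties
    if (seed %% 2 == 0) m[2, , ] <- m[1, , ]
    rt <- rank_methods(m, orient)
    expect_equal(rt$overall, rank_oracle(m, orient), tolerance = 1e-12)
  }
})

test_that("rank sums are conserved per column under any tie pattern", {
  m <- random_means(n_methods = 5, seed = 9)
  m[3, , ] <- m[1, , ]
  m[5, 2, ] <- m[4, 2, ]
  rt <- rank_methods(m, orient)
  for (s in 1:3) for (k in 1:4) {
    expect_equal(sum(rt$ranks[, s, k]), 5 * 6 / 2)
  }
})

test_that("improving one cell never worsens that method's overall rank", {
  m <- random_means(seed = 4)
  rt0 <- rank_methods(m, orient)
  m2 <- m
  m2["M3", "S2", "DSC"] <- m2["M3", "S2", "DSC"] + 10 # strictly better
  rt1 <- rank_methods(m2, orient)
  expect_lte(rt1$overall["M3"], rt0$overall["M3"])
  others <- setdiff(dimnames(m)[[1]], "M3")
  expect_true(all(rt1$overall[others] >= rt0$overall[others]))
})

test_that("missing cells are reported by method, site and metric", {
  m <- random_means(seed = 6)
  m["M4", "S1", "NSD"] <- NA
  expect_error(rank_methods(m, orient), "M4.*S1.*NSD")
})

test_that("scenario evaluation ranks methods over sites x metrics", {
  fed <- tiny_federation(sites = c("X", "Y"), n_cases = 4L, seed = 33L)
  models <- list("L_X" = init_model(fed$config, 1L),
                 "L_Y" = init_model(fed$config, 2L),
                 "FL" = init_model(fed$config, 3L))
  res <- run_scenario("personalization", fed$test, models, fed$config,
                      metric_conventions())
  expect_s3_class(res, "fsb_scenario_result")
  expect_identical(dim(res$means), c(5L, 2L, 4L))
  expect_setequal(rownames(res$means),
                  c("Li", "E", "FL", "Spec(E)", "Spec(FL)"))
  expect_true(all(res$rank_table$overall >= 1 &
                    res$rank_table$overall <= 5))
  # swapping site order leaves every overall rank unchanged
  res2 <- run_scenario("personalization", fed$test[c("Y", "X")], models,
                       fed$config, metric_conventions())
  expect_equal(res$rank_table$overall,
               res2$rank_table$overall[names(res$rank_table$overall)])
  # a missing trained model is an actionable error
  expect_error(run_scenario("generalization_no_local", fed$test, models,
                            fed$config, metric_conventions()),
               "untrained model")
})

test_that("generalization without local training has Nsites+1 methods", {
  fed <- tiny_federation(sites = c("X", "Y", "Z"), n_cases = 3L, seed = 44L)
  models <- c(setNames(lapply(1:3, function(i)
    init_model(fed$config, i)), paste0("L_", c("X", "Y", "Z"))),
    setNames(lapply(4:6, function(i) init_model(fed$config, i)),
             paste0("FL(-", c("X", "Y", "Z"), ")")))
  res <- run_scenario("generalization_no_local", fed$test, models,
                      fed$config, metric_conventions())
  # per evaluation site: (Nsites - 1) local models + E(-i) + FL(-i) = 4
  # methods; rows of the table are the union over sites
  expect_setequal(rownames(res$means),
                  c("L_X", "L_Y", "L_Z", "E(-i)", "FL(-i)"))
  # each L_j column is evaluated at every site but j
  expect_true(all(is.na(res$means["L_X", "X", ])))
  expect_false(anyNA(res$means["L_X", c("Y", "Z"), ]))
})

test_that("reports are written deterministically and refuse empty input", {
  fed <- tiny_federation(sites = c("X", "Y"), n_cases = 3L, seed = 55L)
  models <- list("L_X" = init_model(fed$config, 1L),
                 "L_Y" = init_model(fed$config, 2L),
                 "FL" = init_model(fed$config, 3L))
  res <- run_scenario("personalization", fed$test, models, fed$config,
                      metric_conventions())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  benchmark_report(list(res), d1)
  benchmark_report(list(res), d2)
  f1 <- file.path(d1, "personalization-means.csv")
  f2 <- file.path(d2, "personalization-means.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(d1,
                                    "personalization-rank-heatmap.pdf")))
  expect_error(benchmark_report(list(), withr::local_tempdir()), "empty")
})
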