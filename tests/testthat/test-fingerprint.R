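make_dataset <- function(volumes, masks, spacing = c(1, 1, 1), id = "M") {
  structure(list(
    profile = site_profile(id, n_cases = length(volumes),
                           voxel_spacing = spacing),
    volumes = volumes, masks = masks,
    split_labels = rep("train", length(volumes)), split_info = NULL
  ), class = "fsb_site_dataset")
}

test_that("fingerprint of a constant foreground is degenerate", {
  v <- array(5.0, dim = c(4, 4, 4))
  m <- array(0L, dim = c(4, 4, 4))
  m[2:3, 2:3, 2:3] <- 1L
  fp <- compute_fingerprint(make_dataset(list(v), list(m)))
  expect_equal(fp$intensity_mean, 5.0)
  expect_equal(fp$intensity_sd, 0.0)
  expect_equal(fp$intensity_percentiles, c(5.0, 5.0))
})

test_that("fingerprint matches a pooled-voxel brute-force oracle", {
  d <- generate_site(tiny_profile(n_cases = 10L, seed = 31L))
  fp <- compute_fingerprint(d)
  pooled <- unlist(lapply(seq_along(d$volumes), function(i)
    d$volumes[[i]][d$masks[[i]] > 0]))
  expect_equal(fp$intensity_mean, mean(pooled))
  expect_equal(fp$intensity_sd, sd(pooled))
  expect_equal(fp$intensity_percentiles,
               unname(quantile(pooled, c(0.005, 0.995))))
  expect_equal(fp$n_cases, 10L)
})

test_that("fingerprints never touch test cases and need >= 1 case", {
  d <- split_train_test(generate_site(tiny_profile(n_cases = 6L)), 0.5, 1L)
  tr <- subset_split(d, "train")
  fp_tr <- compute_fingerprint(tr)
  expect_identical(fp_tr$n_cases, length(tr$volumes))
  empty <- tr
  empty$volumes <- list()
  empty$masks <- list()
  expect_error(compute_fingerprint(empty), "at least one")
})

test_that("aggregation is identity on one site, weighted on several", {
  d <- generate_site(tiny_profile(n_cases = 5L, seed = 13L))
  fp <- compute_fingerprint(d)
  g <- aggregate_fingerprints(list(fp))
  expect_equal(g$intensity_mean, fp$intensity_mean)
  expect_equal(g$intensity_sd, fp$intensity_sd, tolerance = 1e-12)
  expect_equal(g$spacing_median, fp$spacing_median)
  expect_equal(g$n_cases, fp$n_cases)
  # equal case counts, means 2 and 4 -> pooled mean 3
  fa <- fp; fa$site_id <- "a"; fa$intensity_mean <- 2
  fb <- fp; fb$site_id <- "b"; fb$intensity_mean <- 4
  expect_equal(aggregate_fingerprints(list(fa, fb))$intensity_mean, 3)
  # spacing medians (1,1,1) and (3,3,3), equal counts -> (2,2,2)
  fa$spacing_median <- c(1, 1, 1)
  fb$spacing_median <- c(3, 3, 3)
  expect_equal(aggregate_fingerprints(list(fa, fb))$spacing_median,
               c(2, 2, 2))
})

test_that("aggregation is order-invariant and rejects duplicate sites", {
  fps <- lapply(c("P", "Q", "R"), function(s)
    compute_fingerprint(generate_site(tiny_profile(
      s, n_cases = 3L + nchar(s), seed = utf8ToInt(s)))))
  g1 <- aggregate_fingerprints(fps)
  g2 <- aggregate_fingerprints(fps[c(3, 1, 2)])
  expect_identical(g1, g2)
  expect_identical(object_digest(g1), object_digest(g2))
  expect_error(aggregate_fingerprints(fps[c(1, 1)]), "duplicate")
})

test_that("model configuration is a pure function of the fingerprint", {
  fps <- lapply(c("P", "Q"), function(s)
    compute_fingerprint(generate_site(tiny_profile(s, n_cases = 4L,
                                                   seed = 50L))))
  g <- aggregate_fingerprints(fps)
  c1 <- configure_model(g, "desk")
  c2 <- configure_model(g, "desk") # a second "site" doing the same thing
  expect_identical(serialize_config(c1), serialize_config(c2))
  expect_identical(c1$config_hash, c2$config_hash)
  expect_equal(c1$target_spacing, 2 * g$spacing_median)
})

test_that("paper-scale configuration uses the full training schedule", {
  fp <- compute_fingerprint(generate_site(tiny_profile(n_cases = 3L)))
  cfg <- configure_model(aggregate_fingerprints(list(fp)), "paper")
  expect_identical(cfg$epochs, 1000L)
  expect_identical(cfg$batches_per_epoch, 250L)
})

test_that("preprocessing resamples, clips and standardizes", {
  fp <- compute_fingerprint(generate_site(tiny_profile(n_cases = 4L,
                                                       seed = 61L)))
  cfg <- configure_model(aggregate_fingerprints(list(fp)), "desk")
  # a case already at target spacing keeps its shape
  v <- array(rnorm(6 * 6 * 6), dim = c(6, 6, 6))
  m <- array(0L, dim = c(6, 6, 6)); m[3, 3, 3] <- 1L
  pc <- preprocess_case(v, m, cfg$target_spacing, cfg)
  expect_identical(dim(pc$volume), c(6L, 6L, 6L))
  # constant volume stays constant after the affine normalization
  vc <- array(0.5, dim = c(6, 6, 6))
  pc2 <- preprocess_case(vc, m, cfg$target_spacing, cfg)
  expect_equal(max(pc2$volume) - min(pc2$volume), 0)
  # resampled label set is a subset of the original label set
  d <- generate_site(tiny_profile(n_cases = 3L, seed = 62L,
                                  spacing = c(1.3, 0.9, 2.1)))
  for (i in seq_along(d$masks)) {
    pc3 <- preprocess_case(d$volumes[[i]], d$masks[[i]],
                           d$profile$voxel_spacing, cfg)
    expect_true(all(unique(as.vector(pc3$mask)) %in%
                      unique(as.vector(d$masks[[i]]))))
  }
  expect_error(preprocess_case(v, m, c(0, 1, 1), cfg), "spacing")
})
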