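test_that("generation is bit-identical for a fixed seed", {
  p <- tiny_profile(n_cases = 5L, seed = 7L)
  d1 <- generate_site(p)
  d2 <- generate_site(p)
  expect_identical(d1, d2)
  # and sensitive to the seed
  d3 <- generate_site(tiny_profile(n_cases = 5L, seed = 8L))
  expect_false(identical(d1$volumes, d3$volumes))
})

test_that("prevalence 1 forces every class into every case", {
  p <- tiny_profile(n_cases = 6L, prev = c(cons = 1, ggo = 1, pe = 1))
  d <- generate_site(p)
  for (m in d$masks) expect_true(all(1:3 %in% unique(as.vector(m))))
})

test_that("every generated case contains pathology foreground", {
  d <- generate_site(tiny_profile(n_cases = 8L,
                                  prev = c(cons = .2, ggo = .2, pe = .1)))
  for (m in d$masks) expect_gt(sum(m > 0), 0)
})

test_that("auto-style fragmentation never lowers per-class component counts", {
  pa <- tiny_profile("S", n_cases = 4L, seed = 21L)
  pb <- tiny_profile("S", n_cases = 4L, seed = 21L, style = "auto",
                     frag = 3L)
  da <- generate_site(pa)
  db <- generate_site(pb)
  saw_increase <- FALSE
  for (i in seq_len(4)) {
    for (cls in 1:3) {
      if (!any(da$masks[[i]] == cls)) next
      ca <- connected_components(da$masks[[i]] == cls)$count
      cb <- connected_components(db$masks[[i]] == cls)$count
      expect_gte(cb, ca)
      if (cb > ca) saw_increase <- TRUE
    }
  }
  expect_true(saw_increase)
})

test_that("invalid profiles are rejected", {
  expect_error(site_profile("x", n_cases = 0), "positive")
  expect_error(site_profile("x", voxel_spacing = c(1, -1, 1)), "spacing")
  expect_error(site_profile("x", annotation_style = "manual",
                            fragmentation_level = 2), "manual")
  expect_error(site_profile("x", class_prevalence = c(1.2, 0.5, 0.1)),
               "prevalence")
})

test_that("voxel volume equals the product of profile spacings exactly", {
  p <- tiny_profile(spacing = c(0.5, 0.5, 0.6))
  d <- generate_site(p)
  s <- summarize_sites(list(d))
  expect_identical(s[[1]]$voxel_volume, prod(c(0.5, 0.5, 0.6)))
})

test_that("80/20 split is exact on 100 cases and stratified on PE", {
  p <- tiny_profile(n_cases = 100L, shape = c(8L, 8L, 8L), seed = 2L)
  d <- split_train_test(generate_site(p), 0.8, seed = 3L)
  expect_identical(sum(d$split_labels == "train"), 80L)
  expect_identical(sum(d$split_labels == "test"), 20L)
  pe <- vapply(d$masks, function(m) any(m == 3L), logical(1))
  n_pe_train <- sum(pe & d$split_labels == "train")
  expect_identical(n_pe_train, as.integer(round(0.8 * sum(pe))))
})

test_that("different split seeds keep per-stratum counts identical", {
  p <- tiny_profile(n_cases = 20L, shape = c(8L, 8L, 8L), seed = 4L)
  d <- generate_site(p)
  s1 <- split_train_test(d, 0.8, seed = 1L)
  s2 <- split_train_test(d, 0.8, seed = 2L)
  pe <- vapply(d$masks, function(m) any(m == 3L), logical(1))
  for (stratum in list(which(pe), which(!pe))) {
    expect_identical(sum(s1$split_labels[stratum] == "train"),
                     sum(s2$split_labels[stratum] == "train"))
  }
  expect_false(identical(s1$split_labels, s2$split_labels) &&
                 length(unique(s1$split_labels)) == 1)
})

test_that("degenerate strata fall back to an unstratified split with warning", {
  p <- tiny_profile(n_cases = 5L, shape = c(8L, 8L, 8L),
                    prev = c(cons = 1, ggo = 0, pe = 0))
  d <- generate_site(p)
  # no PE cases at all: PE stratum empty is fine (stratified)
  expect_silent(split_train_test(d, 0.8, 1L))
  # force exactly one PE case
  d$masks[[1]][2, 2, 2] <- 3L
  expect_warning(s <- split_train_test(d, 0.8, 1L), "unstratified")
  expect_false(s$split_info$stratified)
})

test_that("PE prevalence converges to the profile probability", {
  prev_pe <- 0.5
  p <- tiny_profile(n_cases = 500L, shape = c(8L, 8L, 8L), seed = 9L,
                    prev = c(cons = 0.9, ggo = 0.8, pe = prev_pe))
  d <- generate_site(p)
  frac <- mean(vapply(d$masks, function(m) any(m == 3L), logical(1)))
  # every-case-has-pathology forcing can only raise prevalence slightly;
  # allow a 3-sigma binomial band around the nominal probability
  tol <- 3 * sqrt(prev_pe * (1 - prev_pe) / 500)
  expect_lt(abs(frac - prev_pe), tol + 0.02)
})

test_that("validation reports planted defects and passes clean data", {
  d <- generate_site(tiny_profile(n_cases = 10L, shape = c(8L, 8L, 8L)))
  expect_true(validate_dataset(d)$pass)
  d_bad <- d
  d_bad$masks[[3]][1, 1, 1] <- 9L
  rep1 <- validate_dataset(d_bad)
  expect_false(rep1$pass)
  expect_identical(nrow(rep1$flags), 1L)
  expect_match(rep1$flags$issue, "unexpected label 9")
  expect_match(rep1$flags$case, "003")
  d_bad2 <- d
  d_bad2$volumes[[1]] <- d_bad2$volumes[[1]][1:4, , ]
  d_bad2$volumes[[2]] <- d_bad2$volumes[[2]][, 1:4, ]
  rep2 <- validate_dataset(d_bad2)
  expect_identical(nrow(rep2$flags), 2L)
  # wrong rank is flagged too
  d_bad3 <- d
  d_bad3$masks[[5]] <- matrix(0L, 8, 8)
  expect_false(validate_dataset(d_bad3)$pass)
})
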