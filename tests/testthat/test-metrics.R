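test_that("cases classify into computed / FN-penalized / FP-excluded", {
  empty <- array(0L, dim = c(3, 3, 3))
  full <- mask_at(c(3, 3, 3), rbind(c(2, 2, 2)))
  expect_identical(classify_case(empty, full), "fp_excluded")
  expect_identical(classify_case(empty, empty), "fp_excluded")
  expect_identical(classify_case(full, empty), "fn_penalized")
  expect_identical(classify_case(full, full), "computed")
  expect_error(classify_case(full, array(0L, dim = c(2, 2, 2))), "shape")
})

test_that("Dice matches hand-counted voxel sets", {
  a <- mask_at(c(4, 4, 4), rbind(c(1, 1, 1), c(1, 2, 1), c(2, 1, 1),
                                 c(2, 2, 1)))
  b <- mask_at(c(4, 4, 4), rbind(c(1, 1, 1), c(1, 2, 1)))
  expect_equal(dsc(a, b), 2 * 2 / (4 + 2))
  expect_equal(dsc(a, a), 1.0)
  disj <- mask_at(c(4, 4, 4), rbind(c(4, 4, 4)))
  expect_equal(dsc(a, disj), 0.0)
  expect_equal(dsc(a, b), dsc(b, a))
})

test_that("surface Dice respects the millimetre tolerance", {
  # two single-voxel masks whose centres are 1 mm apart
  a <- mask_at(c(5, 5, 5), rbind(c(2, 3, 3)))
  b <- mask_at(c(5, 5, 5), rbind(c(3, 3, 3)))
  sp <- c(1, 1, 1)
  expect_equal(nsd(a, b, sp, tolerance = 1.0), 1.0)
  expect_equal(nsd(a, b, sp, tolerance = 0.5), 0.0)
  expect_equal(nsd(a, a, sp, tolerance = 1.0), 1.0)
  expect_error(nsd(a, b, sp, tolerance = 0), "positive")
  # symmetric in the two masks
  expect_equal(nsd(a, b, sp, 1.0), nsd(b, a, sp, 1.0))
})

test_that("surface Dice is monotonically non-decreasing in tolerance", {
  set.seed(5)
  a <- array(as.integer(runif(6^3) < 0.2), dim = c(6, 6, 6))
  b <- array(as.integer(runif(6^3) < 0.2), dim = c(6, 6, 6))
  sp <- c(1, 1.5, 1)
  tols <- c(0.5, 1, 2, 4, 8)
  vals <- vapply(tols, function(t) nsd(a, b, sp, t), 0)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("Hausdorff surface distance matches hand geometry", {
  sp <- c(1, 1, 1)
  a <- mask_at(c(7, 7, 7), rbind(c(2, 4, 4)))
  b <- mask_at(c(7, 7, 7), rbind(c(5, 4, 4))) # 3 voxels apart along axis 1
  expect_equal(hsd(a, b, sp), 3.0)
  expect_equal(hsd(a, a, sp), 0.0)
  expect_equal(hsd(a, b, sp), hsd(b, a, sp))
  # anisotropic spacing: one slice offset along axis 3 at 2 mm slices
  a2 <- mask_at(c(5, 5, 5), rbind(c(3, 3, 2)))
  b2 <- mask_at(c(5, 5, 5), rbind(c(3, 3, 3)))
  expect_equal(hsd(a2, b2, c(1, 1, 2)), 2.0)
})

test_that("volume error is normalized and spacing-invariant", {
  gt <- array(0L, dim = c(6, 6, 6)); gt[1:10] <- 1L
  pr <- array(0L, dim = c(6, 6, 6)); pr[1:15] <- 1L
  expect_equal(nave(gt, pr, c(1, 1, 1)), 0.5)
  expect_equal(nave(gt, gt, c(1, 1, 1)), 0.0)
  expect_equal(nave(gt, pr, c(2, 2, 2)), nave(gt, pr, c(1, 1, 1)))
  expect_equal(nave(gt, pr, c(1, 1, 1), mode = "mean"), 5 / 12.5)
})

test_that("FN-penalized sites aggregate to exactly the penalty constants", {
  conv <- metric_conventions()
  gt <- lapply(1:3, function(i) {
    m <- array(0L, dim = c(5, 5, 5))
    m[2, 2, 2] <- 1L; m[3, 3, 3] <- 2L; m[4, 4, 4] <- 3L
    m
  })
  pred <- lapply(1:3, function(i) array(0L, dim = c(5, 5, 5)))
  ev <- evaluate_predictions(gt, pred, c(1, 1, 1), conv, site = "S")
  expect_equal(unname(ev$means), c(0.0, 0.0, 260.0, 20.0))
  expect_true(all(ev$records$status == "fn_penalized"))
})

test_that("FP-excluded records are provably inert in aggregates", {
  conv <- metric_conventions()
  gt <- list(mask_at(c(5, 5, 5), rbind(c(2, 2, 2))),
             array(0L, dim = c(5, 5, 5)))   # second case: empty gt
  pred <- list(mask_at(c(5, 5, 5), rbind(c(2, 2, 2))),
               mask_at(c(5, 5, 5), rbind(c(4, 4, 4)))) # false positive
  gt[[1]][2, 2, 2] <- 1L
  pred[[1]][2, 2, 2] <- 1L
  ev <- evaluate_predictions(gt, pred, c(1, 1, 1), conv, site = "S")
  excl <- ev$records$status == "fp_excluded"
  expect_true(any(excl))
  expect_true(all(is.na(ev$records$value[excl])))
  # mutation test: perturbing excluded values must not change any mean
  mutated <- ev$records
  mutated$value[excl] <- 1e6
  expect_identical(metric_means(mutated), metric_means(ev$records))
  # dropping them entirely leaves the means unchanged too
  expect_identical(metric_means(ev$records[!excl, ]),
                   metric_means(ev$records))
})

test_that("per-site means equal a hand-computed mixed-case mean", {
  conv <- metric_conventions()
  sp <- c(1, 1, 1)
  d <- c(6, 6, 6)
  gt1 <- array(0L, dim = d); gt1[2:3, 2:3, 2] <- 1L
  pr1 <- array(0L, dim = d); pr1[2:3, 2, 2] <- 1L     # partial overlap
  gt2 <- array(0L, dim = d); gt2[4, 4, 4] <- 1L
  pr2 <- array(0L, dim = d)                            # false negative
  gt3 <- array(0L, dim = d)
  pr3 <- array(0L, dim = d); pr3[1, 1, 1] <- 1L        # false positive
  ev <- evaluate_predictions(list(gt1, gt2, gt3), list(pr1, pr2, pr3),
                             sp, conv, site = "S")
  recs <- ev$records
  cons <- recs[recs$class == "cons", ]
  expect_identical(cons$status[cons$metric == "DSC"],
                   c("computed", "fn_penalized", "fp_excluded"))
  hand_dsc <- mean(c(dsc(gt1, pr1), 0.0))
  hand_hsd <- mean(c(hsd(gt1, pr1, sp), 260.0))
  hand_nave <- mean(c(nave(gt1, pr1, sp), 20.0))
  got <- metric_means(cons)
  expect_equal(unname(got["DSC"]), hand_dsc)
  expect_equal(unname(got["HSD"]), hand_hsd)
  expect_equal(unname(got["NAVE"]), hand_nave)
  # ggo and pe columns have empty ground truth everywhere -> all excluded,
  # and the site means are driven by cons alone
  expect_true(all(recs$status[recs$class != "cons"] == "fp_excluded"))
})

test_that("conventions are validated and echoed", {
  expect_error(metric_conventions(nsd_tolerance = 0), "positive")
  expect_error(metric_conventions(fp_policy = "impute"), "exclude")
  conv <- metric_conventions(hsd_mode = "p95")
  expect_identical(conv$hsd_mode, "p95")
  set.seed(1)
  a <- array(as.integer(runif(6^3) < 0.3), dim = c(6, 6, 6))
  b <- array(as.integer(runif(6^3) < 0.3), dim = c(6, 6, 6))
  expect_lte(hsd(a, b, c(1, 1, 1), mode = "p95"),
             hsd(a, b, c(1, 1, 1), mode = "max"))
})

test_that("missing predictions are reported with the case count", {
  expect_error(evaluate_predictions(list(array(1L, c(2, 2, 2))), list(),
                                    c(1, 1, 1)),
               "missing prediction")
})
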