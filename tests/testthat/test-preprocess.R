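test_that("detection filter applies the >=20% boundary and censors survivors", {
  # 40 samples; assay a01 has exactly 8/40 bad cells (boundary: excluded),
  # a02 is clean at Ct 30 (retained), a03 has 7 bad (retained, censored)
  v <- matrix(30, nrow = 3, ncol = 40,
              dimnames = list(c("a01", "a02", "a03"),
                              sprintf("s%02d", 1:40)))
  v[1, 1:4] <- NA; v[1, 5:8] <- 36.2
  v[3, 1:7] <- 35.4
  out <- detection_filter(ct_matrix(v))
  expect_equal(out$excluded, "a01")
  expect_equal(rownames(out$ct), c("a02", "a03"))
  expect_equal(sum(is.na(out$ct["a03", ])), 7L)
  expect_equal(out$n_censored, 7L)
  expect_equal(ct_stage(out$ct), "filtered")
})

test_that("filter matches a brute-force recount and ignores permutation", {
  sim <- simulate_array_dataset(n_assays = 200, seed = 31)
  v <- unclass(sim$ct)
  planted_bad <- rownames(v)[rowMeans(is.na(v) | v > 35) >= 0.20]
  out <- detection_filter(sim$ct)
  expect_setequal(out$excluded, planted_bad)

  perm <- ct_matrix(v[sample(nrow(v)), sample(ncol(v))], "raw")
  out2 <- detection_filter(perm)
  expect_setequal(out2$excluded, out$excluded)
})

test_that("lowess normalization removes sample-level trends", {
  set.seed(8)
  base <- rnorm(120, 28, 3)
  v <- matrix(rep(base, 12), ncol = 12,
              dimnames = list(sprintf("a%03d", 1:120), sprintf("s%02d", 1:12)))
  # identical profiles: output equals input
  out <- lowess_normalize(ct_matrix(v, "filtered"))
  expect_lt(max(abs(unclass(out) - v)), 1e-8)
  expect_equal(ct_stage(out), "normalized")

  # constant +1 offset on one sample is removed
  v2 <- v; v2[, 5] <- v2[, 5] + 1
  out2 <- lowess_normalize(ct_matrix(v2, "filtered"))
  ref <- apply(v2, 1, median)
  expect_lt(abs(mean(unclass(out2)[, 5] - ref)), 0.05)

  # linear-in-reference deviation: residual slope ~ 0, matching an
  # independent least-squares detrend on the same pairs
  v3 <- v; v3[, 7] <- v3[, 7] + 0.15 * (base - mean(base))
  out3 <- lowess_normalize(ct_matrix(v3, "filtered"))
  ref3 <- apply(v3, 1, median)
  res_slope <- coef(lm(I(unclass(out3)[, 7] - ref3) ~ ref3))[2]
  expect_lt(abs(res_slope), 0.02)
  lm_resid <- resid(lm(I(v3[, 7] - ref3) ~ ref3))
  expect_lt(abs(coef(lm(lm_resid ~ ref3))[2]), 1e-10)
})

test_that("lowess rejects samples with too few observations", {
  v <- matrix(rnorm(60, 28), nrow = 12,
              dimnames = list(sprintf("a%02d", 1:12), sprintf("s%d", 1:5)))
  v[1:4, 2] <- NA
  expect_error(lowess_normalize(ct_matrix(v, "filtered")), "s2")
})

test_that("KNN imputation: identity, exact-neighbour case, observed untouched", {
  sim <- simulate_array_dataset(n_assays = 30, missing_midpoint = 1000,
                                seed = 12)
  expect_identical(unclass(knn_impute(sim$ct))[, ], unclass(sim$ct)[, ])

  # an assay equal to three others except one missing cell, k = 3
  set.seed(13)
  prof <- rnorm(8, 28)
  v <- rbind(a1 = prof, a2 = prof, a3 = prof, a4 = prof,
             matrix(rnorm(40, 35, 0.1), nrow = 5,
                    dimnames = list(sprintf("b%d", 1:5), NULL)))
  colnames(v) <- sprintf("s%d", 1:8)
  v["a1", 3] <- NA
  imp <- knn_impute(ct_matrix(v, "filtered"), k = 3)
  expect_equal(unclass(imp)["a1", 3], prof[3])
  obs <- !is.na(v)
  expect_identical(unclass(imp)[obs], v[obs])
})

test_that("KNN imputation equals the exhaustive nearest-neighbour oracle", {
  set.seed(14)
  v <- matrix(rnorm(1000, 28, 2), nrow = 50,
              dimnames = list(sprintf("a%02d", 1:50), sprintf("s%02d", 1:20)))
  v[sample(length(v), 50)] <- NA  # 5% missing
  imp <- knn_impute(ct_matrix(v, "filtered"), k = 10)
  expect_equal(unclass(imp)[, ], knn_oracle(v, 10), tolerance = 1e-12)
})

test_that("KNN warns when neighbours run short and errors with none", {
  v <- matrix(rnorm(12, 28), nrow = 3,
              dimnames = list(c("a1", "a2", "a3"), sprintf("s%d", 1:4)))
  v[1, 1] <- NA
  expect_warning(knn_impute(ct_matrix(v, "filtered"), k = 10),
                 "fewer than k")
  v[, 1] <- NA
  expect_error(suppressWarnings(knn_impute(ct_matrix(v, "filtered"), k = 2)),
               "no eligible neighbour")
})

test_that("winsorization clamps at median +/- c*MAD and is idempotent", {
  # all-within-bounds assay unchanged
  set.seed(15)
  row <- rnorm(40, 28, 0.5)
  m <- make_ct(row, 1, "imputed")
  expect_identical(unclass(shrink_extremes(m))[, ], unclass(m)[, ])

  # MAD = 0: left unchanged even with a wild outlier
  row2 <- c(rep(28, 39), 50)
  m2 <- make_ct(row2, 1, "imputed")
  expect_identical(unname(unclass(shrink_extremes(m2))[1, ]), row2)

  # spread the bulk so MAD > 0: the 50 clamps to median + 3*sigma exactly
  row3 <- c(rep(28, 20), rep(28.4, 19), 50)
  med <- median(row3); sig <- mad(row3)
  expect_gt(sig, 0)
  out3 <- shrink_extremes(make_ct(row3, 1, "imputed"))
  expect_equal(unclass(out3)[1, 40], med + 3 * sig, tolerance = 1e-12)

  # random matrices match a brute-force per-row winsorize oracle
  v <- matrix(rnorm(600, 28, 1.5), nrow = 30,
              dimnames = list(sprintf("a%02d", 1:30), sprintf("s%02d", 1:20)))
  out <- shrink_extremes(ct_matrix(v, "imputed"))
  oracle <- t(apply(v, 1, function(r) {
    m <- median(r); s <- mad(r)
    if (s == 0) r else pmin(pmax(r, m - 3 * s), m + 3 * s)
  }))
  dimnames(oracle) <- dimnames(v)
  expect_equal(unclass(out)[, ], oracle, tolerance = 1e-12)

  expect_identical(unclass(shrink_extremes(out))[, ], unclass(out)[, ])
})

test_that("the pipeline composes in order and reports stage counts", {
  sim <- simulate_array_dataset(n_assays = 150, seed = 16)
  pre <- preprocess_ct(sim$ct)
  expect_equal(ct_stage(pre$ct), "shrunk")
  expect_false(anyNA(pre$ct))
  expect_equal(pre$report$stages,
               c("raw", "filtered", "normalized", "imputed", "shrunk"))

  v <- unclass(sim$ct)
  bad <- rowMeans(is.na(v) | v > 35) >= 0.20
  expect_equal(pre$report$n_excluded, sum(bad))
  expect_equal(pre$report$n_assays_retained, sum(!bad))
  kept <- v[!bad, , drop = FALSE]
  expect_equal(pre$report$n_imputed_cells, sum(is.na(kept) | kept > 35))

  # clean complete matrix (no dropout, baselines clear of the Ct>35
  # censor): filter removes nothing, imputation is identity
  clean <- simulate_array_dataset(n_assays = 40, missing_midpoint = 1000,
                                  baseline_ct_sd = 1.5, seed = 17)
  pre2 <- preprocess_ct(clean$ct)
  expect_equal(pre2$report$n_excluded, 0L)
  expect_equal(pre2$report$n_imputed_cells, 0L)
})

test_that("stage transitions are enforced in pipeline order", {
  sim <- simulate_array_dataset(n_assays = 20, missing_midpoint = 1000,
                                seed = 18)
  shr <- shrink_extremes(knn_impute(lowess_normalize(
    detection_filter(sim$ct)$ct)))
  expect_error(detection_filter(shr), "stage")
  expect_error(lowess_normalize(shr), "stage")
})
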