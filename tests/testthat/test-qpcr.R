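make_wells <- function(assay, cts_by_sample, control = 24) {
  samples <- names(cts_by_sample)
  rows <- list()
  for (s in samples) {
    ct <- cts_by_sample[[s]]
    rows[[length(rows) + 1]] <- data.frame(
      assay_id = assay, sample_id = s,
      well_replicate = seq_along(ct), ct = ct)
    rows[[length(rows) + 1]] <- data.frame(
      assay_id = "RNU48", sample_id = s,
      well_replicate = 1:2, ct = c(control, control))
  }
  qpcr_wells(do.call(rbind, rows))
}

test_that("duplicate reconciliation: mean, deletion, and strict boundary", {
  # agreeing wells: mean
  w <- make_wells("miR-a", list(s1 = c(24.0, 24.5), s2 = c(24.2, 24.4)))
  rec <- reconcile_duplicates(w)
  expect_equal(rec$ct[rec$assay_id == "miR-a" & rec$sample_id == "s1"], 24.25)

  # disagreement > 2: delete the well farther from the assay-wide median
  w2 <- make_wells("miR-a", list(s1 = c(24.0, 27.0), s2 = c(24.3, 24.3),
                                 s3 = c(24.3, 24.3)))
  rec2 <- reconcile_duplicates(w2)
  expect_equal(rec2$ct[rec2$assay_id == "miR-a" & rec2$sample_id == "s1"], 24.0)

  # exactly 2.0 apart: the rule does not trigger (strictly more than 2)
  w3 <- make_wells("miR-a", list(s1 = c(24.0, 26.0), s2 = c(24.0, 24.2)))
  rec3 <- reconcile_duplicates(w3)
  expect_equal(rec3$ct[rec3$assay_id == "miR-a" & rec3$sample_id == "s1"], 25.0)
})

test_that("reconciliation is symmetric in well order and handles gaps", {
  w <- make_wells("miR-a", list(s1 = c(27.0, 24.0), s2 = c(24.3, 24.3),
                                s3 = c(24.3, 24.3)))
  rec <- reconcile_duplicates(w)
  expect_equal(rec$ct[rec$assay_id == "miR-a" & rec$sample_id == "s1"], 24.0)

  # single well kept as-is; both missing -> NA
  w2 <- make_wells("miR-a", list(s1 = c(25.0, NA), s2 = c(NA_real_, NA_real_)))
  rec2 <- reconcile_duplicates(w2)
  expect_equal(rec2$ct[rec2$assay_id == "miR-a" & rec2$sample_id == "s1"], 25.0)
  expect_true(is.na(rec2$ct[rec2$assay_id == "miR-a" & rec2$sample_id == "s2"]))
})

test_that("delta-Ct arithmetic and sample-shift invariance", {
  w <- make_wells("miR-a", list(s1 = c(28, 28), s2 = c(24, 24)))
  mdct <- delta_ct(reconcile_duplicates(w))
  expect_equal(mdct$delta_ct[mdct$sample_id == "s1"], 4)
  expect_equal(mdct$minus_dct[mdct$sample_id == "s1"], -4)
  expect_equal(mdct$minus_dct[mdct$sample_id == "s2"], 0)

  # adding a constant to every well of a sample leaves minus-dCt unchanged
  df <- as.data.frame(w)
  df$ct[df$sample_id == "s1"] <- df$ct[df$sample_id == "s1"] + 5
  mdct2 <- delta_ct(reconcile_duplicates(qpcr_wells(df)))
  expect_equal(mdct2$minus_dct, mdct$minus_dct)
})

test_that("missing control drops the sample with a warning", {
  w <- make_wells("miR-a", list(s1 = c(25, 25), s2 = c(26, 26)))
  df <- as.data.frame(w)
  df$ct[df$assay_id == "RNU48" & df$sample_id == "s2"] <- NA
  expect_warning(mdct <- delta_ct(reconcile_duplicates(qpcr_wells(df))),
                 "s2")
  expect_false("s2" %in% mdct$sample_id)
})

test_that("fold changes exponentiate the minus-dCt difference exactly", {
  design <- make_design(3, 3)
  base <- list(s01 = c(26, 26), s02 = c(26, 26), s03 = c(26, 26),
               s04 = c(27, 27), s05 = c(27, 27), s06 = c(27, 27))
  # d = mean(g1) - mean(g2) of minus-dCt = (-2) - (-3) = +1 -> FC 2
  val <- qpcr_validate(delta_ct(reconcile_duplicates(make_wells("miR-a", base))),
                       design)
  expect_true(val$table$degenerate)  # zero within-group variance flagged
  expect_equal(val$table$fc, 2)

  jit <- lapply(base, function(x) x + rnorm(2, 0, 0.05))
  mdct <- delta_ct(reconcile_duplicates(make_wells("miR-a", jit)))
  val2 <- qpcr_validate(mdct, design)
  expect_equal(log2(val2$table$fc), val2$table$d, tolerance = 1e-12)

  # identical group means: FC = 1 and the CI spans 1
  flat <- list(s01 = c(26, 26.2), s02 = c(26.1, 25.9), s03 = c(26, 26.1),
               s04 = c(26.1, 26), s05 = c(25.9, 26.2), s06 = c(26, 26))
  val3 <- qpcr_validate(delta_ct(reconcile_duplicates(make_wells("miR-a", flat))),
                        design)
  expect_true(val3$table$ci_lo < 1 && val3$table$ci_hi > 1)
  expect_true(val3$table$ci_lo < val3$table$fc & val3$table$fc < val3$table$ci_hi)
})

test_that("fold change, CI and p match a closed-form pooled-t oracle", {
  design <- make_design(4, 5)
  set.seed(50)
  for (rep in 1:10) {
    plate <- simulate_qpcr_plate("miR-x", design,
                                 effect_ct = c("miR-x" = runif(1, -2, 2)),
                                 dup_noise_sd = 0.2, seed = 100 + rep)
    mdct <- delta_ct(reconcile_duplicates(plate$wells))
    val <- qpcr_validate(mdct, design)
    g <- setNames(as.character(design$group), design$sample_id)
    x1 <- mdct$minus_dct[g[mdct$sample_id] == "PGRN+"]
    x2 <- mdct$minus_dct[g[mdct$sample_id] == "PGRN-"]
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(val$table$p, ref$p.value, tolerance = 1e-9)
    expect_equal(val$table$fc, 2^(mean(x1) - mean(x2)), tolerance = 1e-9)
    expect_equal(c(val$table$ci_lo, val$table$ci_hi),
                 2^as.vector(ref$conf.int), tolerance = 1e-9)
  }
})

test_that("planted -1 Ct effects recover a two-fold change across seeds", {
  design <- make_design(8, 12)
  fc <- sapply(1:50, function(s) {
    plate <- simulate_qpcr_plate("miR-x", design,
                                 effect_ct = c("miR-x" = -1),
                                 dup_noise_sd = 0.25, outlier_rate = 0.05,
                                 seed = s)
    qpcr_pipeline(plate$wells, design)$table$fc
  })
  expect_gte(median(fc), 1.8)
  expect_lte(median(fc), 2.2)
})

test_that("detectability flags follow median Ct and missingness", {
  w <- make_wells("miR-dim", list(s1 = c(38, 38), s2 = c(38.5, 38.2),
                                  s3 = c(37.9, 38.1)))
  rec <- reconcile_duplicates(w)
  flags <- detectability_check(rec)
  expect_false(flags[["miR-dim"]])
  expect_true(flags[["RNU48"]])

  w2 <- make_wells("miR-ok", list(s1 = c(25, 25), s2 = c(25.2, 25.1)))
  expect_true(detectability_check(reconcile_duplicates(w2))[["miR-ok"]])

  # brute-force recount on a synthetic plate
  design <- make_design(3, 5)
  plate <- simulate_qpcr_plate(c("miR-a", "miR-b"), design,
                               baseline_ct = c("miR-a" = 37, "miR-b" = 26),
                               seed = 9)
  rec3 <- reconcile_duplicates(plate$wells)
  flags3 <- detectability_check(rec3)
  for (a in names(flags3)) {
    sub <- rec3[rec3$assay_id == a, ]
    expect_equal(flags3[[a]],
                 median(sub$ct, na.rm = TRUE) <= 35 && mean(is.na(sub$ct)) <= 0.5)
  }
})
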