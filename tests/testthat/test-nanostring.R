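make_panel_from_counts <- function(counts_by_lane) {
  # counts_by_lane: named list lane -> named count vector over default_panel
  panel <- default_panel()
  m <- vapply(counts_by_lane, function(x) x[panel$probe_id],
              numeric(nrow(panel)))
  rownames(m) <- panel$probe_id
  count_panel(m, panel)
}

flat_lane <- function(neg = 4, hk = c(ABCF1 = 600, ALAS1 = 900, CLTC = 1200,
                                      HPRT1 = 1500),
                      fusion = 1, tag = 200) {
  panel <- default_panel()
  x <- numeric(nrow(panel)); names(x) <- panel$probe_id
  x[panel$probe_class == "negative_control"] <- neg
  x[names(hk)] <- hk
  x[panel$probe_class == "fusion"] <- fusion
  x[panel$probe_class == "reporter_tag"] <- tag
  x
}

test_that("background threshold is mean(neg) + 2*sqrt(mean(neg)) floored at zero", {
  lanes <- list(L1 = flat_lane(neg = 0, fusion = 20),
                L2 = flat_lane(neg = 4, fusion = 20),
                L3 = flat_lane(neg = 4, fusion = 5))
  p <- background_correct(make_panel_from_counts(lanes))
  B <- attr(p, "background")
  expect_equal(unname(B), c(0, 8, 8))             # 4 + 2*sqrt(4) = 8
  expect_equal(unname(p$counts["PPP1CB_ALK", ]), c(20, 12, 0))
  # negative controls pass through unchanged
  expect_equal(unname(p$counts["NEG_1", ]), c(0, 4, 4))
})

test_that("housekeeping normalization cancels global lane scaling", {
  # zero background so the correction step is the identity: the doubling
  # cancellation is a property of housekeeping normalization itself
  base <- flat_lane(fusion = 40, neg = 0)
  lanes <- list(A = base, B = base, C = 2 * base)
  p <- normalize_housekeeping(background_correct(make_panel_from_counts(lanes)))
  f <- attr(p, "size_factors")
  expect_equal(p$counts["PPP1CB_ALK", "C"], p$counts["PPP1CB_ALK", "A"],
               tolerance = 1e-9)
  # identical lanes get factor 1 when every lane is identical
  same <- normalize_housekeeping(
    background_correct(make_panel_from_counts(list(A = base, B = base))))
  expect_equal(unname(attr(same, "size_factors")), c(1, 1))
  # explicit reference: lane geomean 100 against reference 200 doubles counts
  hk100 <- flat_lane(hk = c(ABCF1 = 100, ALAS1 = 100, CLTC = 100, HPRT1 = 100),
                     fusion = 50, neg = 0)
  p2 <- normalize_housekeeping(make_panel_from_counts(list(A = hk100)) |>
                                 background_correct(),
                               cohort_reference = 200)
  expect_equal(unname(p2$counts["PPP1CB_ALK", "A"]), 100)
})

test_that("normalization is idempotent and zero housekeepers fail QC", {
  p <- make_test_panel(nl = 10)
  n1 <- normalize_housekeeping(background_correct(p))
  n2 <- normalize_housekeeping(n1)
  expect_equal(unname(attr(n2, "size_factors")),
               rep(1, ncol(n1$counts)), tolerance = 1e-12)
  bad <- p
  bad$counts["ABCF1", 1] <- 0
  expect_warning(nb <- normalize_housekeeping(background_correct(bad)),
                 "QC-fail")
  expect_equal(ncol(nb$counts), 9)
})

test_that("3x IQR outlier calling matches the sort-based quantile oracle", {
  vals <- c(10, 12, 11, 13, 10, 11, 12, 400)
  p <- make_panel_from_counts(lapply(seq_along(vals), function(i)
    flat_lane(neg = 0, fusion = 0)))
  colnames(p$counts) <- sprintf("L%d", seq_along(vals))
  p$counts["PPP1CB_ALK", ] <- vals
  calls <- call_fusion_outliers(p)
  alk <- calls[calls$probe_id == "PPP1CB_ALK", ]
  expect_equal(alk$q1[1], oracle_quantile7(vals, 0.25))
  expect_equal(alk$q3[1], oracle_quantile7(vals, 0.75))
  expect_equal(alk$sample_id[alk$outlier], "L8")

  # constant probe: IQR 0, nothing exceeds Q3 + 0
  pc <- make_panel_from_counts(lapply(1:8, function(i) flat_lane(fusion = 7)))
  colnames(pc$counts) <- sprintf("L%d", 1:8)
  expect_false(any(call_fusion_outliers(pc)$outlier))

  # shift invariance of the fence
  shifted <- p
  fus <- p$probes$probe_id[p$probes$probe_class == "fusion"]
  shifted$counts[fus, ] <- shifted$counts[fus, ] + 100
  expect_equal(call_fusion_outliers(shifted)$outlier, calls$outlier)

  expect_error(call_fusion_outliers(make_test_panel(nl = 5)), "batch-size")
})

test_that("quantiles match the oracle on short vectors", {
  set.seed(42)
  for (n in c(4, 5, 8, 11, 12)) {
    x <- round(rlnorm(n, 3, 1))
    for (p in c(0.25, 0.75)) {
      expect_equal(unname(quantile(x, p, type = 7)), oracle_quantile7(x, p))
    }
  }
})

test_that("reporter-tag imbalance detects breakpoint steps, not overexpression", {
  cfg <- default_config()
  set.seed(1)
  nl <- 60
  lanes <- lapply(seq_len(nl), function(i) {
    x <- flat_lane()
    x[sprintf("ALK_TAG_%d", 1:6)] <- rpois(6, 200)
    x
  })
  # lane 1: downstream tags 10x upstream
  lanes[[1]][sprintf("ALK_TAG_%d", 4:6)] <- rpois(3, 2000)
  # lane 2: whole-gene 5x overexpression, balanced tags
  lanes[[2]][sprintf("ALK_TAG_%d", 1:6)] <- rpois(6, 1000)
  p <- make_panel_from_counts(lanes)
  colnames(p$counts) <- sprintf("L%02d", seq_len(nl))
  norm <- normalize_housekeeping(background_correct(p))
  imb <- reporter_imbalance(norm, "ALK", cfg)
  expect_true(imb$call[imb$sample_id == "L01"])
  expect_false(imb$call[imb$sample_id == "L02"])
  expect_lt(sum(imb$call), 2)

  # score is invariant to scaling a lane's tag counts
  p2 <- p
  p2$counts[sprintf("ALK_TAG_%d", 1:6), "L05"] <-
    p2$counts[sprintf("ALK_TAG_%d", 1:6), "L05"] * 3
  # compare raw ratio statistic before normalization interference
  r1 <- reporter_imbalance(p, "ALK", cfg)
  r2 <- reporter_imbalance(p2, "ALK", cfg)
  expect_equal(r2$log2_ratio[r2$sample_id == "L05"],
               r1$log2_ratio[r1$sample_id == "L05"], tolerance = 0.05)

  expect_error(reporter_imbalance(norm, "MET", cfg), "panel-definition")
})
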