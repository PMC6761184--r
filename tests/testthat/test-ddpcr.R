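test_that("Poisson quantification matches the digital-PCR estimator", {
  q0 <- quantify_target(0, 10000, 0.85)
  expect_equal(q0$lambda_hat, 0)
  expect_equal(q0$concentration, 0)

  q <- quantify_target(5000, 10000, 0.85)
  expect_equal(q$lambda_hat, log(2), tolerance = 1e-12)
  expect_equal(q$concentration, log(2) / 0.00085, tolerance = 1e-9)
  expect_equal(round(q$concentration, 2), 815.47)

  expect_error(quantify_target(10000, 10000, 0.85), "saturation")
  expect_error(quantify_target(10001, 10000, 0.85), "input error")
  expect_error(quantify_target(5, 0, 0.85), "input error")
})

test_that("lambda is strictly increasing in the positive fraction", {
  ks <- seq(0, 11000, by = 500)
  lam <- vapply(ks, function(k) quantify_target(k, 12000)$lambda_hat, 0)
  expect_true(all(diff(lam) > 0))
  expect_equal(lam[1], 0)
})

test_that("mutant allele fraction from channel concentrations", {
  expect_equal(mutant_allele_fraction(0, 1.0), 0)
  expect_equal(mutant_allele_fraction(0.5, 0.5), 50)
  expect_equal(round(mutant_allele_fraction(0.0101, 1.0), 1), 1.0)
  expect_error(mutant_allele_fraction(0, 0), "undefined-fraction")
  expect_error(mutant_allele_fraction(-0.1, 1), "input error")
})

test_that("MAF agrees with numeric inversion of the two-channel droplet model", {
  # oracle: recover each lambda by uniroot on k/n = 1 - exp(-lambda)
  n <- 10000
  for (km in c(50, 500, 3000)) for (kw in c(4000, 8000)) {
    lam_m <- uniroot(function(l) (1 - exp(-l)) - km / n, c(0, 10), tol = 1e-12)$root
    lam_w <- uniroot(function(l) (1 - exp(-l)) - kw / n, c(0, 10), tol = 1e-12)$root
    oracle <- 100 * lam_m / (lam_m + lam_w)
    got <- mutant_allele_fraction(quantify_target(km, n)$lambda_hat,
                                  quantify_target(kw, n)$lambda_hat)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("hotspot calling enforces both-replicate MAF and the droplet floor", {
  expect_true(hotspot_rule(c(1.5, 1.2), c(60, 55)))
  expect_false(hotspot_rule(c(2.0, 0.8), c(200, 200)))   # one replicate below 1%
  expect_false(hotspot_rule(c(5, 5), c(49, 120)))        # droplet floor fails once
  expect_true(hotspot_rule(c(1.0, 1.0), c(50, 50)))      # boundaries are inclusive

  # full path from droplet counts: 12000 droplets, ~2% MAF duplex
  assay <- data.frame(n_droplets = 12000,
                      positive_mut = c(95, 90), positive_wt = c(4700, 4650))
  res <- call_hotspot(assay)
  expect_equal(res$call, "positive")
  expect_true(all(res$maf > 1))

  expect_error(call_hotspot(assay[1, , drop = FALSE]), "design error")
  sat <- data.frame(n_droplets = 100, positive_mut = c(5, 5),
                    positive_wt = c(100, 90))
  expect_error(call_hotspot(sat), "saturation")
})

test_that("copy-number calibration and the CDKN2A deletion boundary", {
  expect_equal(copy_number_value(0.6, 0.6, 1), 2)        # calibration identity
  expect_equal(copy_number_value(0, 0.6, 1), 0)          # zero-copy control
  expect_equal(copy_number_value(0.55, 1, 1), 1.1)
  expect_error(copy_number_value(0.5, 0), "division error")

  expect_equal(call_cdkn2a(1.19), "deleted")              # strict inequality
  expect_equal(call_cdkn2a(1.2), "neutral")               # boundary excluded
  expect_equal(call_cdkn2a(2.0), "neutral")
  expect_error(call_cdkn2a(-1), "input error")
})

test_that("FGFR1 TKD duplication boundary is inclusive at the printed ratio", {
  expect_equal(call_fgfr1_tkd(1.0, 1.0)$call, "neutral")
  expect_equal(call_fgfr1_tkd(1.125, 1.0)$call, "duplicated")
  r <- call_fgfr1_tkd(1.2, 1.0)
  expect_equal(r$call, "duplicated")
  expect_equal(r$ratio, 1.2)
  expect_error(call_fgfr1_tkd(1.2, 0), "division error")
})

test_that("calling is pure and thresholds are config-driven", {
  assay <- data.frame(n_droplets = 12000,
                      positive_mut = c(95, 90), positive_wt = c(4700, 4650))
  expect_identical(call_hotspot(assay), call_hotspot(assay))
  strict <- pipeline_config(ddpcr = list(maf_threshold_pct = 5))
  expect_equal(call_hotspot(assay, strict)$call, "negative")
  perm <- pipeline_config(ddpcr = list(fgfr1_tkd_ratio = 1.5))
  expect_equal(call_fgfr1_tkd(1.4, 1.0, perm)$call, "neutral")
})

test_that("cohort droplet tables produce one call per sample and target", {
  cohort <- reference_cohort()[c(6, 36, 44, 118), ]   # ALK, V600E, TKD, NONE
  cfg <- default_config()
  droplets <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    simulate_ddpcr_assay(cohort[i, ], cfg, noiseless = TRUE)))
  calls <- call_ddpcr_table(droplets, cfg)
  expect_equal(nrow(calls), 8)
  v600 <- calls[calls$target == "BRAF_V600E", ]
  expect_equal(v600$call[v600$sample_id == cohort$sample_id[2]], "positive")
  expect_equal(sum(v600$call == "positive"), 1)
  tkd <- calls[calls$target == "FGFR1_TKD", ]
  expect_equal(tkd$call[tkd$sample_id == cohort$sample_id[3]], "duplicated")
  expect_equal(sum(tkd$call == "duplicated"), 1)
})
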