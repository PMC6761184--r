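test_that("cohort generation is seeded, validated and distributionally correct", {
  sc <- sim_config(n_samples = 60, seed = 7)
  expect_identical(generate_cohort(sc), generate_cohort(sc))

  all_none <- sim_config(n_samples = 50, driver_frequencies = c(NONE = 1),
                         seed = 1)
  expect_true(all(generate_cohort(all_none)$true_driver == "NONE"))

  bad <- sc; bad$driver_frequencies <- c(NONE = 0.6, OTHER = 0.6)
  expect_error(generate_cohort(bad), "configuration error")
  expect_error(sim_config(n_samples = -5), "configuration error")

  # marginal convergence: empirical fraction within 3 binomial SDs
  freq <- c(KIAA1549_BRAF = 0.237, NONE = 0.763)
  big <- generate_cohort(sim_config(10000, freq, seed = 3))
  phat <- mean(big$true_driver == "KIAA1549_BRAF")
  expect_lt(abs(phat - 0.237), 3 * sqrt(0.237 * 0.763 / 10000))

  # structural invariants of the latent truth
  co <- generate_cohort(sim_config(500, seed = 5))
  expect_true(all((co$true_vaf > 0) == (co$true_driver == "BRAF_V600E")))
  expect_true(all(co$location %in% location_levels()))
})

test_that("droplet simulation respects the partition range and the VAF", {
  cfg <- default_config()
  wt <- data.frame(sample_id = "S1", true_driver = "NONE", true_vaf = 0)
  set.seed(2)
  d <- simulate_ddpcr_assay(wt, cfg, targets = "BRAF_V600E")
  expect_equal(d$positive_mut, c(0, 0))   # VAF 0 gives lambda 0 exactly
  expect_equal(nrow(d), 2)
  expect_true(all(d$n_droplets >= 10000 & d$n_droplets <= 15000))

  set.seed(4); a <- simulate_ddpcr_assay(wt, cfg)
  set.seed(4); b <- simulate_ddpcr_assay(wt, cfg)
  expect_identical(a, b)

  bad <- pipeline_config(); bad$simulation$wildtype_lambda <- -1
  expect_error(simulate_ddpcr_assay(wt, bad), "configuration error")
})

test_that("Monte-Carlo MAF recovery is unbiased at the published design", {
  # 2000 duplicate assays at VAF 10%, wild-type lambda 0.5
  cfg <- default_config()
  truth <- data.frame(sample_id = "S1", true_driver = "BRAF_V600E",
                      true_vaf = 0.10)
  set.seed(1)
  mafs <- replicate(2000, {
    d <- simulate_ddpcr_assay(truth, cfg, targets = "BRAF_V600E")
    lm <- mean(-log1p(-d$positive_mut / d$n_droplets))
    lw <- mean(-log1p(-d$positive_wt / d$n_droplets))
    100 * lm / (lm + lw)
  })
  expect_lt(abs(mean(mafs) - 10), 0.5)
})

test_that("count-lane simulation produces the constructed signal shapes", {
  cfg <- default_config()
  panel <- default_panel()
  # fused sample with unknown partner: downstream tags up, upstream flat
  alk <- data.frame(sample_id = "S1", true_driver = "ALK_FUSION",
                    partner_known = FALSE)
  lane <- simulate_count_lane(alk, cfg, panel, size_factor = 1, noiseless = TRUE)
  up <- lane[sprintf("ALK_TAG_%d", 1:3)]
  dn <- lane[sprintf("ALK_TAG_%d", 4:6)]
  expect_true(all(dn == 10 * up))
  expect_equal(unname(lane["PPP1CB_ALK"]), 1)  # partner unknown: junction silent

  known <- alk; known$partner_known <- TRUE
  lk <- simulate_count_lane(known, cfg, panel, size_factor = 1, noiseless = TRUE)
  expect_equal(unname(lk["PPP1CB_ALK"]), 50)

  # size factor scales every probe mean
  l2 <- simulate_count_lane(known, cfg, panel, size_factor = 2, noiseless = TRUE)
  expect_equal(unname(l2), unname(2 * lk))

  badpanel <- panel; badpanel$probe_class[1] <- "mystery"
  expect_error(simulate_count_lane(alk, cfg, badpanel), "configuration error")
})

test_that("no extreme-outlier fusion call arises in a 50-lane null cohort", {
  set.seed(1)
  cfg <- default_config()
  null_cohort <- data.frame(sample_id = sprintf("N%02d", 1:50),
                            true_driver = "NONE", partner_known = FALSE)
  p <- simulate_count_matrix(null_cohort, cfg)
  res <- call_count_panel(p, cfg)
  expect_equal(sum(res$outliers$outlier), 0)
})

test_that("survival simulation honours medians, censoring and PFS <= OS", {
  cfg <- default_config()
  co <- data.frame(sample_id = sprintf("S%03d", 1:300), group = "GROUP2")
  set.seed(8)
  s <- simulate_survival(co, cfg)
  expect_true(all(s$pfs_time <= s$os_time + 1e-12))
  expect_true(all(s$os_event %in% 0:1))

  allc <- pipeline_config(survival_sim = list(censoring_rate = 1))
  sc <- simulate_survival(co, allc)
  expect_true(all(sc$os_event == 0) && all(sc$pfs_event == 0))

  # exponential KM recovery: median 2.0 y at n = 5000, no censoring
  cfg2 <- pipeline_config(survival_sim = list(
    median_os = c(GROUP1 = 2, GROUP2 = 2, GROUP3 = 2, UNCLASSIFIED = 2),
    censoring_rate = 0))
  big <- data.frame(sample_id = sprintf("S%04d", 1:5000), group = "GROUP1")
  set.seed(12)
  sb <- simulate_survival(big, cfg2)
  km <- km_estimate(sb$os_time, sb$os_event)
  med <- min(km$time[km$surv <= 0.5])
  expect_lt(abs(med - 2.0), 0.1)

  badm <- pipeline_config(); badm$survival_sim$median_os[1] <- -1
  expect_error(simulate_survival(co, badm), "configuration error")
})
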