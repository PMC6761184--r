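test_that("fusion annotation assigns kinase-domain retention and pathway", {
  models <- kinase_domain_models()
  # PPP1CB-ALK, ALK breakpoint upstream of the kinase domain: activating RTK
  f <- annotate_fusion(list(gene_5p = "PPP1CB", exon_5p = 5,
                            gene_3p = "ALK", exon_3p = 20), models)
  expect_true(f$tkd_retained)
  expect_equal(f$driver, "ALK_FUSION")
  expect_equal(f$pathway, "RTK")

  k <- annotate_fusion(list(gene_5p = "KIAA1549", exon_5p = 15,
                            gene_3p = "BRAF", exon_3p = 9), models)
  expect_equal(k$pathway, "RAS_MAPK")
  expect_true(k$tkd_retained)

  # breakpoint downstream of the kinase domain: non-activating
  dn <- annotate_fusion(list(gene_5p = "PPP1CB", exon_5p = 5,
                             gene_3p = "ALK", exon_3p = 27), models)
  expect_false(dn$tkd_retained)

  unk <- annotate_fusion(list(gene_5p = "AAA", exon_5p = 1,
                              gene_3p = "ZZZ9", exon_3p = 2), models)
  expect_true(is.na(unk$tkd_retained))
  expect_equal(unk$driver, "OTHER")
})

test_that("pathway mapping is the fixed driver-to-pathway table", {
  expect_equal(pathway_class("NTRK_FUSION"), "RTK")     # e.g. ETV6-NTRK3
  expect_equal(pathway_class("MYBL1_GAIN"), "RAS_MAPK")
  expect_equal(pathway_class("NONE"), "NONE")
  expect_equal(pathway_class(c("ALK_FUSION", "BRAF_V600E", "OTHER")),
               c("RTK", "RAS_MAPK", "OTHER"))
  expect_error(pathway_class("BANANA"), "mapping error")
})

test_that("multi-caller consensus merges within tolerance and filters support", {
  expect_equal(nrow(consensus_fusions(NULL)), 0)
  empty <- data.frame(gene_5p = character(), exon_5p = integer(),
                      gene_3p = character(), exon_3p = integer(),
                      caller = character())
  expect_equal(nrow(consensus_fusions(empty)), 0)

  two <- data.frame(gene_5p = "PPP1CB", exon_5p = c(5, 5),
                    gene_3p = "ALK", exon_3p = c(20, 21),
                    caller = c("defuse", "ericscript"))
  m <- consensus_fusions(two, min_support = 2, tolerance = 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_callers, 2)
  expect_equal(m$supporting_callers, "defuse,ericscript")

  one <- two[1, ]
  expect_equal(nrow(consensus_fusions(one, min_support = 2)), 0)

  # beyond tolerance: two separate records, each unsupported
  far <- data.frame(gene_5p = "PPP1CB", exon_5p = c(5, 5),
                    gene_3p = "ALK", exon_3p = c(20, 25),
                    caller = c("defuse", "tophat"))
  expect_equal(nrow(consensus_fusions(far, min_support = 2, tolerance = 1)), 0)
})

test_that("consensus is invariant to input order (associativity)", {
  set.seed(7)
  base <- data.frame(
    gene_5p = sample(c("PPP1CB", "ETV6", "KIAA1549"), 12, TRUE),
    exon_5p = sample(4:6, 12, TRUE),
    gene_3p = NA, exon_3p = sample(19:21, 12, TRUE),
    caller = sample(c("defuse", "tophat", "ericscript", "fusionmap"), 12, TRUE))
  base$gene_3p <- c(PPP1CB = "ALK", ETV6 = "NTRK3", KIAA1549 = "BRAF")[base$gene_5p]
  ref <- consensus_fusions(base)
  for (i in 1:5) {
    perm <- base[sample(nrow(base)), ]
    expect_equal(consensus_fusions(perm), ref)
  }
})

test_that("tier-1 positivity suppresses tier-2 evidence", {
  t1 <- data.frame(assay_class = "snv_hotspot", driver = "BRAF_V600E",
                   positive = TRUE)
  t2 <- data.frame(assay_class = "panel_fusion", driver = "ALK_FUSION",
                   positive = TRUE)
  r <- integrate_sample("S1", t1, t2)
  expect_equal(r$driver, "BRAF_V600E")
  expect_equal(r$evidence_tier, 1)

  neg <- data.frame(assay_class = "snv_hotspot", driver = "BRAF_V600E",
                    positive = FALSE)
  r2 <- integrate_sample("S1", neg, t2)
  expect_equal(r2$driver, "ALK_FUSION")
  expect_equal(r2$evidence_tier, 2)

  r3 <- integrate_sample("S1", neg, NULL)
  expect_equal(r3$driver, "NONE")
  expect_equal(r3$pathway, "NONE")
})

test_that("within-tier conflicts follow the configured precedence", {
  both <- data.frame(
    assay_class = c("panel_fusion", "snv_hotspot", "cnv"),
    driver = c("KIAA1549_BRAF", "BRAF_V600E", "FGFR1_TKD"),
    positive = c(TRUE, TRUE, TRUE))
  r <- integrate_sample("S1", both)
  expect_equal(r$driver, "BRAF_V600E")   # snv_hotspot outranks fusion and cnv
  expect_true(r$conflict)

  # integration is order-independent
  r2 <- integrate_sample("S1", both[c(3, 1, 2), ])
  expect_equal(r2$driver, r$driver)

  dup <- data.frame(assay_class = "snv_hotspot", driver = "BRAF_V600E",
                    positive = c(TRUE, FALSE))
  expect_error(integrate_sample("S1", dup), "input-integrity")
})
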