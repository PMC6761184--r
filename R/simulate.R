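# Synthetic-cohort generation: latent ground truth plus raw assay data,
# emulating (a) droplet partitioning given target concentrations, (b) count
# lanes with negative-control noise, housekeeping structure, fusion-probe
# signal and reporter-tag profiles, (c) censored survival times.

#' Default count-panel definition
#'
#' Junction probes for the recurrent fusions (KIAA1549-BRAF, FGFR1-TACC1,
#' PML-RAF1 and the canonical RTK fusions PPP1CB-ALK, CCDC88A-ALK,
#' GOPC-ROS1, ETV6-NTRK3), the four housekeeping transcripts, eight
#' negative-control spikes, and reporter-tag systems (three tags on each
#' side of the breakpoint hotspot) for ALK, ROS1 and NTRK2. Probe identity
#' is modelled at gene/exon granularity; real probe sequences are
#' proprietary.
#'
#' @return probe annotation data frame suitable for \code{\link{count_panel}}.
#' @export
default_panel <- function() {
  fus <- data.frame(
    probe_id = c("KIAA1549_BRAF", "FGFR1_TACC1", "PML_RAF1",
                 "PPP1CB_ALK", "CCDC88A_ALK", "GOPC_ROS1", "ETV6_NTRK3"),
    probe_class = "fusion",
    gene_5p = c("KIAA1549", "FGFR1", "PML", "PPP1CB", "CCDC88A", "GOPC", "ETV6"),
    gene_3p = c("BRAF", "TACC1", "RAF1", "ALK", "ALK", "ROS1", "NTRK3"),
    gene = NA_character_, tag_index = NA_integer_, tag_side = NA_character_)
  hk <- data.frame(probe_id = c("ABCF1", "ALAS1", "CLTC", "HPRT1"),
                   probe_class = "housekeeping", gene_5p = NA, gene_3p = NA,
                   gene = NA_character_, tag_index = NA_integer_,
                   tag_side = NA_character_)
  neg <- data.frame(probe_id = sprintf("NEG_%d", 1:8),
                    probe_class = "negative_control", gene_5p = NA, gene_3p = NA,
                    gene = NA_character_, tag_index = NA_integer_,
                    tag_side = NA_character_)
  tags <- do.call(rbind, lapply(c("ALK", "ROS1", "NTRK2"), function(g)
    data.frame(probe_id = sprintf("%s_TAG_%d", g, 1:6),
               probe_class = "reporter_tag", gene_5p = NA, gene_3p = NA,
               gene = g, tag_index = 1:6,
               tag_side = rep(c("upstream", "downstream"), each = 3))))
  rbind(fus, hk, neg, tags)
}

# gene whose fusion probe carries a given driver's signal (MET is off-panel)
driver_probe <- function(driver) {
  switch(driver,
         KIAA1549_BRAF = "KIAA1549_BRAF", FGFR1_TACC1 = "FGFR1_TACC1",
         PML_RAF1 = "PML_RAF1", ALK_FUSION = "PPP1CB_ALK",
         ROS1_FUSION = "GOPC_ROS1", NTRK_FUSION = "ETV6_NTRK3", NULL)
}

driver_tag_gene <- function(driver) {
  switch(driver, ALK_FUSION = "ALK", ROS1_FUSION = "ROS1",
         NTRK_FUSION = "NTRK2", NULL)
}

#' Build a simulation configuration
#'
#' Cohort-level defaults describe the published cohort structure: driver
#' frequencies default to the observed 118-sample marginals, tumor location
#' and grade are drawn conditionally on driver class at the observed rates,
#' and assay noise defaults come from \code{\link{default_config}}.
#'
#' @param n_samples cohort size.
#' @param driver_frequencies named probabilities over
#'   \code{\link{driver_levels}} summing to 1.
#' @param seed integer seed.
#' @param config pipeline configuration supplying assay and survival
#'   parameters.
#' @return validated simulation configuration list.
#' @export
sim_config <- function(n_samples = 118L,
                       driver_frequencies = NULL,
                       seed = 1L,
                       config = default_config()) {
  if (is.null(driver_frequencies)) {
    driver_frequencies <- c(KIAA1549_BRAF = 28, BRAF_V600E = 21,
                            FGFR1_TACC1 = 3, FGFR1_TKD = 2, PML_RAF1 = 1,
                            MYBL1_GAIN = 1, ALK_FUSION = 12, ROS1_FUSION = 8,
                            NTRK_FUSION = 7, MET_FUSION = 3,
                            OTHER = 16, NONE = 16) / 118
  }
  sc <- list(n_samples = as.integer(n_samples),
             driver_frequencies = driver_frequencies,
             seed = as.integer(seed),
             config = config)
  validate_sim_config(sc)
  sc
}

#' Validate a simulation configuration
#' @param sc result of \code{\link{sim_config}}.
#' @return \code{sc} invisibly; errors on invalid values.
#' @export
validate_sim_config <- function(sc) {
  f <- sc$driver_frequencies
  if (sc$n_samples < 0)
    stop("configuration error: n_samples must be >= 0", call. = FALSE)
  if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("configuration error: driver frequencies must lie in [0,1] and sum to 1",
         call. = FALSE)
  if (!all(names(f) %in% driver_levels()))
    stop("configuration error: unknown driver in frequencies", call. = FALSE)
  validate_config(sc$config)
  invisible(sc)
}

#' Generate a synthetic cohort with latent ground truth
#'
#' Each sample gets exactly one true driver (these tumors are
#' overwhelmingly single-driver), a location and grade drawn conditionally
#' on the driver class at the observed cohort rates, an age at diagnosis,
#' extent of surgery, a true variant allele fraction for SNV drivers, and
#' a flag for whether the fusion partner is on the panel.
#'
#' @param sc simulation configuration from \code{\link{sim_config}}.
#' @return data frame of latent truth, one row per sample.
#' @export
generate_cohort <- function(sc) {
  validate_sim_config(sc)
  set.seed(sc$seed)
  n <- sc$n_samples
  drv <- sample(names(sc$driver_frequencies), n, replace = TRUE,
                prob = sc$driver_frequencies)
  pw <- pathway_class(drv)
  # conditional location rates from the observed cohort structure
  p_hemi <- ifelse(pw == "RTK", 29 / 30,
                   ifelse(pw == "RAS_MAPK", 17 / 56, 19 / 32))
  location <- ifelse(stats::runif(n) < p_hemi, "hemispheric", "midline")
  # RAS/MAPK tumors are LGG; RTK mostly HGG (25/30 incl. mixed)
  grade <- ifelse(pw == "RAS_MAPK", "LGG",
                  ifelse(pw == "RTK",
                         ifelse(stats::runif(n) < 25 / 30, "HGG", "LGG"),
                         ifelse(stats::runif(n) < 0.25, "HGG", "LGG")))
  sel <- which(grade == "HGG" & pw == "RTK")
  grade[sel[stats::runif(length(sel)) < 3 / 25]] <- "mixed"
  histology <- ifelse(grade == "LGG" & location == "midline" &
                        stats::runif(n) < 27 / 39, "pilocytic astrocytoma",
                      ifelse(grade %in% c("HGG", "mixed"), "glioblastoma",
                             "low-grade glioma, NOS"))
  opg_flag <- location == "midline" & pw == "RAS_MAPK" & stats::runif(n) < 31 / 39
  age_mu <- ifelse(pw == "RTK", 3.8, ifelse(location == "hemispheric", 9.0, 7.5))
  age <- pmax(0, stats::rnorm(n, age_mu, 3.5))
  surgery <- ifelse(location == "hemispheric",
                    sample(c("none", "biopsy", "partial", "GTR"), n, TRUE,
                           prob = c(0.05, 0.2, 0.3, 0.45)),
                    sample(c("none", "biopsy", "partial", "GTR"), n, TRUE,
                           prob = c(0.05, 0.33, 0.54, 0.08)))
  vaf <- ifelse(drv == "BRAF_V600E", stats::runif(n, 0.1, 0.5), 0)
  partner_known <- ifelse(pw == "RTK" & drv != "MET_FUSION",
                          stats::runif(n) < 0.7, drv %in%
                            c("KIAA1549_BRAF", "FGFR1_TACC1", "PML_RAF1"))
  data.frame(sample_id = sprintf("SYN%04d", seq_len(n)),
             true_driver = drv, location = location, grade = grade,
             histology = histology, opg_flag = opg_flag,
             age_at_dx = round(age, 1), surgery = surgery,
             true_vaf = vaf, partner_known = partner_known,
             stringsAsFactors = FALSE)
}

#' Simulate duplicate ddPCR assays for one sample
#'
#' Droplet totals are drawn uniformly from the configured range
#' (10,000-15,000 by default) and per-channel positives from
#' Binomial(n, 1 - exp(-lambda)). Hotspot duplexes set the mutant-channel
#' concentration from the sample's true VAF
#' (\eqn{\lambda_{mut} = \lambda_{wt} v/(1-v)}, so the implied MAF equals
#' the VAF); the FGFR1 duplex multiplies the exon-16 channel by the
#' configured true ratio for TKD-duplicated samples. With
#' \code{noiseless = TRUE}, totals are fixed at 12,000 and positives at
#' their rounded expectations.
#'
#' @param truth one row of a \code{\link{generate_cohort}} cohort.
#' @param config pipeline configuration.
#' @param targets ddPCR targets to run (default the BRAF V600E hotspot and
#'   the FGFR1 TKD duplex).
#' @param noiseless logical; deterministic expected counts.
#' @return droplet table: \code{sample_id}, \code{target}, \code{replicate},
#'   \code{n_droplets}, \code{positive_mut}, \code{positive_wt}.
#' @export
simulate_ddpcr_assay <- function(truth, config = default_config(),
                                 targets = c("BRAF_V600E", "FGFR1_TKD"),
                                 noiseless = FALSE) {
  s <- config$simulation
  if (s$wildtype_lambda < 0)
    stop("configuration error: negative concentration", call. = FALSE)
  lam_wt <- s$wildtype_lambda
  rows <- list()
  for (tg in targets) {
    if (tg == "FGFR1_TKD") {
      ratio <- if (truth$true_driver == "FGFR1_TKD") s$tkd_true_ratio else 1
      lm <- lam_wt * ratio          # exon 16 channel
      lw <- lam_wt                  # exon 8 channel
    } else {
      v <- if (truth$true_driver == tg) truth$true_vaf else 0
      lm <- lam_wt * v / (1 - v)
      lw <- lam_wt
    }
    for (rep_i in seq_len(config$ddpcr$n_replicates)) {
      if (noiseless) {
        nd <- 12000L
        pm <- round(nd * (1 - exp(-lm)))
        pw <- round(nd * (1 - exp(-lw)))
      } else {
        nd <- sample(seq(s$n_droplets_range[1], s$n_droplets_range[2]), 1)
        pm <- stats::rbinom(1, nd, 1 - exp(-lm))
        pw <- stats::rbinom(1, nd, 1 - exp(-lw))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = truth$sample_id, target = tg, replicate = rep_i,
        n_droplets = nd, positive_mut = pm, positive_wt = pw)
    }
  }
  do.call(rbind, rows)
}

#' Simulate one count lane
#'
#' Negative controls are Poisson around the configured background mean;
#' housekeepers are lognormal around their configured means with the
#' configured CV; fusion junction probes sit at a one-count baseline unless
#' they match the sample's driver (then elevated by the configured fold
#' change); reporter tags are flat except downstream of the breakpoint in
#' fused samples, where they are stepped up. Every probe mean is scaled by
#' a per-lane size factor.
#'
#' @param truth one cohort row.
#' @param config pipeline configuration.
#' @param panel probe annotation (default \code{\link{default_panel}}).
#' @param size_factor optional fixed per-lane scale; default lognormal with
#'   the configured CV.
#' @param noiseless logical; counts at their rounded expectations.
#' @return named count vector over the panel's probes.
#' @export
simulate_count_lane <- function(truth, config = default_config(),
                                panel = default_panel(), size_factor = NULL,
                                noiseless = FALSE) {
  s <- config$simulation
  bad <- setdiff(unique(panel$probe_class),
                 c("fusion", "housekeeping", "negative_control", "reporter_tag"))
  if (length(bad))
    stop("configuration error: unknown probe class ", paste(bad, collapse = ","),
         call. = FALSE)
  if (is.null(size_factor))
    size_factor <- if (noiseless) 1 else
      stats::rlnorm(1, -0.5 * log(1 + s$size_factor_cv^2),
                    sqrt(log(1 + s$size_factor_cv^2)))
  mu <- numeric(nrow(panel)); names(mu) <- panel$probe_id
  mu[panel$probe_class == "negative_control"] <- s$negative_control_mean
  hk <- panel$probe_id[panel$probe_class == "housekeeping"]
  mu[hk] <- s$housekeeping_means[hk]
  mu[panel$probe_class == "fusion"] <- s$fusion_baseline_mean
  pp <- driver_probe(truth$true_driver)
  if (!is.null(pp) && isTRUE(truth$partner_known) && pp %in% panel$probe_id)
    mu[pp] <- s$fusion_baseline_mean * s$fusion_fold_change
  tagsel <- panel$probe_class == "reporter_tag"
  mu[tagsel] <- s$reporter_tag_baseline
  tg <- driver_tag_gene(truth$true_driver)
  if (!is.null(tg)) {
    dn <- tagsel & panel$gene == tg & panel$tag_side == "downstream"
    mu[which(dn)] <- s$reporter_tag_baseline * s$reporter_tag_step
  }
  mu <- mu * size_factor
  if (noiseless) return(round(mu))
  # housekeepers carry extra lognormal biological/technical noise
  cv <- s$housekeeping_cv
  mu[hk] <- mu[hk] * stats::rlnorm(length(hk), -0.5 * log(1 + cv^2),
                                   sqrt(log(1 + cv^2)))
  counts <- stats::rpois(length(mu), mu)
  names(counts) <- names(mu)
  counts
}

#' Simulate a cohort count panel
#'
#' One lane per cohort row, assembled into a \code{\link{count_panel}}.
#'
#' @param cohort cohort data frame.
#' @param config pipeline configuration.
#' @param panel probe annotation.
#' @param noiseless logical.
#' @return \code{count_panel}.
#' @export
simulate_count_matrix <- function(cohort, config = default_config(),
                                  panel = default_panel(), noiseless = FALSE) {
  lanes <- vapply(seq_len(nrow(cohort)), function(i)
    simulate_count_lane(cohort[i, ], config, panel, noiseless = noiseless),
    numeric(nrow(panel)))
  colnames(lanes) <- cohort$sample_id
  rownames(lanes) <- panel$probe_id
  count_panel(lanes, panel)
}

#' Simulate tier-2 evidence tables
#'
#' Transcriptome fusion-caller candidates (three of the four configured
#' callers, breakpoints jittered by at most one exon) for fusion drivers,
#' and pre-called copy-number events for MYBL1 gains. OTHER drivers emit a
#' non-recurrent fusion pair so the tier-2 route is exercised without
#' mapping to an enumerated driver.
#'
#' @param cohort cohort data frame.
#' @param config pipeline configuration.
#' @param noiseless logical; suppresses breakpoint jitter.
#' @return list with \code{fusions} (caller candidate table, per sample)
#'   and \code{cnv} (pre-called events).
#' @export
simulate_tier2_evidence <- function(cohort, config = default_config(),
                                    noiseless = FALSE) {
  pairs <- list(
    KIAA1549_BRAF = c("KIAA1549", 15L, "BRAF", 9L),
    FGFR1_TACC1   = c("FGFR1", 17L, "TACC1", 7L),
    PML_RAF1      = c("PML", 3L, "RAF1", 8L),
    ALK_FUSION    = c("PPP1CB", 5L, "ALK", 20L),
    ROS1_FUSION   = c("GOPC", 7L, "ROS1", 35L),
    NTRK_FUSION   = c("ETV6", 5L, "NTRK3", 14L),
    MET_FUSION    = c("TFG", 4L, "MET", 14L),
    OTHER         = c("EWSR1", 8L, "PATZ1", 1L))
  callers <- config$integration$callers
  frows <- list(); crows <- list()
  for (i in seq_len(nrow(cohort))) {
    d <- cohort$true_driver[i]
    if (d == "MYBL1_GAIN") {
      crows[[length(crows) + 1L]] <- data.frame(
        sample_id = cohort$sample_id[i], gene = "MYBL1", event = "gain")
    } else if (!is.null(pairs[[d]])) {
      p <- pairs[[d]]
      for (k in 1:3) {
        jit <- if (noiseless) c(0L, 0L) else
          sample(c(-1L, 0L, 0L, 1L), 2, replace = TRUE)
        frows[[length(frows) + 1L]] <- data.frame(
          sample_id = cohort$sample_id[i],
          gene_5p = p[1], exon_5p = as.integer(p[2]) + jit[1],
          gene_3p = p[3], exon_3p = as.integer(p[4]) + jit[2],
          caller = callers[k], source = "wts")
      }
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(fusions = bind(frows,
         data.frame(sample_id = character(), gene_5p = character(),
                    exon_5p = integer(), gene_3p = character(),
                    exon_3p = integer(), caller = character(),
                    source = character())),
       cnv = bind(crows, data.frame(sample_id = character(),
                                    gene = character(), event = character())))
}

#' Simulate censored survival endpoints for a classified cohort
#'
#' OS event times are exponential with the configured per-group median
#' (rate = log 2 / median); the PFS event is the earlier of an independent
#' exponential draw at the PFS median and the OS event, so PFS <= OS by
#' construction while the OS marginal stays exactly exponential.
#' With probability \code{censoring_rate} a uniform censoring time on
#' (0, PFS event time) is drawn and applied to both endpoints, so a rate
#' of 1 censors every record and PFS time <= OS time always holds. Note
#' this mechanism is informative; unbiased-recovery checks should run at
#' rate 0 (see the methods vignette).
#'
#' @param cohort data frame with a \code{group} column.
#' @param config pipeline configuration (survival_sim block).
#' @return cohort with \code{os_time}, \code{os_event}, \code{pfs_time},
#'   \code{pfs_event} (years / 0-1) appended.
#' @export
simulate_survival <- function(cohort, config = default_config()) {
  ss <- config$survival_sim
  if (any(ss$median_pfs <= 0) || any(ss$median_os <= 0))
    stop("configuration error: medians must be positive", call. = FALSE)
  n <- nrow(cohort)
  g <- ifelse(cohort$group %in% names(ss$median_os), cohort$group, "UNCLASSIFIED")
  os_ev <- stats::rexp(n, log(2) / ss$median_os[g])
  pfs_ev <- pmin(stats::rexp(n, log(2) / ss$median_pfs[g]), os_ev)
  cens <- stats::runif(n) < ss$censoring_rate
  ctime <- stats::runif(n, 0, pfs_ev)
  cohort$pfs_time <- ifelse(cens, ctime, pfs_ev)
  cohort$pfs_event <- as.integer(!cens)
  cohort$os_time <- ifelse(cens, ctime, os_ev)
  cohort$os_event <- as.integer(!cens)
  cohort
}
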