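#' Default pipeline configuration
#'
#' Every calling threshold used by the pipeline lives here and nowhere else.
#' The assay thresholds default to the published rule set:
#' \itemize{
#'   \item \code{maf_threshold_pct = 1}: a hotspot call requires a minimum 1\%
#'     mutant allele frequency in both duplicate runs;
#'   \item \code{droplet_floor = 50}: and at least 50 fluorescent (positive)
#'     droplets per replicate;
#'   \item \code{cdkn2a_deleted_below = 1.2}: CDKN2A is called deleted
#'     strictly below a copy-number value of 1.2;
#'   \item \code{fgfr1_tkd_ratio = 1.125}: the FGFR1 exon16:exon8
#'     concentration ratio at or above which the tyrosine-kinase-domain
#'     duplication is called;
#'   \item \code{iqr_multiplier = 3}: the extreme-outlier fence
#'     Q3 + 3*IQR used for count-panel fusion detection.
#' }
#' Simulation defaults describe a realistic nCounter/ddPCR experiment; see
#' the methods vignette for the rationale behind each noise level.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    ddpcr = list(
      droplet_volume_nl = 0.85,     # vendor-standard droplet volume, nL
      maf_threshold_pct = 1,
      droplet_floor     = 50,
      n_replicates      = 2L,
      cdkn2a_deleted_below = 1.2,
      fgfr1_tkd_ratio   = 1.125,
      maf_from_corrected = TRUE     # MAF from Poisson-corrected lambdas, not raw fractions
    ),
    nanostring = list(
      background_method = "poisson",  # mean(neg) + 2*sqrt(mean(neg)); "mean" = plain subtraction
      iqr_multiplier    = 3,
      min_lanes         = 8L,
      imbalance_z       = 5,
      imbalance_pseudocount = 1,
      imbalance_min_downstream = 10,
      quantile_type     = 7L          # linear interpolation between order statistics
    ),
    integration = list(
      min_support = 2L,
      breakpoint_tolerance = 1L,
      tier1_precedence = c("snv_hotspot", "panel_fusion", "cnv"),
      callers = c("defuse", "tophat", "ericscript", "fusionmap")
    ),
    simulation = list(
      n_droplets_range     = c(10000L, 15000L),
      wildtype_lambda      = 0.5,    # wild-type copies per droplet
      negative_control_mean = 4,
      housekeeping_means   = c(ABCF1 = 600, ALAS1 = 900, CLTC = 1200, HPRT1 = 1500),
      housekeeping_cv      = 0.2,
      fusion_baseline_mean = 1,      # junction probe in fusion-negative RNA
      fusion_fold_change   = 50,
      reporter_tag_baseline = 200,
      reporter_tag_step    = 10,     # downstream/upstream fold for fused samples
      size_factor_cv       = 0.15,
      tkd_true_ratio       = 1.4     # exon16:exon8 ratio simulated for TKD-duplicated samples
    ),
    survival_sim = list(
      # group-specific medians (years) motivated by the published cohort summaries
      median_pfs = c(GROUP1 = 1.1, GROUP2 = 1.2, GROUP3 = 1.1, UNCLASSIFIED = 1.1),
      median_os  = c(GROUP1 = 1.9, GROUP2 = 3.6, GROUP3 = 6.5, UNCLASSIFIED = 3.0),
      censoring_rate = 0.4
    ),
    rounding = list(digits = 1L)
  )
}

#' Merge user overrides into the default configuration
#'
#' @param ... named overrides, nested lists merged recursively, e.g.
#'   \code{pipeline_config(ddpcr = list(maf_threshold_pct = 2))}.
#' @return full configuration list.
#' @export
pipeline_config <- function(...) {
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else
        base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_lists(default_config(), list(...))
  validate_config(cfg)
  cfg
}

#' Validate a configuration list
#' @param cfg configuration list.
#' @return \code{cfg}, invisibly; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  d <- cfg$ddpcr
  if (d$maf_threshold_pct <= 0 || d$droplet_floor <= 0 ||
      d$cdkn2a_deleted_below <= 0 || d$fgfr1_tkd_ratio <= 0 ||
      d$droplet_volume_nl <= 0)
    stop("configuration error: every assay threshold must be positive", call. = FALSE)
  n <- cfg$nanostring
  if (n$iqr_multiplier <= 0 || n$imbalance_z <= 0 || n$min_lanes < 2)
    stop("configuration error: invalid count-panel thresholds", call. = FALSE)
  s <- cfg$simulation
  if (any(s$n_droplets_range <= 0) || diff(s$n_droplets_range) < 0)
    stop("configuration error: invalid droplet range", call. = FALSE)
  if (s$wildtype_lambda < 0)
    stop("configuration error: wild-type concentration must be >= 0", call. = FALSE)
  if (any(cfg$survival_sim$median_pfs <= 0) || any(cfg$survival_sim$median_os <= 0))
    stop("configuration error: survival medians must be positive", call. = FALSE)
  if (cfg$survival_sim$censoring_rate < 0 || cfg$survival_sim$censoring_rate > 1)
    stop("configuration error: censoring rate must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Read / write a configuration as JSON
#'
#' @param path file path.
#' @return \code{read_config} returns the validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()  |> utils::modifyList(cfg)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
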