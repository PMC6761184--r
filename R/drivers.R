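# Tiered driver integration: fusion annotation, multi-caller consensus and
# one integrated DriverCall per sample.

#' Built-in kinase-domain exon spans
#'
#' Approximate, literature-conventional tyrosine-kinase-domain exon spans
#' (1-based inclusive) for the receptor and RAF kinases recurrently fused
#' in infant gliomas. Shipped as an editable TSV
#' (\code{inst/extdata/kinase_domains.tsv}); only the ordering of a
#' breakpoint relative to the domain start is consumed.
#'
#' @param path optional path to an alternative TSV (columns \code{gene},
#'   \code{kd_start_exon}, \code{kd_end_exon}).
#' @return data frame of gene models.
#' @export
kinase_domain_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinase_domains.tsv", package = "infantglioma")
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(m$kd_start_exon > m$kd_end_exon))
    stop("gene-model error: kinase-domain span start > end", call. = FALSE)
  m
}

#' Map a gene pair to an enumerated driver
#'
#' The altered gene determines the driver: a 3' RTK (ALK, ROS1, NTRK1/2/3,
#' MET) gives the corresponding RTK fusion; a 3' BRAF gives the
#' KIAA1549-BRAF class; 3' RAF1 the PML-RAF1 class; FGFR1 on either side
#' the FGFR1 fusion class. Unrecognised pairs map to OTHER.
#'
#' @param gene_5p,gene_3p gene symbols.
#' @return driver identifier (see \code{\link{driver_levels}}).
#' @export
fusion_driver <- function(gene_5p, gene_3p) {
  rtk <- c(ALK = "ALK_FUSION", ROS1 = "ROS1_FUSION", NTRK1 = "NTRK_FUSION",
           NTRK2 = "NTRK_FUSION", NTRK3 = "NTRK_FUSION", MET = "MET_FUSION")
  if (gene_3p %in% names(rtk)) return(unname(rtk[gene_3p]))
  if (gene_3p == "BRAF") return("KIAA1549_BRAF")
  if (gene_3p == "RAF1") return("PML_RAF1")
  if (gene_3p == "FGFR1" || gene_5p == "FGFR1") return("FGFR1_TACC1")
  "OTHER"
}

#' Pathway class of a driver
#'
#' Fixed mapping: ALK/ROS1/NTRK/MET fusions are RTK; KIAA1549-BRAF,
#' BRAF V600E, FGFR1 fusion or kinase-domain duplication, PML-RAF1 and
#' MYBL1 gain are RAS/MAPK; NONE maps to NONE; anything else to OTHER.
#'
#' @param driver driver identifier(s).
#' @return character vector of \{"RTK", "RAS_MAPK", "OTHER", "NONE"\}.
#' @export
pathway_class <- function(driver) {
  map <- c(KIAA1549_BRAF = "RAS_MAPK", BRAF_V600E = "RAS_MAPK",
           FGFR1_TACC1 = "RAS_MAPK", FGFR1_TKD = "RAS_MAPK",
           PML_RAF1 = "RAS_MAPK", MYBL1_GAIN = "RAS_MAPK",
           ALK_FUSION = "RTK", ROS1_FUSION = "RTK", NTRK_FUSION = "RTK",
           MET_FUSION = "RTK", OTHER = "OTHER", NONE = "NONE")
  bad <- setdiff(driver, names(map))
  if (length(bad))
    stop("mapping error: unknown driver ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(map[driver])
}

#' Annotate a fusion record with kinase-domain retention and pathway
#'
#' These gliomas activate kinases by fusing a 5' partner to the 3' portion
#' of the kinase; the event is activating when the 3' breakpoint lies
#' upstream of the kinase domain so the domain is retained
#' (\code{exon_3p <= kd_start_exon}).
#'
#' @param fusion one-row data frame or list with \code{gene_5p},
#'   \code{gene_3p}, \code{exon_5p}, \code{exon_3p}.
#' @param models gene models from \code{\link{kinase_domain_models}}.
#' @return the record with \code{tkd_retained} (logical or NA when the 3'
#'   gene is not modelled), \code{driver} and \code{pathway} added.
#' @export
annotate_fusion <- function(fusion, models = kinase_domain_models()) {
  f <- as.list(fusion)
  i <- match(f$gene_3p, models$gene)
  f$tkd_retained <- if (is.na(i)) NA else f$exon_3p <= models$kd_start_exon[i]
  f$driver <- fusion_driver(f$gene_5p, f$gene_3p)
  f$pathway <- pathway_class(f$driver)
  f
}

#' Merge multi-caller fusion candidates into consensus records
#'
#' Candidates from the transcriptome fusion callers sharing the same gene
#' pair with breakpoints within the exon tolerance are merged (supporting
#' callers unioned, representative breakpoint = rounded median); merged
#' records supported by fewer than \code{min_support} distinct callers are
#' dropped. Clustering is single-linkage on sorted breakpoints, so the
#' result is independent of input order.
#'
#' @param fusions data frame with columns \code{gene_5p}, \code{exon_5p},
#'   \code{gene_3p}, \code{exon_3p}, \code{caller} (one row per candidate).
#'   Zero rows allowed.
#' @param min_support minimum distinct supporting callers (default 2).
#' @param tolerance maximum exon difference treated as the same breakpoint
#'   (default 1).
#' @return data frame of consensus records with a \code{supporting_callers}
#'   comma-separated column and \code{n_callers}.
#' @export
consensus_fusions <- function(fusions, min_support = 2L, tolerance = 1L) {
  empty <- data.frame(gene_5p = character(), exon_5p = integer(),
                      gene_3p = character(), exon_3p = integer(),
                      supporting_callers = character(), n_callers = integer())
  if (is.null(fusions) || nrow(fusions) == 0) return(empty)
  out <- list()
  for (key in unique(paste(fusions$gene_5p, fusions$gene_3p, sep = "|"))) {
    g <- fusions[paste(fusions$gene_5p, fusions$gene_3p, sep = "|") == key, ,
                 drop = FALSE]
    g <- g[order(g$exon_5p, g$exon_3p, g$caller), , drop = FALSE]
    cluster <- cumsum(c(1L, (diff(g$exon_5p) > tolerance) |
                             (diff(g$exon_3p) > tolerance)))
    for (cl in unique(cluster)) {
      gc <- g[cluster == cl, , drop = FALSE]
      callers <- sort(unique(gc$caller))
      out[[length(out) + 1L]] <- data.frame(
        gene_5p = gc$gene_5p[1],
        exon_5p = as.integer(round(stats::median(gc$exon_5p))),
        gene_3p = gc$gene_3p[1],
        exon_3p = as.integer(round(stats::median(gc$exon_3p))),
        supporting_callers = paste(callers, collapse = ","),
        n_callers = length(callers))
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$n_callers >= min_support, , drop = FALSE]
  res <- res[order(res$gene_5p, res$gene_3p, res$exon_5p, res$exon_3p), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Integrate tiered assay evidence into one driver call per sample
#'
#' Tier 1 (ddPCR hotspots and copy assays, count-panel fusion and imbalance
#' calls) short-circuits tier 2: a sample positive in any tier-1 assay gets
#' its driver from tier 1 and tier-2 evidence is never consulted. Otherwise
#' tier-2 evidence (targeted RNA-seq fusions, transcriptome consensus,
#' pre-called copy-number events) is used. Multiple positives within a tier
#' are resolved by the configured precedence over assay classes (default
#' SNV hotspot > panel fusion > CNV) and the conflict is recorded.
#'
#' @param sample_id sample identifier.
#' @param tier1,tier2 data frames of evidence rows with columns
#'   \code{assay_class} (one of "snv_hotspot", "panel_fusion", "cnv"),
#'   \code{driver}, \code{positive} (logical) and optionally \code{detail}.
#'   \code{tier2} may be \code{NULL} or empty.
#' @param config pipeline configuration.
#' @return one-row data frame: \code{sample_id}, \code{driver},
#'   \code{pathway}, \code{evidence_tier} (1, 2 or NA for NONE),
#'   \code{evidence}, \code{conflict} (logical).
#' @export
integrate_sample <- function(sample_id, tier1, tier2 = NULL,
                             config = default_config()) {
  prec <- config$integration$tier1_precedence
  pick <- function(ev) {
    ev <- ev[ev$positive, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    # one driver may be supported by several assays; a conflict is >1 driver
    drivers <- unique(ev$driver)
    ord <- order(match(ev$assay_class, prec))
    list(driver = ev$driver[ord[1]],
         evidence = paste(sprintf("%s:%s", ev$assay_class, ev$driver),
                          collapse = ";"),
         conflict = length(drivers) > 1)
  }
  check_dupes <- function(ev, tier) {
    if (is.null(ev) || nrow(ev) == 0) return(invisible())
    # duplicates of the SAME assay (class + driver + detail when present)
    detail <- if (is.null(ev$detail)) ev$driver else ev$detail
    contradictory <- tapply(ev$positive, paste(ev$assay_class, ev$driver, detail),
                            function(p) length(unique(p)) > 1)
    if (any(contradictory))
      stop(sprintf("input-integrity error: contradictory duplicate %s records for %s",
                   tier, sample_id), call. = FALSE)
  }
  check_dupes(tier1, "tier-1"); check_dupes(tier2, "tier-2")
  hit <- pick(tier1)
  tier <- 1L
  if (is.null(hit) && !is.null(tier2) && nrow(tier2)) {
    hit <- pick(tier2)
    tier <- 2L
  }
  if (is.null(hit))
    return(data.frame(sample_id = sample_id, driver = "NONE",
                      pathway = "NONE", evidence_tier = NA_integer_,
                      evidence = "", conflict = FALSE))
  data.frame(sample_id = sample_id, driver = hit$driver,
             pathway = pathway_class(hit$driver), evidence_tier = tier,
             evidence = hit$evidence, conflict = hit$conflict)
}
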