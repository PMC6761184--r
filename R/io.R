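# Plain-text formats: TSV sample sheets and count matrices, CSV droplet
# exports (mirroring instrument convention), and the end-to-end orchestrator.

# documented vocabulary mapping for free-text tumor locations
.location_map <- c(
  hemispheric = "hemispheric", hemisphere = "hemispheric",
  cortical = "hemispheric", temporal = "hemispheric", frontal = "hemispheric",
  parietal = "hemispheric", occipital = "hemispheric",
  midline = "midline", thalamic = "midline", hypothalamic = "midline",
  "optic pathway" = "midline", suprasellar = "midline", brainstem = "midline",
  other = "other", cerebellar = "other", "posterior fossa" = "other",
  spinal = "other")

#' Read a clinical sample sheet
#'
#' Tab-separated with header; required columns \code{sample_id},
#' \code{location}, \code{grade}. Free-text locations are mapped to the
#' \{hemispheric, midline, other\} vocabulary via a documented synonym
#' table; unknown values are rejected with row-numbered messages.
#'
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "location", "grade"))
    if (is.null(x[[col]]))
      stop(sprintf("format error: missing required column '%s'", col),
           call. = FALSE)
  loc <- .location_map[tolower(x$location)]
  bad <- which(is.na(loc))
  if (length(bad))
    stop("format error: unknown location at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x$location[bad]), collapse = ", "), call. = FALSE)
  x$location <- unname(loc)
  badg <- which(!x$grade %in% c("LGG", "HGG", "mixed"))
  if (length(badg))
    stop("format error: unknown grade at row(s) ",
         paste(badg, collapse = ", "), call. = FALSE)
  x
}

#' Write a sample sheet
#' @param x cohort data frame.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write droplet-count tables
#'
#' CSV with columns \code{sample_id}, \code{target}, \code{replicate},
#' \code{n_droplets}, \code{positive_mut}, \code{positive_wt}.
#'
#' @param path CSV path.
#' @return data frame of droplet counts.
#' @export
read_droplets <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "replicate", "n_droplets",
            "positive_mut", "positive_wt")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("format error: missing required column '", miss[1], "'", call. = FALSE)
  if (any(x$positive_mut > x$n_droplets | x$positive_wt > x$n_droplets))
    stop("format error: positive droplets exceed total", call. = FALSE)
  x
}

#' @rdname read_droplets
#' @param x droplet table.
#' @export
write_droplets <- function(x, path) {
  utils::write.csv(x, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a count matrix with probe annotation
#'
#' TSV with probes in rows: annotation columns \code{probe_id},
#' \code{probe_class}, \code{gene_5p}, \code{gene_3p}, \code{gene},
#' \code{tag_index}, \code{tag_side}, followed by one column per sample
#' lane.
#'
#' @param path TSV path.
#' @return a \code{\link{count_panel}}.
#' @export
read_counts_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ann_cols <- c("probe_id", "probe_class", "gene_5p", "gene_3p", "gene",
                "tag_index", "tag_side")
  miss <- setdiff(c("probe_id", "probe_class"), names(x))
  if (length(miss))
    stop("format error: missing required column '", miss[1], "'", call. = FALSE)
  if (anyDuplicated(x$probe_id))
    stop("format error: duplicate probe_id", call. = FALSE)
  lanes <- setdiff(names(x), ann_cols)
  m <- as.matrix(x[, lanes, drop = FALSE])
  if (!is.numeric(m) || any(m != floor(m)))
    stop("format error: non-integer count", call. = FALSE)
  rownames(m) <- x$probe_id
  count_panel(m, x[, intersect(ann_cols, names(x)), drop = FALSE])
}

#' @rdname read_counts_matrix
#' @param panel a \code{count_panel}.
#' @export
write_counts_matrix <- function(panel, path) {
  out <- cbind(panel$probes, as.data.frame(panel$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the tiered pipeline end to end
#'
#' ddPCR calling, count-panel calling, tiered driver integration, subgroup
#' classification and cohort summaries, plus survival statistics when
#' endpoint columns are present. Samples positive in tier 1 never consult
#' tier-2 evidence. Every assay row must belong to a sample on the sample
#' sheet.
#'
#' @param samples cohort/sample sheet data frame (needs \code{sample_id},
#'   \code{location}, \code{grade}).
#' @param droplets droplet table (may be \code{NULL}).
#' @param panel raw \code{\link{count_panel}} (may be \code{NULL}).
#' @param fusions tier-2 fusion-caller candidates (may be \code{NULL}).
#' @param cnv tier-2 pre-called copy-number events (may be \code{NULL}).
#' @param config pipeline configuration.
#' @return list: \code{drivers} (one DriverCall row per sample),
#'   \code{cohort} (samples + driver/pathway/group), \code{summary},
#'   \code{headline}, \code{ddpcr_calls}, \code{panel_calls},
#'   \code{survival} (KM per group + log-rank, when endpoints present),
#'   \code{log} (character vector of decisions).
#' @export
run_pipeline <- function(samples, droplets = NULL, panel = NULL,
                         fusions = NULL, cnv = NULL,
                         config = default_config()) {
  log <- character()
  ids <- samples$sample_id
  orphan <- unique(c(
    if (!is.null(droplets)) setdiff(droplets$sample_id, ids),
    if (!is.null(panel)) setdiff(colnames(panel$counts), ids),
    if (!is.null(fusions) && nrow(fusions)) setdiff(fusions$sample_id, ids),
    if (!is.null(cnv) && nrow(cnv)) setdiff(cnv$sample_id, ids)))
  if (length(orphan))
    stop("reconciliation error: assay sample_ids missing from sample sheet: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  dd <- if (!is.null(droplets)) call_ddpcr_table(droplets, config) else NULL
  pc <- if (!is.null(panel)) call_count_panel(panel, config) else NULL
  models <- kinase_domain_models()

  tier1_for <- function(sid) {
    rows <- list()
    if (!is.null(dd)) {
      d <- dd[dd$sample_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        tg <- d$target[i]
        if (tg %in% c("BRAF_V600E", "H3F3A_K28M", "H3F3A_G35R"))
          rows[[length(rows) + 1L]] <- data.frame(
            assay_class = "snv_hotspot", driver = tg,
            positive = d$call[i] == "positive", detail = paste0("ddpcr_", tg))
        else if (tg == "FGFR1_TKD")
          rows[[length(rows) + 1L]] <- data.frame(
            assay_class = "cnv", driver = "FGFR1_TKD",
            positive = d$call[i] == "duplicated", detail = "ddpcr_FGFR1_TKD")
      }
    }
    if (!is.null(pc)) {
      o <- pc$outliers[pc$outliers$sample_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(o)))
        rows[[length(rows) + 1L]] <- data.frame(
          assay_class = "panel_fusion",
          driver = fusion_driver(o$gene_5p[i], o$gene_3p[i]),
          positive = o$outlier[i], detail = o$probe_id[i])
      im <- pc$imbalance[pc$imbalance$sample_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(im)))
        rows[[length(rows) + 1L]] <- data.frame(
          assay_class = "panel_fusion",
          driver = fusion_driver("UNKNOWN", im$gene[i]),
          positive = im$call[i], detail = paste0("tags_", im$gene[i]))
    }
    if (length(rows)) unique(do.call(rbind, rows)) else
      data.frame(assay_class = character(), driver = character(),
                 positive = logical(), detail = character())
  }

  cons_by_sample <- if (!is.null(fusions) && nrow(fusions)) {
    split_f <- split(fusions, fusions$sample_id)
    lapply(split_f, consensus_fusions,
           min_support = config$integration$min_support,
           tolerance = config$integration$breakpoint_tolerance)
  } else list()

  tier2_for <- function(sid) {
    rows <- list()
    cf <- cons_by_sample[[sid]]
    if (!is.null(cf) && nrow(cf)) for (i in seq_len(nrow(cf))) {
      ann <- annotate_fusion(cf[i, ], models)
      rows[[length(rows) + 1L]] <- data.frame(
        assay_class = "panel_fusion", driver = ann$driver, positive = TRUE,
        detail = sprintf("wts_%s_%s", ann$gene_5p, ann$gene_3p))
    }
    if (!is.null(cnv) && nrow(cnv)) {
      cv <- cnv[cnv$sample_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(cv)))
        if (cv$gene[i] == "MYBL1" && cv$event[i] == "gain")
          rows[[length(rows) + 1L]] <- data.frame(
            assay_class = "cnv", driver = "MYBL1_GAIN", positive = TRUE,
            detail = "cnv_MYBL1")
    }
    if (length(rows)) unique(do.call(rbind, rows)) else NULL
  }

  drivers <- do.call(rbind, lapply(ids, function(sid) {
    t1 <- tier1_for(sid)
    t2 <- if (any(t1$positive)) NULL else tier2_for(sid)  # tier-1 short-circuit
    integrate_sample(sid, t1, t2, config)
  }))
  log <- c(log, sprintf("%d/%d samples driver-positive",
                        sum(drivers$driver != "NONE"), length(ids)))

  cohort <- merge(samples, drivers[, c("sample_id", "driver", "pathway",
                                       "evidence_tier")],
                  by = "sample_id", sort = TRUE)
  grp <- assign_subgroup(cohort$pathway, cohort$location)
  cohort$group <- grp$group

  surv <- NULL
  if (!is.null(cohort$os_time)) {
    km <- lapply(split(cohort, cohort$group), function(g)
      if (nrow(g)) km_estimate(g$os_time, g$os_event) else NULL)
    grps <- cohort$group[cohort$group != "UNCLASSIFIED"]
    lr <- if (length(unique(grps)) >= 2) {
      sub <- cohort[cohort$group != "UNCLASSIFIED", ]
      logrank_test(sub$os_time, sub$os_event, sub$group)
    } else NULL
    surv <- list(km_by_group = km, logrank_os = lr)
  }

  list(drivers = drivers, cohort = cohort,
       summary = cohort_summary(cohort, config),
       headline = headline_fractions(cohort, config),
       ddpcr_calls = dd, panel_calls = pc, survival = surv, log = log)
}

#' Simulate the full raw-assay bundle for a cohort
#'
#' Convenience wrapper producing everything \code{\link{run_pipeline}}
#' consumes from a latent-truth cohort: droplet tables, the count panel
#' and tier-2 evidence. With \code{noiseless = TRUE} every assay takes its
#' expected value, which is how the deterministic reference cohort is
#' pushed through the pipeline.
#'
#' @param cohort latent-truth cohort.
#' @param config pipeline configuration.
#' @param seed integer seed (ignored when noiseless).
#' @param noiseless logical.
#' @return list: \code{droplets}, \code{panel}, \code{fusions}, \code{cnv}.
#' @export
simulate_assays <- function(cohort, config = default_config(), seed = 1L,
                            noiseless = FALSE) {
  if (!noiseless) set.seed(seed)
  droplets <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    simulate_ddpcr_assay(cohort[i, ], config, noiseless = noiseless)))
  panel <- simulate_count_matrix(cohort, config, noiseless = noiseless)
  t2 <- simulate_tier2_evidence(cohort, config, noiseless = noiseless)
  list(droplets = droplets, panel = panel, fusions = t2$fusions, cnv = t2$cnv)
}
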