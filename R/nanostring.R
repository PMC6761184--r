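#' Construct a count panel
#'
#' Container for one batch of count lanes: a probe-by-sample count matrix
#' plus per-probe annotation. Probe classes are \code{fusion} (junction
#' probes), \code{housekeeping}, \code{negative_control} and
#' \code{reporter_tag} (partner-agnostic tags flanking a breakpoint
#' hotspot; \code{tag_index} is 1-based along the transcript and
#' \code{tag_side} is "upstream" or "downstream" of the hotspot).
#'
#' @param counts numeric matrix, probes in rows (rownames = probe ids),
#'   lanes/samples in columns.
#' @param probes data frame with columns \code{probe_id}, \code{probe_class}
#'   and, for fusion probes, \code{gene_5p}/\code{gene_3p}; for reporter
#'   tags, \code{gene}, \code{tag_index}, \code{tag_side}.
#' @return object of class \code{count_panel}.
#' @export
count_panel <- function(counts, probes) {
  counts <- as.matrix(counts)
  if (anyDuplicated(probes$probe_id))
    stop("format error: duplicate probe_id in panel definition", call. = FALSE)
  if (!setequal(rownames(counts), probes$probe_id))
    stop("format error: count rows and probe annotation disagree", call. = FALSE)
  if (any(counts < 0)) stop("format error: negative count", call. = FALSE)
  bad <- setdiff(unique(probes$probe_class),
                 c("fusion", "housekeeping", "negative_control", "reporter_tag"))
  if (length(bad))
    stop("configuration error: unknown probe class ", paste(bad, collapse = ", "),
         call. = FALSE)
  probes <- probes[match(rownames(counts), probes$probe_id), , drop = FALSE]
  hk <- sum(probes$probe_class == "housekeeping")
  if (hk < 4) stop("configuration error: panel needs >= 4 housekeeping probes",
                   call. = FALSE)
  structure(list(counts = counts, probes = probes), class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf("count_panel: %d probes x %d lanes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$probes$probe_class)),
                            as.integer(table(x$probes$probe_class))),
                    collapse = ", ")))
  invisible(x)
}

probe_ids <- function(panel, class) {
  panel$probes$probe_id[panel$probes$probe_class == class]
}

#' Background-correct count lanes from negative-control spikes
#'
#' Counting of barcodes is Poisson, so the background threshold for each
#' lane is taken as \eqn{B = \bar m + 2\sqrt{\bar m}} where \eqn{\bar m} is
#' that lane's mean negative-control count (mean plus two Poisson standard
#' deviations). Non-control probes are floored at zero after subtracting
#' \eqn{B}; controls pass through unchanged. Setting the configuration's
#' \code{background_method} to \code{"mean"} subtracts the plain mean.
#'
#' @param panel a \code{\link{count_panel}}.
#' @param config pipeline configuration.
#' @return corrected \code{count_panel}; per-lane thresholds in
#'   \code{attr(,"background")}.
#' @export
background_correct <- function(panel, config = default_config()) {
  neg <- probe_ids(panel, "negative_control")
  if (!length(neg))
    stop("panel-definition error: no negative-control probes", call. = FALSE)
  m <- colMeans(panel$counts[neg, , drop = FALSE])
  B <- if (identical(config$nanostring$background_method, "mean")) m
       else m + 2 * sqrt(m)
  corrected <- panel$counts
  keep <- !(rownames(corrected) %in% neg)
  corrected[keep, ] <- pmax(0, sweep(corrected[keep, , drop = FALSE], 2, B))
  out <- panel
  out$counts <- corrected
  attr(out, "background") <- B
  out
}

#' Normalize lanes on the four housekeeping transcripts
#'
#' Each lane is summarised by the geometric mean of its housekeeping counts
#' (ABCF1, ALAS1, CLTC, HPRT1 in the default panel); the batch reference is
#' the arithmetic mean of those per-lane geometric means, and every
#' non-control probe is scaled by reference / lane-geomean. Lanes with any
#' zero housekeeper fail QC and are dropped with a recorded reason.
#'
#' @param panel background-corrected \code{\link{count_panel}}.
#' @param cohort_reference optional fixed reference value (defaults to the
#'   batch mean, which makes normalization idempotent).
#' @param config pipeline configuration.
#' @return normalized \code{count_panel}; scale factors in
#'   \code{attr(,"size_factors")}, QC failures in \code{attr(,"qc_failed")}.
#' @export
normalize_housekeeping <- function(panel, cohort_reference = NULL,
                                   config = default_config()) {
  hk <- probe_ids(panel, "housekeeping")
  hkm <- panel$counts[hk, , drop = FALSE]
  fail <- colnames(panel$counts)[apply(hkm, 2, function(x) any(x <= 0))]
  if (length(fail)) {
    warning("lane QC-fail (zero housekeeper), excluded: ",
            paste(fail, collapse = ", "), call. = FALSE)
    panel$counts <- panel$counts[, setdiff(colnames(panel$counts), fail), drop = FALSE]
    hkm <- panel$counts[hk, , drop = FALSE]
  }
  gm <- apply(hkm, 2, geom_mean)
  ref <- if (is.null(cohort_reference)) mean(gm) else cohort_reference
  f <- ref / gm
  keep <- panel$probes$probe_class != "negative_control"
  panel$counts[keep, ] <- sweep(panel$counts[keep, , drop = FALSE], 2, f, `*`)
  attr(panel, "size_factors") <- f
  attr(panel, "qc_failed") <- fail
  panel
}

#' Call expressed fusions by the extreme-outlier (3x IQR) rule
#'
#' For each fusion junction probe, the first and third quartiles of the
#' normalized values across the lanes of the batch are computed with the
#' linear-interpolation quantile convention (R type 7); a lane is flagged
#' when its value strictly exceeds Q3 + \code{iqr_multiplier} * IQR. The
#' cross-sample distribution is used because a junction probe is silent in
#' fusion-negative samples, so expressing lanes stand out as extreme
#' outliers of an essentially null distribution.
#'
#' @param panel normalized \code{\link{count_panel}} with at least the
#'   configured minimum number of lanes (default 8).
#' @param config pipeline configuration.
#' @return data frame: \code{sample_id}, \code{probe_id}, \code{gene_5p},
#'   \code{gene_3p}, \code{value}, \code{q1}, \code{q3}, \code{iqr},
#'   \code{outlier}.
#' @export
call_fusion_outliers <- function(panel, config = default_config()) {
  ns <- config$nanostring
  if (ncol(panel$counts) < ns$min_lanes)
    stop(sprintf("batch-size error: %d lanes < required minimum %d",
                 ncol(panel$counts), ns$min_lanes), call. = FALSE)
  fus <- panel$probes[panel$probes$probe_class == "fusion", , drop = FALSE]
  out <- lapply(seq_len(nrow(fus)), function(i) {
    pid <- fus$probe_id[i]
    v <- panel$counts[pid, ]
    q <- stats::quantile(v, c(0.25, 0.75), type = ns$quantile_type, names = FALSE)
    iqr <- q[2] - q[1]
    data.frame(sample_id = colnames(panel$counts), probe_id = pid,
               gene_5p = fus$gene_5p[i], gene_3p = fus$gene_3p[i],
               value = as.numeric(v), q1 = q[1], q3 = q[2], iqr = iqr,
               outlier = as.numeric(v) > q[2] + ns$iqr_multiplier * iqr,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Score 3'/5' reporter-tag imbalance
#'
#' Partner-agnostic fusion evidence: for each monitored gene the statistic
#' is \eqn{r = \log_2(\bar d + 1) - \log_2(\bar u + 1)} (mean downstream vs
#' upstream tag counts, pseudocount 1), compared across the batch with a
#' robust z-score \eqn{(r - median) / (1.4826 \cdot MAD)}. A lane is called
#' when z reaches the configured cutoff (default 5) and its mean downstream
#' signal exceeds the configured floor. The ratio statistic is invariant to
#' whole-lane scaling, so overall overexpression does not trigger a call.
#' When the batch MAD is zero the spread falls back to IQR/1.349 (flagged
#' in the output).
#'
#' @param panel normalized \code{\link{count_panel}}.
#' @param gene gene symbol monitored by a reporter-tag system (needs >= 2
#'   tags on each side of the hotspot).
#' @param config pipeline configuration.
#' @return data frame: \code{sample_id}, \code{gene}, \code{log2_ratio},
#'   \code{z}, \code{mean_downstream}, \code{call}, \code{spread_fallback}.
#' @export
reporter_imbalance <- function(panel, gene, config = default_config()) {
  ns <- config$nanostring
  tags <- panel$probes[panel$probes$probe_class == "reporter_tag" &
                         panel$probes$gene == gene, , drop = FALSE]
  up <- tags$probe_id[tags$tag_side == "upstream"]
  dn <- tags$probe_id[tags$tag_side == "downstream"]
  if (length(up) < 2 || length(dn) < 2)
    stop(sprintf("panel-definition error: gene %s needs >= 2 tags per side", gene),
         call. = FALSE)
  mu <- colMeans(panel$counts[up, , drop = FALSE])
  md <- colMeans(panel$counts[dn, , drop = FALSE])
  pc <- ns$imbalance_pseudocount
  r <- log2(md + pc) - log2(mu + pc)
  med <- stats::median(r)
  spread <- 1.4826 * stats::mad(r, constant = 1)
  fallback <- FALSE
  if (spread == 0) {
    spread <- diff(stats::quantile(r, c(0.25, 0.75), names = FALSE)) / 1.349
    fallback <- TRUE
  }
  dev <- r - med
  z <- ifelse(dev == 0, 0, dev / spread)   # 0/0 -> no evidence, not NaN
  data.frame(sample_id = colnames(panel$counts), gene = gene,
             log2_ratio = as.numeric(r), z = as.numeric(z),
             mean_downstream = as.numeric(md),
             call = z >= ns$imbalance_z & md > ns$imbalance_min_downstream,
             spread_fallback = fallback, row.names = NULL)
}

#' Run the full count-panel calling chain on a raw panel
#'
#' Background correction, housekeeping normalization, 3x IQR outlier
#' calling on every fusion probe and imbalance scoring on every
#' reporter-tag gene.
#'
#' @param panel raw \code{\link{count_panel}}.
#' @param config pipeline configuration.
#' @return list with \code{normalized} panel, \code{outliers} and
#'   \code{imbalance} call tables.
#' @export
call_count_panel <- function(panel, config = default_config()) {
  norm <- normalize_housekeeping(background_correct(panel, config), config = config)
  genes <- unique(panel$probes$gene[panel$probes$probe_class == "reporter_tag"])
  imb <- do.call(rbind, lapply(genes, function(g)
    reporter_imbalance(norm, g, config)))
  list(normalized = norm,
       outliers = call_fusion_outliers(norm, config),
       imbalance = imb)
}
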