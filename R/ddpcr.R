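#' Poisson quantification of a droplet digital PCR channel
#'
#' In digital PCR the sample is partitioned into droplets and target
#' molecules distribute approximately Poisson. With \code{k} of \code{n}
#' droplets positive, the mean copies per droplet is
#' \deqn{\hat\lambda = -\ln(1 - k/n)}
#' and the concentration follows by dividing by the droplet volume.
#'
#' @param positive number of positive droplets in the channel.
#' @param total total droplets read (> 0).
#' @param droplet_volume_nl droplet volume in nanolitres (default 0.85,
#'   vendor-standard for the QX200-class instrument).
#' @return object of class \code{quant_result}: list with \code{lambda_hat}
#'   (copies/droplet), \code{concentration} (copies/microlitre) and
#'   \code{n_positive}.
#' @examples
#' quantify_target(5000, 10000)          # lambda = log(2)
#' @export
quantify_target <- function(positive, total, droplet_volume_nl = 0.85) {
  stopifnot_scalar(positive); stopifnot_scalar(total)
  if (total <= 0) stop("input error: total droplets must be > 0", call. = FALSE)
  if (droplet_volume_nl <= 0) stop("input error: droplet volume must be > 0", call. = FALSE)
  if (positive < 0 || positive > total)
    stop("input error: positive droplets must lie in [0, total]", call. = FALSE)
  if (positive == total)
    stop("saturation error: all droplets positive, lambda undefined", call. = FALSE)
  lambda <- -log1p(-positive / total)
  structure(
    list(lambda_hat    = lambda,
         concentration = lambda / (droplet_volume_nl * 1e-3),  # nL -> uL
         n_positive    = positive),
    class = "quant_result")
}

#' Mutant allele fraction from channel concentrations
#'
#' Reported as a percent of the total gene copy:
#' \eqn{100 \lambda_{mut} / (\lambda_{mut} + \lambda_{wt})}.
#'
#' @param lambda_mut mutant-channel copies/droplet (>= 0).
#' @param lambda_wt wild-type-channel copies/droplet (>= 0).
#' @return MAF in percent, in [0, 100].
#' @export
mutant_allele_fraction <- function(lambda_mut, lambda_wt) {
  if (any(lambda_mut < 0) || any(lambda_wt < 0))
    stop("input error: lambdas must be non-negative", call. = FALSE)
  tot <- lambda_mut + lambda_wt
  if (any(tot == 0))
    stop("undefined-fraction error: both channels zero", call. = FALSE)
  100 * lambda_mut / tot
}

#' Pure hotspot positivity rule
#'
#' A sample is positive when the mutant allele frequency reaches the
#' threshold in \emph{both} duplicate runs and each replicate carries at
#' least the configured floor of fluorescent (positive) droplets.
#'
#' @param maf_pct per-replicate MAFs (percent).
#' @param fluorescent_droplets per-replicate totals of positive droplets
#'   summed over both channels.
#' @param maf_threshold_pct minimum MAF, percent (default 1).
#' @param droplet_floor minimum fluorescent droplets per replicate (default 50).
#' @return logical: positive call.
#' @export
hotspot_rule <- function(maf_pct, fluorescent_droplets,
                         maf_threshold_pct = 1, droplet_floor = 50) {
  all(maf_pct >= maf_threshold_pct) && all(fluorescent_droplets >= droplet_floor)
}

#' Call a hotspot mutation from a duplicate ddPCR run
#'
#' @param assay data frame with one row per replicate and columns
#'   \code{n_droplets}, \code{positive_mut}, \code{positive_wt}. Exactly two
#'   replicates are required (the duplicate design is enforced).
#' @param config pipeline configuration (see \code{\link{default_config}}).
#' @return list with \code{call} ("positive"/"negative"), per-replicate
#'   \code{maf} (percent) and \code{fluorescent} droplet totals.
#' @export
call_hotspot <- function(assay, config = default_config()) {
  cc <- config$ddpcr
  if (nrow(assay) != cc$n_replicates)
    stop(sprintf("design error: expected %d replicates, got %d",
                 cc$n_replicates, nrow(assay)), call. = FALSE)
  maf <- fluo <- numeric(nrow(assay))
  for (i in seq_len(nrow(assay))) {
    r <- assay[i, ]
    if (cc$maf_from_corrected) {
      qm <- quantify_target(r$positive_mut, r$n_droplets, cc$droplet_volume_nl)
      qw <- quantify_target(r$positive_wt,  r$n_droplets, cc$droplet_volume_nl)
      maf[i] <- if (qm$lambda_hat + qw$lambda_hat == 0) 0 else
        mutant_allele_fraction(qm$lambda_hat, qw$lambda_hat)
    } else {
      tot <- r$positive_mut + r$positive_wt
      maf[i] <- if (tot == 0) 0 else 100 * r$positive_mut / tot
    }
    fluo[i] <- r$positive_mut + r$positive_wt
  }
  pos <- hotspot_rule(maf, fluo, cc$maf_threshold_pct, cc$droplet_floor)
  list(call = if (pos) "positive" else "negative", maf = maf, fluorescent = fluo)
}

#' Copy-number value against a two-copy calibrator
#'
#' \eqn{CN = 2 (\lambda_{target}/\lambda_{ref}) / r_{cal}} where
#' \eqn{r_{cal}} is the target/reference concentration ratio measured on a
#' known two-copy control sample.
#'
#' @param lambda_target,lambda_ref copies/droplet for the target and
#'   reference assays (replicate-averaged).
#' @param calibrator_ratio target/reference ratio of the two-copy control
#'   (default 1, i.e. assays of equal efficiency).
#' @return copy-number value.
#' @export
copy_number_value <- function(lambda_target, lambda_ref, calibrator_ratio = 1) {
  if (lambda_ref <= 0) stop("division error: reference lambda must be > 0", call. = FALSE)
  if (calibrator_ratio <= 0) stop("input error: calibrator ratio must be > 0", call. = FALSE)
  2 * (lambda_target / lambda_ref) / calibrator_ratio
}

#' Call CDKN2A deletion from a copy-number value
#'
#' Deleted strictly below the configured boundary (default 1.2); the
#' boundary value itself is neutral.
#'
#' @param cn copy-number value (>= 0).
#' @param config pipeline configuration.
#' @return "deleted" or "neutral".
#' @export
call_cdkn2a <- function(cn, config = default_config()) {
  if (cn < 0) stop("input error: copy-number value must be >= 0", call. = FALSE)
  if (cn < config$ddpcr$cdkn2a_deleted_below) "deleted" else "neutral"
}

#' Call FGFR1 tyrosine-kinase-domain duplication
#'
#' Duplicated when the exon16:exon8 concentration ratio reaches the
#' configured boundary (default 1.125, boundary included).
#'
#' @param lambda_exon16,lambda_exon8 copies/droplet for the two amplicons
#'   (replicate-averaged); exon 8 must be > 0.
#' @param config pipeline configuration.
#' @return list with \code{call} ("duplicated"/"neutral") and \code{ratio}.
#' @export
call_fgfr1_tkd <- function(lambda_exon16, lambda_exon8, config = default_config()) {
  if (lambda_exon8 <= 0)
    stop("division error: exon-8 lambda must be > 0", call. = FALSE)
  ratio <- lambda_exon16 / lambda_exon8
  list(call = if (ratio >= config$ddpcr$fgfr1_tkd_ratio) "duplicated" else "neutral",
       ratio = ratio)
}

#' Call all ddPCR assays for a cohort droplet table
#'
#' Interprets the duplex targets of the shipped design: \code{BRAF_V600E},
#' \code{H3F3A_K28M} and \code{H3F3A_G35R} are mutant/wild-type hotspot
#' duplexes; \code{CDKN2A} pairs the target (mut channel) with the APB31
#' reference (wt channel); \code{FGFR1_TKD} pairs exon 16 (mut channel)
#' with exon 8 (wt channel).
#'
#' @param droplets data frame with columns \code{sample_id}, \code{target},
#'   \code{replicate}, \code{n_droplets}, \code{positive_mut},
#'   \code{positive_wt}.
#' @param config pipeline configuration.
#' @return data frame: \code{sample_id}, \code{target}, \code{call},
#'   \code{value} (MAF percent, CN value or exon ratio).
#' @export
call_ddpcr_table <- function(droplets, config = default_config()) {
  out <- list()
  for (sid in unique(droplets$sample_id)) {
    ds <- droplets[droplets$sample_id == sid, , drop = FALSE]
    for (tg in unique(ds$target)) {
      a <- ds[ds$target == tg, , drop = FALSE]
      a <- a[order(a$replicate), , drop = FALSE]
      vol <- config$ddpcr$droplet_volume_nl
      lam <- function(col) mean(vapply(seq_len(nrow(a)), function(i)
        quantify_target(a[[col]][i], a$n_droplets[i], vol)$lambda_hat, 0))
      row <- switch(tg,
        CDKN2A = {
          cn <- copy_number_value(lam("positive_mut"), lam("positive_wt"))
          data.frame(sample_id = sid, target = tg,
                     call = call_cdkn2a(cn, config), value = cn)
        },
        FGFR1_TKD = {
          r <- call_fgfr1_tkd(lam("positive_mut"), lam("positive_wt"), config)
          data.frame(sample_id = sid, target = tg, call = r$call, value = r$ratio)
        },
        {
          h <- call_hotspot(a, config)
          data.frame(sample_id = sid, target = tg, call = h$call,
                     value = min(h$maf))
        })
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), target = character(),
                      call = character(), value = numeric()))
  do.call(rbind, out)
}
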