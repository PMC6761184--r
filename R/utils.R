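#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; clinical summary tables in this
#' field conventionally round half up. Used for every printed percentage.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1, the reporting precision).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with reporting rounding
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places.
#' @return percentage rounded half-up; \code{NA} for zero denominators.
#' @export
pct <- function(num, den, digits = 1) {
  out <- round_half_up(100 * num / den, digits)
  out[rep_len(den == 0, length(out))] <- NA_real_
  out
}

#' Geometric mean
#' @param x positive numeric vector.
#' @return geometric mean.
#' @keywords internal
geom_mean <- function(x) exp(mean(log(x)))

# single-value assertions used across modules
stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  invisible(x)
}

#' Driver vocabulary
#'
#' Enumerated molecular drivers recognised by the pipeline. Fusions are named
#' by the canonical partner pair where one exists; \code{*_FUSION} entries
#' cover any activating fusion of that receptor tyrosine kinase.
#'
#' @return character vector of driver identifiers.
#' @export
driver_levels <- function() {
  c("KIAA1549_BRAF", "BRAF_V600E", "FGFR1_TACC1", "FGFR1_TKD", "PML_RAF1",
    "MYBL1_GAIN", "ALK_FUSION", "ROS1_FUSION", "NTRK_FUSION", "MET_FUSION",
    "OTHER", "NONE")
}

#' Tumor location vocabulary
#' @return character vector: hemispheric, midline, other.
#' @export
location_levels <- function() c("hemispheric", "midline", "other")

#' Deterministic per-sample seed stream
#'
#' Derives a child seed from a base seed and an index, kept below 2^31 so it
#' is always a valid R integer.
#'
#' @keywords internal
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 69621) %% 2147483587) + 1L
}
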