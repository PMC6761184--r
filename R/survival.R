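# Endpoint derivation and survival statistics. The estimators are the
# standard clinical ones (product-limit curve with Greenwood variance,
# log-rank test, Cox proportional hazards with Efron ties and Wald tests),
# computed via the survival package; confidence bands default to the
# log-survival transform, that machinery's default.

#' Derive OS and PFS records from clinical dates
#'
#' OS is the time from diagnosis to death, or to last follow-up for
#' patients still alive; PFS is the time from diagnosis to the first
#' progression requiring a change in clinical management, or to last
#' follow-up without progression. Times are reported in years (365.25-day
#' years). Records missing a diagnosis date are excluded with a recorded
#' reason; PFS time never exceeds OS time.
#'
#' @param clinical data frame with columns \code{sample_id}, \code{dx_date},
#'   \code{last_fu_date}, and optional \code{death_date},
#'   \code{progression_date} (Date or coercible).
#' @return data frame with \code{sample_id}, \code{endpoint} ("OS"/"PFS"),
#'   \code{time} (years) and \code{event} (1 event, 0 censored); excluded
#'   samples in \code{attr(,"excluded")}.
#' @export
derive_endpoints <- function(clinical) {
  dt <- function(col) if (is.null(clinical[[col]])) rep(NA, nrow(clinical))
                      else as.Date(clinical[[col]])
  dx <- dt("dx_date"); fu <- dt("last_fu_date")
  death <- dt("death_date"); prog <- dt("progression_date")
  bad <- is.na(dx)
  if (any(bad))
    warning("record-level error: missing diagnosis date, excluded: ",
            paste(clinical$sample_id[bad], collapse = ", "), call. = FALSE)
  keep <- which(!bad)
  yrs <- function(a, b) as.numeric(b - a) / 365.25
  rows <- lapply(keep, function(i) {
    os_end <- if (!is.na(death[i])) death[i] else fu[i]
    os_t <- yrs(dx[i], os_end)
    pfs_end <- if (!is.na(prog[i])) prog[i] else os_end
    pfs_t <- min(yrs(dx[i], pfs_end), os_t)
    data.frame(sample_id = clinical$sample_id[i],
               endpoint = c("OS", "PFS"),
               time = c(os_t, pfs_t),
               event = c(as.integer(!is.na(death[i])),
                         as.integer(!is.na(prog[i]))))
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- clinical$sample_id[bad]
  out
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimate with Greenwood variance and 95\% confidence
#' bands on the log-survival scale (set \code{conf_type = "log-log"} for
#' the complementary log-log transform).
#'
#' @param time follow-up times (> 0), years.
#' @param event event indicators (1 event, 0 censored).
#' @param conf_type "log" (default) or "log-log".
#' @return object of class \code{km_curve}: data frame of event times with
#'   \code{n_risk}, \code{n_event}, \code{surv}, \code{std_err} (of S, via
#'   Greenwood), \code{lower}, \code{upper}; max follow-up in
#'   \code{attr(,"max_time")}.
#' @export
km_estimate <- function(time, event, conf_type = c("log", "log-log")) {
  conf_type <- match.arg(conf_type)
  if (length(time) < 1) stop("input error: no records", call. = FALSE)
  if (any(time <= 0)) stop("input error: times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = sub("log-log", "log-log", conf_type))
  s <- summary(fit, censored = TRUE)
  curve <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                      surv = s$surv, std_err = s$std.err,
                      lower = pmax(0, pmin(1, s$lower)),
                      upper = pmax(0, pmin(1, s$upper)))
  structure(curve, class = c("km_curve", "data.frame"),
            max_time = max(time), conf_type = conf_type)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, max follow-up %.2f y\n",
              nrow(x), attr(x, "max_time")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation with the 95\% interval,
#' formatted as percentages at the 1-decimal reporting precision. Times
#' past the last observed follow-up return the last estimate with a
#' truncation flag.
#'
#' @param curve a \code{\link{km_estimate}} result.
#' @param t time (years, >= 0), vectorised.
#' @return data frame: \code{t}, \code{surv_pct}, \code{lower_pct},
#'   \code{upper_pct}, \code{truncated}.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("input error: t must be >= 0", call. = FALSE)
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  eval1 <- function(ti) {
    i <- findInterval(ti, ev$time)   # right-continuous: S(t) = S at last event <= t
    if (i == 0) c(1, 1, 1) else unlist(ev[i, c("surv", "lower", "upper")])
  }
  vals <- t(vapply(t, eval1, numeric(3)))
  data.frame(t = t,
             surv_pct  = round_half_up(100 * vals[, 1], 1),
             lower_pct = round_half_up(100 * vals[, 2], 1),
             upper_pct = round_half_up(100 * vals[, 3], 1),
             truncated = t > attr(curve, "max_time"))
}

#' Log-rank test across groups
#'
#' Observed-minus-expected statistic with hypergeometric variance,
#' df = number of groups - 1.
#'
#' @param time,event follow-up times and event indicators.
#' @param group group labels (>= 2 distinct values, each non-empty).
#' @return list: \code{chisq}, \code{df}, \code{p}.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("test error: log-rank needs >= 2 groups", call. = FALSE)
  d <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(d$n) - 1
  list(chisq = unname(d$chisq), df = df,
       p = stats::pchisq(d$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards model with Wald tests
#'
#' Partial-likelihood fit with Efron tie handling (Breslow selectable);
#' per-covariate hazard ratios with 95\% Wald intervals and p-values.
#' Errors when there are no events or the likelihood is monotone
#' (complete separation).
#'
#' @param data data frame containing \code{time}, \code{event} and the
#'   covariates.
#' @param covariates character vector of covariate column names (numeric
#'   or binary-encoded).
#' @param ties "efron" (default) or "breslow".
#' @return data frame: \code{covariate}, \code{coef}, \code{hr},
#'   \code{hr_lower}, \code{hr_upper}, \code{se}, \code{wald_p}.
#' @export
cox_ph <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(data$event) == 0)
    stop("estimation error: no events observed", call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-10)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("estimation error: monotone likelihood (complete separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  data.frame(covariate = rownames(co),
             coef = co[, "coef"],
             hr = exp(co[, "coef"]),
             hr_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             hr_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             se = co[, "se(coef)"],
             wald_p = co[, "Pr(>|z|)"],
             row.names = NULL)
}
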