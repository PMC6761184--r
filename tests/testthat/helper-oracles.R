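# Independent oracles used across tests. None of these call package code.

# type-7 (linear interpolation) quantile computed directly from sorted order
# statistics: h = (n-1)p + 1, Q = x[h0] + (h - h0) (x[h0+1] - x[h0])
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  h0 <- floor(h)
  x[h0] + (h - h0) * (c(x, x[n])[h0 + 1] - x[h0])
}

# hand log-rank: loop over distinct event times, O-E with hypergeometric
# variance for the first group
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Cox partial log-likelihood for one covariate, no ties (Breslow = Efron
# when event times are unique); maximised by brute-force grid + optimize
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_coef <- function(time, event, x, lower = -5, upper = 5) {
  grid <- seq(lower, upper, by = 1e-3)
  ll <- vapply(grid, oracle_cox_loglik, 0, time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(oracle_cox_loglik, c(b0 - 2e-3, b0 + 2e-3), maximum = TRUE,
                  time = time, event = event, x = x, tol = 1e-9)$maximum
}

# hand product-limit estimate at event times
oracle_km <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# bisection to the switch point of a monotone boolean rule
bisect_boundary <- function(rule, lo, hi, tol = 1e-6) {
  stopifnot(!rule(lo), rule(hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rule(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# small raw count panel used by several tests: nl lanes, constant means
make_test_panel <- function(nl = 10, fusion_counts = NULL, seed = 1) {
  set.seed(seed)
  panel <- default_panel()
  cfg <- default_config()
  cohort <- data.frame(sample_id = sprintf("L%02d", seq_len(nl)),
                       true_driver = "NONE", partner_known = FALSE)
  m <- vapply(seq_len(nl), function(i)
    simulate_count_lane(cohort[i, ], cfg, panel), numeric(nrow(panel)))
  colnames(m) <- cohort$sample_id
  rownames(m) <- panel$probe_id
  if (!is.null(fusion_counts))
    m["PPP1CB_ALK", seq_along(fusion_counts)] <- fusion_counts
  count_panel(m, panel)
}
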