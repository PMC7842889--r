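#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' computed from group means, standard deviations and sizes. This is the test
#' used for the continuous state-covariate comparisons; it reproduces the
#' published group p-values from their printed summaries, which the pooled
#' test does not.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list of class `comparison_result`: `variable`, `test`,
#'   `group_summaries`, `statistic` (t), `df`, `p_value`.
#' @examples
#' welch_t_from_summary(7.5, 2.62, 34, 9.5, 3.54, 16)$p_value  # ~0.056
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 <= 0 || sd2 <= 0) stop("degenerate standard deviation")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(variable = NA_character_, test = "welch_t",
                 group_summaries = list(g1 = c(mean = mean1, sd = sd1, n = n1),
                                        g2 = c(mean = mean2, sd = sd2, n = n2)),
                 statistic = tstat, df = df, p_value = p),
            class = "comparison_result")
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Yates-corrected chi-square on 1 df for a 2x2 table laid out as rows =
#' groups, columns = outcome (yes, no):
#' `chi2 = n (|ad - bc| - n/2)^2 / (r1 r2 c1 c2)`.
#'
#' @param a,b first row (yes, no); @param c,d second row.
#' @return `comparison_result` with `statistic` (chi-square), `df = 1`,
#'   `p_value`; if any margin is zero the test is undefined and flagged
#'   (`undefined = TRUE`, p = NA).
#' @examples
#' yates_chi2_2x2(27, 7, 9, 7)$p_value  # ~0.173
#' @export
yates_chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    return(structure(list(variable = NA_character_, test = "yates_chi2",
                          group_summaries = list(g1 = c(yes = a, n = r1),
                                                 g2 = c(yes = c, n = r2)),
                          statistic = NA_real_, df = 1L, p_value = NA_real_,
                          undefined = TRUE),
                     class = "comparison_result"))
  }
  stat <- n * (abs(a * d - b * c) - n / 2)^2 / (r1 * r2 * c1 * c2)
  # correction cannot push the statistic past zero
  if (abs(a * d - b * c) <= n / 2) stat <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(variable = NA_character_, test = "yates_chi2",
                 group_summaries = list(g1 = c(yes = a, n = r1),
                                        g2 = c(yes = c, n = r2)),
                 statistic = stat, df = 1L, p_value = p, undefined = FALSE),
            class = "comparison_result")
}

#' Two-group Poisson rate comparison with exposure offset
#'
#' Closed-form Wald test of the log rate ratio from a two-group Poisson model
#' with an exposure offset: `log RR = log((e2/x2)/(e1/x1))`,
#' `SE = sqrt(1/e1 + 1/e2)`. Used for count covariates (e.g. treatment
#' centers) adjusted for the relevant population.
#'
#' @param events1,exposure1 events and exposure in group 1.
#' @param events2,exposure2 events and exposure in group 2.
#' @return `comparison_result` with `rate_ratio`, `statistic` (z),
#'   `p_value`; flagged `undefined` when both event counts are zero (and the
#'   Wald SE is undefined when either is zero).
#' @export
poisson_rate_compare <- function(events1, exposure1, events2, exposure2) {
  stopifnot(events1 >= 0, events2 >= 0, exposure1 > 0, exposure2 > 0)
  if (events1 == 0 && events2 == 0) {
    return(structure(list(variable = NA_character_, test = "poisson_rate",
                          group_summaries = list(g1 = c(events = events1, exposure = exposure1),
                                                 g2 = c(events = events2, exposure = exposure2)),
                          rate_ratio = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, undefined = TRUE),
                     class = "comparison_result"))
  }
  rr <- (events2 / exposure2) / (events1 / exposure1)
  log_rr <- log(rr)
  se <- sqrt(1 / events1 + 1 / events2)  # Inf when either count is 0
  z <- log_rr / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(variable = NA_character_, test = "poisson_rate",
                 group_summaries = list(g1 = c(events = events1, exposure = exposure1),
                                        g2 = c(events = events2, exposure = exposure2)),
                 rate_ratio = rr, log_rate_ratio = log_rr, se = se,
                 statistic = z, p_value = p,
                 undefined = !is.finite(se)),
            class = "comparison_result")
}

#' Simulated-null envelope for ordered p-values (p-p diagnostic)
#'
#' Simulates `n_sim` draws of `k` independent Uniform(0,1) p-values, sorts
#' each draw, and takes rank-wise empirical quantiles to form a
#' `coverage`-level envelope for the observed ordered p-values. Under the
#' null of no group differences across the battery, observed ordered
#' p-values should lie within the envelope (the i-th order statistic of k
#' iid uniforms is Beta(i, k-i+1), which the simulation approximates).
#'
#' @param pvalues observed p-values (each in `[0,1]`).
#' @param n_sim number of simulated null draws (>= 1000).
#' @param coverage envelope coverage (default 0.95).
#' @param seed integer seed, recorded in the result.
#' @return object of class `pp_diagnostic`: `k`, sorted `observed`,
#'   `envelope_low`, `envelope_high`, `n_sim`, `seed`, `all_within`.
#' @export
pp_envelope <- function(pvalues, n_sim = 10000L, coverage = 0.95, seed = 1L) {
  if (length(pvalues) == 0L) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0,1]")
  if (n_sim < 1000L) stop("n_sim must be at least 1000")
  k <- length(pvalues)
  obs <- sort(pvalues)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sims <- matrix(stats::runif(n_sim * k), nrow = n_sim, ncol = k)
  sorted <- t(apply(sims, 1L, sort.int, method = "quick"))
  alpha <- (1 - coverage) / 2
  lo <- apply(sorted, 2L, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(sorted, 2L, stats::quantile, probs = 1 - alpha, names = FALSE)
  structure(list(k = k, observed = obs, envelope_low = lo, envelope_high = hi,
                 n_sim = n_sim, seed = seed, coverage = coverage,
                 all_within = all(obs >= lo & obs <= hi)),
            class = "pp_diagnostic")
}

#' @export
plot.pp_diagnostic <- function(x, ...) {
  expected <- stats::qbeta(0.5, seq_len(x$k), x$k - seq_len(x$k) + 1)
  graphics::plot(expected, x$observed, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Expected order statistic (null median)",
                 ylab = "Observed ordered p-value", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::lines(expected, x$envelope_low, col = "grey40")
  graphics::lines(expected, x$envelope_high, col = "grey40")
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Power of the two-sample t-test via the noncentral t distribution
#'
#' @param d standardized effect size (difference in means / common SD).
#' @param n1,n2 group sizes.
#' @param alpha significance level.
#' @param two_sided two-sided test (default) or one-sided.
#' @return power (probability of rejection).
#' @examples
#' power_t_two_sample(0.8, 34, 16)  # ~0.734
#' @export
power_t_two_sample <- function(d, n1, n2, alpha = 0.05, two_sided = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (two_sided) {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
}

#' Power of the two-sample proportion test (pooled-variance normal approximation)
#'
#' Normal-approximation power for the two-sided two-sample proportion test,
#' pooled variance under the null and unpooled under the alternative:
#' `power = Phi((|p1-p2| - z * se0) / se1) + Phi((-|p1-p2| - z * se0) / se1)`.
#'
#' @param p1,p2 true proportions in (0,1).
#' @param n1,n2 group sizes.
#' @param alpha significance level (two-sided).
#' @return power.
#' @examples
#' power_two_proportions(0.20, 0.55, 34, 16)  # ~0.70
#' @export
power_two_proportions <- function(p1, p2, n1, n2, alpha = 0.05) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, n1 >= 2, n2 >= 2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- stats::qnorm(1 - alpha / 2)
  delta <- abs(p1 - p2)
  stats::pnorm((delta - z * se0) / se1) + stats::pnorm((-delta - z * se0) / se1)
}

#' Default battery specification for a state covariate table
#'
#' One row per tested variable: which test to apply (`welch_t`,
#' `welch_t_log`, `yates_chi2`) and in which order. Population uses the
#' log-transformed Welch test; the two policy flags use the
#' continuity-corrected chi-square.
#'
#' @return data.frame with columns `variable`, `test`.
#' @export
battery_variables <- function() {
  data.frame(
    variable = c("population", "urban_pct", "minority_pct", "poverty_pct",
                 "uninsured_pct", "opioid_rx_per100", "misuse12plus_pct",
                 "misuse12_17_pct", "misuse18_25_pct", "misuse26plus_pct",
                 "admissions_per100k", "deaths_per100k", "sor_dollars_per_person",
                 "mm_clinics_per100k", "misuse_per_mm_center_per100k",
                 "rx_physicians_per100k", "medicaid_expansion", "moud_covered"),
    test = c("welch_t_log", rep("welch_t", 15), "yates_chi2", "yates_chi2"),
    stringsAsFactors = FALSE)
}

#' Run the state-covariate comparison battery
#'
#' Compares SOR-providing vs non-providing states on every configured
#' variable: Welch t-tests for continuous covariates (log scale for
#' population), Yates chi-square for binary flags, Poisson rate comparison
#' where configured (columns `<variable>` as events with `<variable>_exposure`
#' as exposure). Missing values are dropped per variable (complete-case) and
#' the drop count reported; a variable entirely missing in one group is
#' flagged and skipped.
#'
#' @param records data.frame of state records including logical
#'   `sor_provided` plus the battery variables.
#' @param variables battery specification as from [battery_variables()];
#'   rows for variables absent from `records` are ignored.
#' @return data.frame of class `battery_result`: `variable`, `test`,
#'   per-group summaries, `n_dropped`, `statistic`, `p_value`, `note`.
#' @export
run_battery <- function(records, variables = battery_variables()) {
  stopifnot(is.data.frame(records), "sor_provided" %in% names(records))
  g1 <- records$sor_provided
  if (!any(g1) || !any(!g1)) stop("both groups must be non-empty")
  variables <- variables[variables$variable %in% names(records), , drop = FALSE]
  rows <- lapply(seq_len(nrow(variables)), function(i) {
    v <- variables$variable[i]
    test <- variables$test[i]
    x <- records[[v]]
    out <- data.frame(variable = v, test = test,
                      mean1 = NA_real_, sd1 = NA_real_, n1 = NA_integer_,
                      mean2 = NA_real_, sd2 = NA_real_, n2 = NA_integer_,
                      n_dropped = sum(is.na(x)), statistic = NA_real_,
                      p_value = NA_real_, note = "", stringsAsFactors = FALSE)
    x1 <- x[g1 & !is.na(x)]
    x2 <- x[!g1 & !is.na(x)]
    if (length(x1) < 2L || length(x2) < 2L) {
      out$note <- "skipped: variable missing in one group"
      return(out)
    }
    if (test %in% c("welch_t", "welch_t_log")) {
      y1 <- x1; y2 <- x2
      if (test == "welch_t_log") { y1 <- log(x1); y2 <- log(x2) }
      r <- welch_t_from_summary(mean(y1), stats::sd(y1), length(y1),
                                mean(y2), stats::sd(y2), length(y2))
      out$mean1 <- mean(x1); out$sd1 <- stats::sd(x1); out$n1 <- length(x1)
      out$mean2 <- mean(x2); out$sd2 <- stats::sd(x2); out$n2 <- length(x2)
      out$statistic <- r$statistic; out$p_value <- r$p_value
    } else if (test == "yates_chi2") {
      r <- yates_chi2_2x2(sum(x1), sum(!x1), sum(x2), sum(!x2))
      out$mean1 <- mean(x1); out$n1 <- length(x1)
      out$mean2 <- mean(x2); out$n2 <- length(x2)
      out$statistic <- r$statistic; out$p_value <- r$p_value
      if (isTRUE(r$undefined)) out$note <- "undefined: zero margin"
    } else if (test == "poisson_rate") {
      expo <- records[[paste0(v, "_exposure")]]
      ok <- !is.na(x) & !is.na(expo)
      r <- poisson_rate_compare(sum(x[ok & g1]), sum(expo[ok & g1]),
                                sum(x[ok & !g1]), sum(expo[ok & !g1]))
      out$statistic <- r$statistic; out$p_value <- r$p_value
      if (isTRUE(r$undefined)) out$note <- "undefined: zero events"
    } else {
      stop("unknown test: ", test)
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("battery_result", class(res))
  res
}

#' Read a state covariate table
#'
#' CSV with columns named as in [battery_variables()] plus `state_id` and
#' `sor_provided` (0/1 or logical); empty cells are missing values.
#'
#' @param path CSV path.
#' @return data.frame with `sor_provided`, `medicaid_expansion`,
#'   `moud_covered` as logical.
#' @export
read_state_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("state_id", "sor_provided") %in% names(d))) {
    stop("state table must have columns state_id, sor_provided")
  }
  for (v in c("sor_provided", "medicaid_expansion", "moud_covered")) {
    if (v %in% names(d)) d[[v]] <- as.logical(d[[v]] == 1 | d[[v]] == TRUE)
  }
  pct <- grep("_pct$", names(d), value = TRUE)
  for (v in pct) {
    bad <- !is.na(d[[v]]) & (d[[v]] < 0 | d[[v]] > 100)
    if (any(bad)) stop("percent column ", v, " outside [0,100]")
  }
  d
}
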