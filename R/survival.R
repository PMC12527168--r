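# Kaplan-Meier estimation and the stratified (Mantel-Haenszel) log-rank
# test, implemented from the product-limit and hypergeometric formulas so
# every quantity is auditable; replicate cultures enter the comparison as
# strata.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, with
#' Greenwood's variance on the log scale for pointwise confidence
#' intervals. Individuals censored at an event time are counted as at risk
#' through that time (right-continuous convention).
#'
#' @param data Data frame with one row per individual.
#' @param time,event Column names (default `"time_days"`, `"event"`; event
#'   1 = death observed, 0 = right-censored).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of class `zw_km`, one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `estimate`, `std_error`
#'   (Greenwood, on the survival scale), `conf_low`, `conf_high`.
#' @export
#' @examples
#' km_estimate(tibble::tibble(time_days = c(1, 2, 3), event = 1))
km_estimate <- function(data, time = "time_days", event = "event",
                        conf_level = 0.95) {
  t <- as.numeric(data[[time]])
  ev <- as.integer(data[[event]])
  if (any(t <= 0) || anyNA(t)) abort("times must be positive and non-missing")
  if (!all(ev %in% c(0L, 1L))) abort("event must be 0 (censored) or 1")
  ut <- sort(unique(t))
  n <- length(t)
  n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
  n_event <- vapply(ut, function(u) sum(t == u & ev == 1L), numeric(1))
  n_censor <- vapply(ut, function(u) sum(t == u & ev == 0L), numeric(1))
  s <- cumprod(1 - n_event / n_risk)
  # Greenwood: Var(S) = S^2 * sum d / (n (n - d))
  gw_term <- if_else(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)),
                     NA_real_)
  gw <- cumsum(gw_term)
  se <- s * sqrt(gw)
  # log-scale CI: exp(log S -+ z * se(log S)), se(log S)^2 = sum term
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- if_else(s > 0, s * exp(-z * sqrt(gw)), NA_real_)
  hi <- if_else(s > 0, pmin(1, s * exp(z * sqrt(gw))), NA_real_)
  out <- tibble(time = ut, n_risk = n_risk, n_event = n_event,
                n_censor = n_censor, estimate = s, std_error = se,
                conf_low = lo, conf_high = hi)
  class(out) <- c("zw_km", class(out))
  attr(out, "n") <- n
  attr(out, "conf_level") <- conf_level
  out
}

#' @rdname zw_tidiers
#' @export
tidy.zw_km <- function(x, ...) as_tibble(unclass(x)[seq_along(x)])

#' @rdname zw_tidiers
#' @export
glance.zw_km <- function(x, ...) {
  tibble(n = attr(x, "n"), events = sum(x$n_event),
         rmst = restricted_mean_survival(x),
         median_survival = km_median(x))
}

km_median <- function(km) {
  i <- which(km$estimate <= 0.5)
  if (length(i) == 0) return(NA_real_)
  km$time[i[1]]
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Area under the step function `S(t)` from 0 to `tau` (default: the
#' largest observed time). With complete follow-up (no censoring) this
#' equals the sample mean.
#'
#' @param km A [km_estimate()] result.
#' @param tau Upper integration limit (default `max(km$time)`).
#' @return Mean survival time in the input time unit.
#' @export
restricted_mean_survival <- function(km, tau = NULL) {
  stopifnot(inherits(km, "zw_km"))
  tau <- tau %||% max(km$time)
  tt <- km$time[km$time <= tau]
  lower <- c(0, tt)
  upper <- c(tt, tau)
  surv <- c(1, km$estimate[km$time <= tau])
  # S is right-continuous: surv[i] holds on [lower[i], upper[i])
  sum(surv * pmax(0, upper - lower))
}

#' Stratified (Mantel-Haenszel) log-rank test
#'
#' At every event time within every stratum, the observed number of deaths
#' in the first group is compared with its hypergeometric expectation given
#' the at-risk counts; observed-minus-expected differences and their
#' variances are summed across times and strata, and
#' `(sum(O - E))^2 / sum(V)` is referred to a chi-squared distribution with
#' one degree of freedom. With a single stratum this is the ordinary
#' log-rank test. Strata containing only one group are skipped with a
#' warning.
#'
#' @param data Data frame with one row per individual.
#' @param group Column name of the two-level group factor (default `"sex"`).
#' @param stratum Optional column name of the stratum labels (replicate
#'   cultures); `NULL` for an unstratified test.
#' @inheritParams km_estimate
#' @return A `zw_htest` with the chi-squared statistic; the `estimate` slot
#'   holds `sum(O - E)` for the first group level.
#' @export
stratified_logrank <- function(data, group = "sex", stratum = NULL,
                               time = "time_days", event = "event") {
  data <- as_tibble(data)
  g <- as.character(data[[group]])
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("`group` must have exactly 2 levels")
  strat <- if (is.null(stratum)) rep("all", nrow(data)) else
    as.character(data[[stratum]])
  t <- as.numeric(data[[time]])
  ev <- as.integer(data[[event]])
  if (any(t <= 0)) abort("times must be positive")
  if (sum(ev) == 0) abort("no events observed")
  oe <- 0; vv <- 0
  for (s in unique(strat)) {
    i <- strat == s
    if (length(unique(g[i])) < 2) {
      warn(sprintf("stratum '%s' contains a single group; skipped", s))
      next
    }
    ts <- t[i]; evs <- ev[i]; g1 <- g[i] == lev[1]
    for (u in sort(unique(ts[evs == 1L]))) {
      at <- ts >= u
      n_tot <- sum(at); n1 <- sum(at & g1)
      d <- sum(ts == u & evs == 1L)
      d1 <- sum(ts == u & evs == 1L & g1)
      e1 <- d * n1 / n_tot
      v1 <- if (n_tot > 1) {
        d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
      } else 0
      oe <- oe + (d1 - e1)
      vv <- vv + v1
    }
  }
  if (vv == 0) {
    return(new_htest(0, 1, "Stratified log-rank (Mantel-Haenszel) test",
                     "two_sided", c(n = nrow(data)), estimate = oe))
  }
  chisq <- oe^2 / vv
  new_htest(chisq, pchisq(chisq, df = 1, lower.tail = FALSE),
            "Stratified log-rank (Mantel-Haenszel) test", "two_sided",
            c(n = nrow(data)), estimate = oe)
}
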