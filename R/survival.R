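# Product-limit survival estimation and the two-group log-rank test.

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator: `S(t) = prod_{t_k <= t} (1 - d_k/n_k)`
#' over distinct event times. Subjects censored at an event time are still
#' at risk for that event (events processed before censorings at ties).
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return Object of class `km_curve`: data.frame with `time` (distinct
#'   event times), `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Survival probability at given times from a KM curve
#' @param curve A [km_estimate()] result.
#' @param t Times at which to evaluate the step function.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation given the risk sets; the statistic
#' is `(sum O - sum E)^2 / sum V`, referred to chi-square with 1 df.
#'
#' @param time Follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group Two-level factor/vector of group membership.
#' @return list with `statistic`, `pvalue`, `observed`, `expected` (both
#'   for the first group level), `n`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative follow-up time")
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two groups")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  if (sum(event) == 0L) stop("no events observed")
  et <- sort(unique(time[event == 1]))
  in1 <- g == levels(g)[1L]
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V == 0) 0 else (O - E)^2 / V
  list(statistic = stat, pvalue = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E, n = length(time))
}
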