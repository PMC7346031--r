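# Kaplan-Meier product-limit estimation and the log-rank test, written out
# from the standard O/E/hypergeometric-variance construction. Samples
# censored at an event time are counted at risk for that event (the usual
# convention). The multi-group statistic uses the first k-1 groups and the
# full hypergeometric covariance, on k-1 degrees of freedom.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times.
#'
#' @param times non-negative follow-up times.
#' @param events event indicator (1 = death, 0 = censored).
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `n_censor` (number censored since the previous
#'   event time, inclusive of the current one), `surv`.
#' @examples
#' kmEstimate(c(5, 8, 12), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(times, events) {
  n <- length(times)
  if (!n) .stopf("empty survival input")
  if (length(events) != n) .stopf("times and events lengths differ")
  if (any(times < 0)) .stopf("times must be non-negative")
  if (!all(events %in% c(0, 1))) .stopf("events must be 0 or 1")
  eventTimes <- sort(unique(times[events == 1]))
  surv <- 1
  prevT <- -Inf
  rows <- lapply(eventTimes, function(t) {
    nRisk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    cens <- sum(times >= prevT & times <= t & events == 0 &
                  (times > prevT | prevT == -Inf))
    prevT <<- t
    surv <<- surv * (1 - d / nRisk)
    data.frame(time = t, n_risk = nRisk, n_event = d, n_censor = cens,
               surv = surv)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               n_censor = integer(), surv = numeric())
  attr(out, "n") <- n
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km data.frame from [kmEstimate()].
#' @param at times at which to evaluate the step function.
#' @return Numeric survival probabilities.
#' @export
kmSurvivalAt <- function(km, at) {
  vapply(at, function(t) {
    past <- km$surv[km$time <= t]
    if (length(past)) past[length(past)] else 1
  }, numeric(1))
}

# Moore-Penrose inverse via SVD (for degenerate log-rank covariance)
.ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Log-rank test
#'
#' The standard chi-square statistic from observed minus expected deaths
#' with hypergeometric variance at each event time; two groups give the
#' familiar `(O - E)^2 / V` on 1 df, k groups a quadratic form on k-1 df.
#'
#' @param times non-negative follow-up times.
#' @param events event indicator (1 = death, 0 = censored).
#' @param groups group label per sample (>= 2 distinct values present).
#' @return An `htest` with `statistic`, `parameter` (df) and `p.value`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  if (k < 2L) .stopf("log-rank needs at least 2 groups")
  if (!sum(events == 1)) .stopf("log-rank needs at least 1 event")
  if (any(times < 0)) .stopf("times must be non-negative")
  eventTimes <- sort(unique(times[events == 1]))
  O <- E <- setNames(numeric(k), levels(groups))
  V <- matrix(0, k, k, dimnames = list(levels(groups), levels(groups)))
  for (t in eventTimes) {
    atRisk <- times >= t
    nj <- sum(atRisk)
    dj <- sum(times == t & events == 1)
    ngj <- vapply(levels(groups), function(g) sum(atRisk & groups == g),
                  numeric(1))
    dgj <- vapply(levels(groups), function(g)
      sum(times == t & events == 1 & groups == g), numeric(1))
    O <- O + dgj
    E <- E + dj * ngj / nj
    if (nj > 1) {
      scale <- dj * (nj - dj) / (nj - 1)
      V <- V + scale * (diag(ngj / nj, k) - tcrossprod(ngj / nj)) *
        1  # hypergeometric covariance of per-group deaths
    }
  }
  d <- (O - E)[-k]
  Vr <- V[-k, -k, drop = FALSE]
  stat <- if (max(abs(Vr)) == 0) 0 else
    drop(t(d) %*% .ginv(Vr) %*% d)
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  .htest(c(chisq = stat), p, "log-rank test",
         parameter = c(df = k - 1), n = length(times))
}

#' Remove very short survivors
#'
#' Drops records with overall survival strictly below `minMonths` (default
#' one month; exactly one month is retained).
#'
#' @param clinical clinical data.frame with an `os_months` column.
#' @param minMonths exclusive lower cut in months.
#' @return The filtered data.frame.
#' @export
filterMinSurvival <- function(clinical, minMonths = 1) {
  clinical[clinical$os_months >= minMonths, , drop = FALSE]
}

#' Plot Kaplan-Meier curves by group
#'
#' Simple base-graphics step curves, one per group.
#'
#' @param times,events,groups as in [logrankTest()].
#' @param col colors per group.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the list of per-group [kmEstimate()] frames.
#' @export
plotKaplanMeier <- function(times, events, groups,
                            col = seq_along(unique(groups)), ...) {
  groups <- as.factor(as.character(groups))
  curves <- lapply(levels(groups), function(g) {
    kmEstimate(times[groups == g], events[groups == g])
  })
  names(curves) <- levels(groups)
  graphics::plot(NA, xlim = c(0, max(times)), ylim = c(0, 1),
                 xlab = "months", ylab = "overall survival", ...)
  for (i in seq_along(curves)) {
    km <- curves[[i]]
    graphics::lines(stats::stepfun(km$time, c(1, km$surv)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = levels(groups), col = col, lty = 1,
                   bty = "n")
  invisible(curves)
}
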