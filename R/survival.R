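## From-scratch product-limit estimation, two-group log-rank test and
## Mantel-Haenszel hazard ratio. Convention throughout: subjects censored at
## an event time are still at risk for that event time.

#' Censor follow-up at a horizon
#'
#' Subjects with `time > horizonMonths` are administratively censored at the
#' horizon (`time := horizon`, `event := 0`); others are unchanged.
#'
#' @param table survival `data.frame` (`sample`, `time`, `event`).
#' @param horizonMonths follow-up horizon (default 120, i.e. ten years);
#'   `Inf` is the identity.
#' @return The restricted survival `data.frame`.
#' @export
restrictFollowup <- function(table, horizonMonths = 120) {
  if (horizonMonths <= 0) stop("horizon must be > 0")
  over <- table$time > horizonMonths
  table$event[over] <- 0L
  table$time[over] <- horizonMonths
  table
}

#' Kaplan-Meier product-limit estimate
#'
#' @param table survival `data.frame` (`sample`, `time`, `event`).
#' @return A `data.frame` with one row per distinct event time: `time`,
#'   `n.risk`, `n.event`, `n.censor` (censorings in `(previous time, time]`,
#'   tied censorings counted at risk), and `surv`, the survival probability
#'   just after `time`. `S(0) = 1` is implicit.
#' @examples
#' kmEstimate(data.frame(sample = c("a", "b", "c"),
#'                       time = 1:3, event = c(1, 1, 0)))
#' @export
kmEstimate <- function(table) {
  if (nrow(table) == 0) stop("empty survival table")
  times <- sort(unique(table$time[table$event == 1]))
  if (length(times) == 0)
    return(data.frame(time = numeric(), n.risk = integer(),
                      n.event = integer(), n.censor = integer(),
                      surv = numeric()))
  n_risk <- vapply(times, function(t) sum(table$time >= t), numeric(1))
  n_event <- vapply(times, function(t)
    sum(table$time == t & table$event == 1), numeric(1))
  prev <- c(-Inf, times[-length(times)])
  n_censor <- vapply(seq_along(times), function(i)
    sum(table$event == 0 & table$time > prev[i] & table$time <= times[i]),
    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = times, n.risk = as.integer(n_risk),
             n.event = as.integer(n_event), n.censor = as.integer(n_censor),
             surv = surv)
}

join_strata <- function(table, strata, groups) {
  if (is.data.frame(strata)) {
    idx <- match(table$sample, strata$sample)
    grp <- strata$stratum[idx]
  } else {
    grp <- unname(strata[table$sample])
  }
  keep <- !is.na(grp) & grp %in% groups
  table <- table[keep, , drop = FALSE]
  grp <- factor(grp[keep], levels = groups)
  counts <- base::table(grp)
  if (any(counts == 0))
    stop("group(s) with no subjects: ",
         paste(groups[counts == 0], collapse = ", "))
  list(table = table, group = grp)
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected event count and hypergeometric
#' variance for the first group are accumulated over the risk sets; the
#' statistic is `(O - E)^2 / V` referred to chi-square with 1 df. Times
#' with zero variance contribute nothing. Samples outside the two groups
#' (e.g. a middle tertile) are excluded.
#'
#' @param table survival `data.frame` (`sample`, `time`, `event`).
#' @param strata a stratum assignment from [binByScore()] (or a named
#'   character vector of group labels).
#' @param groups the two group labels to compare (default
#'   `c("high", "low")`).
#' @return A [LogRankResult-class] object.
#' @export
logrankTest <- function(table, strata, groups = c("high", "low")) {
  stopifnot(length(groups) == 2)
  js <- join_strata(table, strata, groups)
  tab <- js$table; grp <- js$group
  times <- sort(unique(tab$time[tab$event == 1]))
  O1 <- sum(tab$event == 1 & grp == groups[1])
  Ototal <- sum(tab$event == 1)
  E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- tab$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == groups[1])
    d <- sum(tab$time == t & tab$event == 1)
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (Ototal == 0 || V == 0) {
    if (Ototal == 0)
      warning("no events in either group; log-rank statistic is 0",
              call. = FALSE)
    stat <- 0; p <- 1
  } else {
    stat <- (O1 - E1)^2 / V
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  new("LogRankResult",
      observed = setNames(c(O1, Ototal - O1), groups),
      expected = setNames(c(E1, Ototal - E1), groups),
      variance = V, statistic = stat, p.value = p)
}

#' Hazard ratio between two strata
#'
#' Default Mantel-Haenszel estimator: the ratio of observed-to-expected
#' event ratios `(O1/E1)/(O2/E2)` from the log-rank table, with log-scale
#' standard error `sqrt(1/E1 + 1/E2)` and a 95% confidence interval
#' `exp(log hr +/- 1.96 se)`. `method = "cox"` instead fits a univariate
#' Cox proportional-hazards model via [survival::coxph()] for comparison.
#'
#' @inheritParams logrankTest
#' @param method `"mantel-haenszel"` (default) or `"cox"`.
#' @return A [HazardRatioEstimate-class] object (first group relative to
#'   the second).
#' @export
hazardRatio <- function(table, strata, groups = c("high", "low"),
                        method = c("mantel-haenszel", "cox")) {
  method <- match.arg(method)
  if (method == "cox") {
    js <- join_strata(table, strata, groups)
    grp <- factor(js$group, levels = rev(groups))  # second group = baseline
    fit <- survival::coxph(
      survival::Surv(js$table$time, js$table$event) ~ grp)
    lhr <- unname(coef(fit)[1])
    se <- sqrt(unname(fit$var[1, 1]))
    return(new("HazardRatioEstimate", hr = exp(lhr), se.log = se,
               conf.low = exp(lhr - 1.96 * se),
               conf.high = exp(lhr + 1.96 * se), method = "cox"))
  }
  lr <- logrankTest(table, strata, groups)
  O <- lr@observed; E <- lr@expected
  if (any(E == 0))
    stop("a group has zero expected events; hazard ratio undefined ",
         "(check that both groups have follow-up at event times)")
  hr <- (O[[1]] / E[[1]]) / (O[[2]] / E[[2]])
  se <- sqrt(1 / E[[1]] + 1 / E[[2]])
  new("HazardRatioEstimate", hr = hr, se.log = se,
      conf.low = exp(log(hr) - 1.96 * se),
      conf.high = exp(log(hr) + 1.96 * se), method = "mantel-haenszel")
}
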