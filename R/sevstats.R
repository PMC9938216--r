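#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration with the sum-of-small-p
#' rule: with all margins fixed, every table whose probability does not
#' exceed that of the observed table (within a relative tolerance of
#' 1e-7) contributes to p. The sample odds ratio `(a d) / (b c)` is
#' reported alongside.
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))` —
#'   e.g. a = responders in group 1, b = non-responders in group 1.
#' @return list with `p`, `odds_ratio` and the observed table.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("fisher_2x2: counts must be non-negative integers")
  if (sum(counts) == 0)
    stop("fisher_2x2: all-zero table")
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c > 0) (a * d) / (b * c) else Inf
  list(p = min(1, p), odds_ratio = or,
       table = matrix(counts, 2, 2, byrow = TRUE))
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator of the survival function (or, equivalently,
#' 1 - cumulative incidence for onset data) with right censoring.
#'
#' @param times non-negative event/censoring times.
#' @param events logical (or 0/1): TRUE if the event was observed,
#'   FALSE if censored.
#' @return data.frame of steps: time, n_risk, n_event, surv.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("km_curve: empty group")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Log-rank test between two groups
#'
#' Standard observed-vs-expected accumulation over distinct event times
#' (1 degree of freedom), delegated to the survival machinery.
#'
#' @param time_a,event_a times and event indicators of group A.
#' @param time_b,event_b times and event indicators of group B.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (sum(event_a) + sum(event_b) == 0)
    stop("logrank_test: no events in either group")
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  group <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd_$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1,
                                        lower.tail = FALSE))
}

#' Social discrimination index
#'
#' `DI (%) = (t_mouse - t_object) / (t_mouse + t_object) * 100`,
#' bounded in `[-100, 100]`.
#'
#' @param t_mouse,t_object non-negative investigation times (seconds);
#'   vectorized.
#' @return numeric vector of DI percentages.
#' @export
discrimination_index <- function(t_mouse, t_object) {
  stopifnot(all(t_mouse >= 0), all(t_object >= 0))
  tot <- t_mouse + t_object
  if (any(tot == 0))
    stop("discrimination_index: t_mouse + t_object must be positive")
  (t_mouse - t_object) / tot * 100
}

#' Percent change in GTCS latency between genotypes
#'
#' Per seizure-induction trial, the ratio of the corrected genotype's
#' mean latency to the duplication genotype's mean latency; trials where
#' either genotype lacks an (uncensored) GTCS are excluded. The summary
#' is the mean per-trial ratio expressed as percent change.
#'
#' @param latencies_corr,latencies_dup lists (one element per trial) of
#'   uncensored GTCS latencies; empty elements mark trials without a
#'   GTCS for that genotype.
#' @return list with `per_trial_ratio`, `n_trials` (used) and
#'   `percent_change`.
#' @export
latency_shift_percent <- function(latencies_corr, latencies_dup) {
  stopifnot(length(latencies_corr) == length(latencies_dup))
  ratios <- numeric(0)
  for (i in seq_along(latencies_corr)) {
    lc <- latencies_corr[[i]]; ld <- latencies_dup[[i]]
    if (length(lc) == 0 || length(ld) == 0) next
    md <- mean(ld)
    if (md == 0) stop("latency_shift_percent: zero mean latency in trial ",
                      i)
    ratios <- c(ratios, mean(lc) / md)
  }
  list(per_trial_ratio = ratios, n_trials = length(ratios),
       percent_change = (mean(ratios) - 1) * 100)
}

#' Seizure-severity summary by genotype
#'
#' Medians and IQRs of the 1-hour Racine score per genotype, with a
#' delegated exact two-sample rank test (Mann-Whitney) when both groups
#' have at least 2 animals. Racine scores are ordinal; no parametric
#' summary is offered.
#'
#' @param table a seizure cohort data.frame with columns `genotype` and
#'   `racine_1h`.
#' @param groups two genotype labels to compare; default the first two
#'   present.
#' @return list with `summary` (data.frame genotype, n, median, q1, q3)
#'   and `test` (list statistic, p, or flag when a group is too small).
#' @export
severity_summary <- function(table, groups = NULL) {
  stopifnot(all(c("genotype", "racine_1h") %in% names(table)))
  if (is.null(groups)) groups <- unique(table$genotype)[1:2]
  sub <- table[table$genotype %in% groups, ]
  sm <- do.call(rbind, lapply(split(sub$racine_1h, sub$genotype),
                              function(x) data.frame(
    n = length(x), median = stats::median(x),
    q1 = unname(stats::quantile(x, 0.25)),
    q3 = unname(stats::quantile(x, 0.75)))))
  sm <- cbind(genotype = rownames(sm), sm)
  rownames(sm) <- NULL
  xa <- sub$racine_1h[sub$genotype == groups[1]]
  xb <- sub$racine_1h[sub$genotype == groups[2]]
  test <- if (length(xa) < 2 || length(xb) < 2) {
    list(flag = "group_too_small")
  } else if (length(xa) + length(xb) <= 12) {
    # ordinal scores tie heavily; with ties wilcox.test falls back to a
    # normal approximation, so enumerate the exact permutation null of
    # the rank-sum for small cohorts
    pooled <- c(xa, xb)
    r <- rank(pooled)
    na <- length(xa)
    w_obs <- sum(r[seq_len(na)])
    combos <- utils::combn(length(pooled), na)
    w_all <- apply(combos, 2, function(i) sum(r[i]))
    mu <- mean(w_all)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    list(statistic = w_obs - na * (na + 1) / 2, p = p,
         method = "exact rank permutation")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(xa, xb))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "wilcox.test")
  }
  list(summary = sm, test = test)
}
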