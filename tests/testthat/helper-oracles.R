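# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Upper-tail hypergeometric p by exhaustive enumeration of all draws of
# size n from a universe of size N containing K marked elements.
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# Two-sided Fisher p by exhaustive enumeration of all column-1
# assignments (sum-of-small-p rule).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  assign_ <- utils::combn(N, k)
  row1 <- seq_len(m)
  avals <- apply(assign_, 2, function(s) sum(s %in% row1))
  tab <- table(factor(avals, levels = 0:min(k, m)))
  probs <- as.numeric(tab) / ncol(assign_)
  p_obs <- probs[a + 1]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Normalized betweenness by exhaustive simple-path enumeration on an
# adjacency matrix (undirected, <= 8 nodes).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { res[[length(res) + 1]] <<- path; return(invisible()) }
      for (w in which(adj[v, ] == 1))
        if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    res
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    for (v in setdiff(1:n, c(s, t))) {
      thru <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + thru / length(sp)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Hand-accumulated log-rank chi-square (no censoring handling beyond
# risk-set bookkeeping), independent of survival::survdiff.
oracle_logrank_chisq <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b) > 0
  grp <- rep(1:2, c(length(time_a), length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & grp == 1); n <- sum(at_risk)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Rank-based ROC AUC of a score against binary labels.
roc_auc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Match detected network events to planted frames within a tolerance.
match_events <- function(detected_start, detected_end, planted_frames,
                         tol_frames = 4) {
  hit_planted <- vapply(planted_frames, function(f)
    any(detected_start - tol_frames <= f & detected_end + tol_frames >= f),
    logical(1))
  hit_detected <- vapply(seq_along(detected_start), function(i)
    any(planted_frames >= detected_start[i] - tol_frames &
          planted_frames <= detected_end[i] + tol_frames), logical(1))
  list(sensitivity = if (length(planted_frames)) mean(hit_planted) else NA,
       spurious = if (length(detected_start)) mean(!hit_detected) else 0)
}
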