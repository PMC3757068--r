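# Independent oracles used across the suite.

# Brute-force oracle for penalty propagation through a Boolean
# gene-protein-reaction rule: enumerate every subset of genes treated as
# available; a subset satisfying the rule can carry the reaction at the
# cost of its worst (largest-penalty) member, and the reaction penalty
# is the cheapest satisfying subset. Independent of gpr_penalty().
oracle_gpr_penalty <- function(rule, penalties) {
  genes <- names(penalties)
  tree <- parse_gpr(rule)
  if (is.null(tree)) return(0)
  n <- length(genes)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    present <- genes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    active <- stats::setNames(genes %in% present, genes)
    if (eval_gpr(tree, active)) {
      cost <- if (length(present)) max(penalties[present]) else 0
      best <- min(best, cost)
    }
  }
  best
}

# Closed-form MCC from the four confusion-matrix counts.
oracle_mcc <- function(tp, tn, fp, fn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp)) / sqrt((tp + fn)) / sqrt((tn + fp)) / sqrt((tn + fn))
}

# Linear-interpolated empirical quantile, written out directly.
oracle_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Small helper: a solved branched fixture with its analytic truth.
solved_branched <- function(seed, n_mets = 5L) {
  fx <- make_fixture("branched", seed = seed, params = list(n_mets = n_mets))
  sol <- solve_fba(fx$model)
  list(fx = fx, sol = sol)
}
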