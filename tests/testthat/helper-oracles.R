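# Brute-force oracles, independent of the implementation paths they check.

# AUC as the pairwise-comparison probability over all (pos, neg) pairs.
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Youden cutoff by exhaustive sweep of observed thresholds via sens_spec_at.
youden_sweep <- function(scores, labels) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    ss <- sens_spec_at(scores, labels, t)
    ss$sensitivity + ss$specificity - 1
  }, numeric(1))
  list(cutoff = thr[which(j >= max(j) - 1e-15)][1], j = max(j))
}

# Hypergeometric 2x2 enumeration with explicit binomial-coefficient arithmetic.
fisher_enum <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(m, k)
  pr <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
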