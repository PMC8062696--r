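# Independent oracles used to check the implementation. These deliberately
# avoid the code paths they verify: Fisher p-values come from direct
# hypergeometric enumeration, threshold selection from a brute-force scan.

# two-sided Fisher exact p for a 2x2 table by summing hypergeometric point
# masses no larger than the observed one (relative slack as in the exact
# test's standard definition)
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 total
  n <- sum(tab[2, ])   # row-2 total
  k <- sum(tab[, 1])   # column-1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force purity-rule threshold: scan every observed control ratio
oracle_purity_threshold <- function(pc, nc, target, mode = "ge") {
  cand <- sort(unique(c(pc, nc)))
  for (t in cand) {
    npc <- sum(pc >= t)
    nnc <- sum(nc >= t)
    if (npc + nnc == 0) next
    pur <- npc / (npc + nnc)
    ok <- if (mode == "ge") pur >= target else pur > target
    if (ok) return(t)
  }
  NA_real_
}

# brute-force FPR-rule threshold: %NC/%PC at-or-above, smallest qualifying
oracle_fpr_threshold <- function(pc, nc, fpr) {
  cand <- sort(unique(c(pc, nc)))
  for (t in cand) {
    pc_rate <- sum(pc >= t) / length(pc)
    nc_rate <- sum(nc >= t) / length(nc)
    if (pc_rate <= 0) next
    ok <- if (fpr == 0) sum(nc >= t) == 0 else nc_rate / pc_rate <= fpr
    if (ok) return(t)
  }
  NA_real_
}

# build a fraction curve directly from PC/NC ratio vectors
curve_from_controls <- function(pc, nc) {
  ratios <- c(pc, nc)
  names(ratios) <- paste0("p", seq_along(ratios))
  cats <- setNames(c(rep("PC", length(pc)), rep("NC", length(nc))),
                   names(ratios))
  fraction_curve(ratios, cats)
}
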