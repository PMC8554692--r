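# Independent oracles, kept deliberately naive.

# two-sided Fisher p by full enumeration with binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  pr <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# Pearson statistic by direct observed-vs-expected summation
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# kinship degree by enumerating ancestor paths: every pair of ascending
# paths from a and from b that meet in exactly one shared individual (the
# common ancestor) contributes (1/2)^(la+lb) to the relatedness r
oracle_kinship_degree <- function(ped, a, b) {
  ascend <- function(x) {
    out <- list(x)
    for (p in c(ped$father[[x]], ped$mother[[x]])) {
      if (!is.na(p) && p %in% ped$members) {
        out <- c(out, lapply(ascend(p), function(path) c(x, path)))
      }
    }
    out
  }
  pa <- ascend(a); pb <- ascend(b)
  r <- 0
  for (p1 in pa) {
    for (p2 in pb) {
      anc <- p1[length(p1)]
      if (p2[length(p2)] == anc &&
            length(intersect(p1, p2)) == 1) {
        r <- r + 0.5^(length(p1) + length(p2) - 2)
      }
    }
  }
  if (r <= 0) NA_integer_ else as.integer(round(-log2(r)))
}
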