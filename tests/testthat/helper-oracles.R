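# Independent brute-force oracles used to check the implementation paths.
# These deliberately avoid the package's own code and R's convenience
# wrappers where the point is to verify a formula.

# direct-formula first-order statistics on a plain value list
oracle_histogram <- function(x, bins = 1024, range = c(0, 4000)) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  sdv <- if (n >= 2) sqrt(sum((x - mu)^2) / (n - 1)) else NA_real_

  # linear-interpolation percentile: h = (n-1)p + 1 on the sorted sample
  pctl <- function(p) {
    s <- sort(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }

  width <- (range[2] - range[1]) / bins
  counts <- integer(bins)
  for (v in x) {
    b <- floor((v - range[1]) / width) + 1
    if (b < 1) b <- 1
    if (b > bins) b <- bins
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / n
  list(
    ADCmean = mu,
    ADCsd = sdv,
    ADCmd = pctl(0.5),
    ADC5p = pctl(0.05),
    ADC95p = pctl(0.95),
    ADCsk = if (n >= 3 && m2 > 0) m3 / m2^1.5 else NA_real_,
    ADCkurt = if (n >= 4 && m2 > 0) m4 / m2^2 - 3 else NA_real_,
    ADCentr = -sum(p * log2(p))
  )
}

# two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_permutation <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(idx) {
    g1 <- pooled[idx]
    g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  centre <- n1 * (length(pooled) - n1) / 2
  assignments <- utils::combn(length(pooled), n1)
  us <- apply(assignments, 2, u_stat)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# AUC by brute-force concordant-pair counting with half credit for ties
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (p in sp) for (q in sn)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(sp) * length(sn))
}

# digitised ellipsoid volume by voxel-centre enumeration
oracle_ellipsoid_voxels <- function(center, radii, dim, spacing) {
  count <- 0L
  for (k in seq_len(dim[3])) for (j in seq_len(dim[2])) for (i in seq_len(dim[1])) {
    x <- (i - 0.5) * spacing[1]
    y <- (j - 0.5) * spacing[2]
    z <- (k - 0.5) * spacing[3]
    if (((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
        ((z - center[3]) / radii[3])^2 <= 1)
      count <- count + 1L
  }
  count
}
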