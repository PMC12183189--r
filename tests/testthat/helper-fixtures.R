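# Shared fixtures built in code.

# Small two-group abundance matrix with optional missing cells.
toy_abundance <- function(values, treatments, regions) {
  samples <- data.frame(
    sample = sprintf("s%d", seq_len(ncol(values))),
    treatment = treatments,
    region = regions,
    replicate = stats::ave(seq_along(treatments),
                           paste(treatments, regions), FUN = seq_along),
    stringsAsFactors = FALSE)
  abundance_matrix(values, samples)
}

# Hand-rolled Welch statistic, Welch-Satterthwaite df and two-sided p,
# written from the textbook formulas (independent of stats::t.test).
welch_by_hand <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Exact hypergeometric upper tail by direct enumeration of binomial
# coefficients (independent of stats::phyper).
hyper_tail_enum <- function(N, m, n, k) {
  ks <- k:min(m, n)
  ks <- ks[ks >= max(0, n - (N - m))]
  if (!length(ks)) return(0)
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}

# Noiseless logistic velocity samples.
logistic_samples <- function(x, a1, a2, x0, p) {
  data.frame(position_mm = x,
             velocity_mm_per_h = a2 + (a1 - a2) / (1 + (x / x0)^p))
}
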