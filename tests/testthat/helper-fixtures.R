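# Small fixtures built in code; no files shipped.

tiny_config <- function(n_genes = 120, seed = 42, ...) {
  sim_config(n_genes = n_genes, band_size = 8, band_stable_frac = 0.5,
             frac_global_stable = 0.3, panel_genes = default_panel()[1:6, ],
             seed = seed, ...)
}

# minimal single-platform design for unit tests of the screen internals
two_group_matrix <- function(n_genes = 10, n = 4, delta = 0, sigma = 0.1,
                             seed = 1) {
  set.seed(seed)
  vals <- cbind(matrix(rnorm(n_genes * n, 8, sigma), n_genes),
                matrix(rnorm(n_genes * n, 8 + delta, sigma), n_genes))
  dimnames(vals) <- list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(2 * n)))
  expr_matrix(vals, "log2")
}

sheet_for <- function(x, platform = "P1", conditions) {
  data.frame(sample_id = colnames(x), platform = platform,
             condition = conditions,
             replicate = stats::ave(seq_len(ncol(x)), conditions, FUN = seq_along),
             stringsAsFactors = FALSE)
}

# permutation oracle for the Tukey-adjusted p of one pair: probability under
# group-label permutation that the studentized-range-style max|q| statistic
# exceeds the observed q of the pair of interest
perm_tukey_p <- function(values, groups, pair, B = 20000, seed = 99) {
  set.seed(seed)
  groups <- factor(groups)
  qstat <- function(v, g) {
    ns <- table(g)
    gm <- tapply(v, g, mean)
    msw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2))) / (length(v) - nlevels(g))
    pairs <- utils::combn(levels(g), 2, simplify = FALSE)
    qs <- vapply(pairs, function(cp)
      abs(gm[cp[1]] - gm[cp[2]]) / sqrt(msw / 2 * (1 / ns[cp[1]] + 1 / ns[cp[2]])),
      numeric(1))
    names(qs) <- vapply(pairs, paste, "", collapse = "-")
    qs
  }
  obs <- qstat(values, groups)[paste(sort(pair), collapse = "-")]
  hits <- 0
  for (b in seq_len(B)) {
    qs <- qstat(values, sample(groups))
    if (max(qs) >= obs) hits <- hits + 1
  }
  hits / B
}

# independent studentized-range CDF by direct numerical integration
# (range of k standard normals divided by sqrt(chi2_df/df))
sr_tail_numeric <- function(q, k, df) {
  p_range_le <- function(x) {
    if (x <= 0) return(0)
    k * stats::integrate(function(z)
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - x))^(k - 1),
      -Inf, Inf, rel.tol = 1e-10)$value
  }
  f_s <- function(s)
    exp(df / 2 * log(df) + (df - 1) * log(s) - df * s^2 / 2 -
        (df / 2 - 1) * log(2) - lgamma(df / 2))
  1 - stats::integrate(function(s) {
    vapply(s, function(si) f_s(si) * p_range_le(q * si), numeric(1))
  }, 0, Inf, rel.tol = 1e-8)$value
}
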