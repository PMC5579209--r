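test_that("signed fold change follows the +/- convention and is antisymmetric", {
  expect_equal(signed_fold_change(0), 1)
  expect_equal(signed_fold_change(c(1, -1)), c(2, -2))
  expect_equal(signed_fold_change(log2(1.1)), 1.1)
  d <- seq(-2, 2, by = 0.25)
  expect_equal(signed_fold_change(-d[d != 0]), -signed_fold_change(d[d != 0]))
  expect_true(all(abs(signed_fold_change(d)) >= 1))
  # |d| <= log2(1.1) iff fc in [-1.1, 1.1]
  expect_true(all((abs(d) <= log2(1.1)) == (abs(signed_fold_change(d)) <= 1.1)))
  expect_error(signed_fold_change(NaN), "finite")
})

test_that("anova_tukey matches aov/TukeyHSD and the studentized-range integral", {
  set.seed(20)
  v <- rnorm(12, rep(c(0, 0.4, 0.1), each = 4), 0.3)
  g <- rep(c("a", "b", "c"), each = 4)
  at <- anova_tukey(v, g)
  fit <- aov(v ~ factor(g))
  expect_equal(at$p_omnibus, summary(fit)[[1]][["Pr(>F)"]][1])
  tk <- TukeyHSD(fit)$`factor(g)`
  expect_equal(sort(at$pairs$p_adj), sort(unname(tk[, "p adj"])), tolerance = 1e-10)
  # independent oracle: numerical integration of the studentized range CDF
  ns <- table(g); k <- 3; df <- 9
  msw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2))) / df
  for (i in seq_len(nrow(at$pairs))) {
    cp <- c(at$pairs$test[i], at$pairs$reference[i])
    q <- abs(mean(v[g == cp[1]]) - mean(v[g == cp[2]])) / sqrt(msw / ns[[1]])
    expect_equal(at$pairs$p_adj[i], sr_tail_numeric(q, k, df), tolerance = 1e-6)
  }
})

test_that("identical groups give F = 0 and p_omnibus = 1", {
  at <- anova_tukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(at$p_omnibus, 1)
  expect_true(all(at$pairs$p_adj == 1))
  expect_error(anova_tukey(rep(1, 6), rep(c("a", "b"), each = 3)), "degenerate")
  expect_error(anova_tukey(1:4, c("a", "a", "a", "b")), ">= 2 values")
})

test_that("Tukey with two groups reduces to the pooled-variance t case", {
  set.seed(21)
  v <- rnorm(11, rep(c(0, 0.5), c(5, 6)), 0.4)
  g <- rep(c("a", "b"), c(5, 6))
  at <- anova_tukey(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(at$pairs$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(at$p_omnibus, tt$p.value, tolerance = 1e-9)
})

test_that("the vectorized screen agrees with per-gene anova_tukey", {
  d <- simulate_dataset(tiny_config(n_genes = 25, seed = 14))
  x <- d$matrices$PFC
  sh <- d$samples[d$samples$platform == "PFC", ]
  sc <- stability_screen(x, d$samples)
  conds <- unique(unlist(default_comparisons("PFC")))
  keep <- sh$condition %in% conds
  for (gid in rownames(x)[c(1, 10, 25)]) {
    at <- anova_tukey(unclass(x)[gid, sh$sample_id[keep]], sh$condition[keep])
    for (cn in sc$comparisons) {
      res <- sc$results[sc$results$gene_id == gid & sc$results$comparison == cn, ]
      cp <- strsplit(cn, " vs ")[[1]]
      row <- at$pairs[(at$pairs$test == cp[1] & at$pairs$reference == cp[2]) |
                      (at$pairs$test == cp[2] & at$pairs$reference == cp[1]), ]
      expect_equal(res$p_adj, row$p_adj, tolerance = 1e-9)
      expect_equal(abs(res$d), abs(row$diff), tolerance = 1e-12)
      expect_equal(res$p_omnibus, at$p_omnibus, tolerance = 1e-9)
    }
  }
})

test_that("stability bins and calls follow the two-notion rule", {
  cl <- classify_transcript(fc = c(1.0, 1.05, -1.35, 1.2, -1.1, 1.3),
                            p = c(0.9, 0.01, 0.001, 0.5, 0.9, 0.9))
  expect_equal(as.character(cl$bin),
               c("stable", "stable", "changed", "minimal", "stable", "changed"))
  expect_equal(cl$is_stable, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("platform stable sets are ANDs over comparisons and shrink monotonically", {
  d <- simulate_dataset(tiny_config(n_genes = 150, seed = 31))
  sc <- stability_screen(d$matrices$PFC, d$samples)
  sm <- sc$stable_matrix
  expect_setequal(sc$stable_set, rownames(sm)[rowSums(sm) == ncol(sm)])
  # gene stable in some but not all comparisons is excluded
  partial <- rownames(sm)[rowSums(sm) > 0 & rowSums(sm) < ncol(sm)]
  expect_true(all(!partial %in% sc$stable_set))
  # subsets of comparisons give supersets of genes
  s1 <- platform_stable_set(sc, sc$comparisons[1])
  s12 <- platform_stable_set(sc, sc$comparisons[1:2])
  expect_true(all(s12 %in% s1))
  expect_true(all(sc$stable_set %in% s12))
  expect_error(platform_stable_set(sc, "nope vs nothing"), "not evaluated")
  # enlarging the FC threshold never shrinks the stable set
  wide <- stability_screen(d$matrices$PFC, d$samples, fc_stable = 1.2)
  expect_true(all(sc$stable_set %in% wide$stable_set))
})

test_that("venn regions match brute-force membership enumeration", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "d", "e"))
  v <- intersect_stable_sets(sets)
  expect_setequal(v$intersection, "c")
  universe <- unique(unlist(sets))
  brute <- table(vapply(universe, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&"), ""))
  expect_equal(v$regions[sort(names(brute))],
               setNames(as.integer(brute[sort(names(brute))]), sort(names(brute))))
  expect_equal(sum(v$regions), length(universe))
  disj <- intersect_stable_sets(list(A = c("a"), B = c("b")))
  expect_length(disj$intersection, 0)
  two <- intersect_stable_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_setequal(two$intersection, c("b", "c"))
})

test_that("census bins partition the array and use the planted counts", {
  d <- simulate_dataset(sim_config(
    n_genes = 1000, gene_sd_range = c(0.01, 0.01), frac_global_stable = 0.99,
    responsive_effects = data.frame(effect = log2(1.6), weight = 1),
    panel_genes = default_panel()[0, ], band_size = 0, band_stable_frac = 0,
    seed = 8))
  expect_equal(sum(d$truth$effect_ug != 0), 10)
  sc <- stability_screen(d$matrices$TX, d$samples)
  cen <- stability_census(sc, "ug vs 1g_IF")
  expect_equal(sum(cen$counts), 1000)
  expect_equal(cen$counts[["changed"]], 10)
  expect_equal(cen$percent[["changed"]], 1.00)
  # all-stable degenerate case
  cen2 <- stability_census(sc, "1g_HW vs 1g_IF")
  expect_equal(cen2$counts[["stable"]], 1000)
  expect_equal(cen2$percent[["stable"]], 100.0)
})

test_that("swapping test and reference flips the fold change sign", {
  d <- simulate_dataset(tiny_config(n_genes = 30, seed = 44))
  fwd <- stability_screen(d$matrices$GBF, d$samples,
                          comparisons = list(c("sim_ug", "1g_GBF")))
  rev <- stability_screen(d$matrices$GBF, d$samples,
                          comparisons = list(c("1g_GBF", "sim_ug")))
  expect_equal(fwd$results$fc, -rev$results$fc, tolerance = 1e-12)
  expect_equal(fwd$results$p_adj, rev$results$p_adj, tolerance = 1e-12)
})
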