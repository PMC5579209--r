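# 4 candidates x 6 samples toy panel used across scorer tests
toy_panel <- function(seed = 2, n = 6) {
  set.seed(seed)
  x <- rbind(A = rnorm(n, 10, 0.05), B = rnorm(n, 12, 0.1),
             C = rnorm(n, 8, 0.2), D = rnorm(n, 11, 0.4))
  colnames(x) <- sprintf("s%d", seq_len(n))
  x
}

test_that("CV is the relative standard deviation in percent", {
  expect_equal(unname(coefficient_of_variation(c(1, 2, 3))), 50)
  expect_equal(unname(coefficient_of_variation(rep(4, 5))), 0)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  x <- toy_panel()
  expect_equal(coefficient_of_variation(x),
               apply(x, 1, function(v) 100 * sd(v) / mean(v)))
})

test_that("delta-Ct scores match brute-force pairwise SDs and are shift invariant", {
  x <- toy_panel()
  sc <- delta_ct_stability(x)
  brute <- sapply(rownames(x), function(i)
    mean(sapply(setdiff(rownames(x), i), function(j) sd(x[i, ] - x[j, ]))))
  expect_equal(sc, brute)
  expect_equal(delta_ct_stability(x + 3.7), sc, tolerance = 1e-12)
  # two genes offset by a constant score zero
  y <- rbind(A = c(1, 2, 3, 4), B = c(2, 3, 4, 5))
  expect_equal(unname(delta_ct_stability(y)), c(0, 0))
  expect_error(delta_ct_stability(x[1, , drop = FALSE]), ">= 2")
})

test_that("BestKeeper index statistics match hand computation", {
  x <- toy_panel(seed = 5, n = 5)
  bk <- bestkeeper_stats(x)
  index <- colMeans(x)
  expect_equal(bk$sd, unname(apply(x, 1, sd)))
  expect_equal(bk$r, unname(apply(x, 1, function(v) cor(v, index))))
  # two genes mirrored around a constant: the index is flat, r undefined
  m <- rbind(A = c(1, 2, 3), B = c(3, 2, 1))
  bkm <- bestkeeper_stats(m)
  expect_equal(bkm$r, c(NA_real_, NA_real_))  # index is constant
  # index (11/3, 3, 7/3) decreases linearly: genes rising with the samples
  # anti-correlate with it, the falling gene tracks it exactly
  m2 <- rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 5, 1))
  bkm2 <- bestkeeper_stats(m2)
  expect_equal(bkm2$r, c(-1, -1, 1), tolerance = 1e-9)
  # zero-variance gene: sd reported, r flagged not computable
  m3 <- rbind(A = c(1, 1, 1), B = c(1, 2, 3), C = c(2, 2.5, 4))
  bkm3 <- bestkeeper_stats(m3)
  expect_equal(bkm3$sd[1], 0)
  expect_false(bkm3$r_computable[1])
  expect_true(is.na(bkm3$r[1]))
  expect_error(bestkeeper_stats(toy_panel(n = 2)), ">= 3 samples")
})

test_that("geNorm M equals the delta-Ct score on the full panel", {
  x <- toy_panel(seed = 9)
  gn <- genorm_ranking(x)
  expect_equal(gn$m, delta_ct_stability(x), tolerance = 1e-12)
})

test_that("geNorm exclusion keeps a perfectly co-varying pair and ranks by M", {
  set.seed(3)
  base <- rnorm(8, 10, 0.3)
  x <- rbind(P1 = base, P2 = base + 1.5, N1 = rnorm(8, 9, 0.4),
             N2 = rnorm(8, 11, 0.5), N3 = rnorm(8, 10, 0.6))
  gn <- genorm_ranking(x)
  expect_setequal(names(gn$rank)[gn$rank == 1.5], c("P1", "P2"))
  expect_equal(sort(unname(gn$rank)), c(1.5, 1.5, 3, 4, 5))
  # permuting input order does not change M or the surviving pair
  perm <- x[c(4, 2, 5, 1, 3), ]
  gnp <- genorm_ranking(perm)
  expect_equal(gnp$m[names(gn$m)], gn$m, tolerance = 1e-12)
  expect_setequal(names(gnp$rank)[gnp$rank == 1.5], c("P1", "P2"))
  expect_error(genorm_ranking(x[1:2, ]), ">= 3")
})

test_that("NormFinder ungrouped equals the SD of sample-centered values", {
  x <- toy_panel(seed = 7, n = 4)
  nf <- normfinder_stability(x)
  z <- sweep(x, 2, colMeans(x))
  expect_equal(nf, apply(z, 1, sd))
  # grouped: zero-noise, zero-deviation gene scores 0 only in the exact
  # degenerate construction; check monotonicity in within-group noise instead
  set.seed(8)
  g <- rep(c("a", "b"), each = 4)
  mk <- function(noise3) rbind(A = rnorm(8, 10, 0.05), B = rnorm(8, 10, 0.05),
                               C = rnorm(8, 10, noise3))
  s_small <- normfinder_stability(mk(0.05), g)["C"]
  set.seed(8)
  s_big <- normfinder_stability(mk(0.8), g)["C"]
  expect_gt(s_big, s_small)
  expect_error(normfinder_stability(mk(0.1), rep(c("a", "b"), c(7, 1))), ">= 2")
})

test_that("grouped NormFinder matches the explicit variance decomposition", {
  x <- toy_panel(seed = 12, n = 8)
  g <- rep(c("a", "b"), each = 4)
  nf <- normfinder_stability(x, g)
  z <- sweep(x, 2, colMeans(x))
  brute <- sapply(rownames(x), function(i) {
    m_ig <- tapply(z[i, ], g, mean)
    v_ig <- tapply(z[i, ], g, var)
    n_g <- table(g)
    d_ig <- m_ig - mean(m_ig)
    mean(abs(d_ig)) + mean(sqrt(v_ig / n_g))
  })
  expect_equal(nf, brute)
})

test_that("consensus is the geometric mean of the four ranks", {
  rk <- matrix(c(1, 2, 4, 8), 1, dimnames = list("g1", NULL))
  expect_equal(reffinder_consensus(rk)$consensus_score, 64^0.25)
  expect_equal(reffinder_consensus(matrix(1, 1, 4,
               dimnames = list("g", NULL)))$consensus_score, 1)
  # symmetric in the method order
  rk2 <- matrix(c(3, 1, 2, 5), 1, dimnames = list("g1", NULL))
  expect_equal(reffinder_consensus(rk2)$consensus_score,
               reffinder_consensus(rk2[, c(4, 2, 3, 1), drop = FALSE])$consensus_score)
  expect_error(reffinder_consensus(matrix(c(1, NA), 1)), "candidate sets")
})

test_that("global ranking averages platform consensus ranks geometrically", {
  cr <- matrix(c(1, 2, 2, 1, 4, 3), 2, dimnames = list(c("g1", "g2"), NULL))
  gl <- global_ranking(cr)
  expect_equal(gl$global_score[gl$gene_id == "g1"], (1 * 2 * 4)^(1/3))
  # all-tied platform leaves the ordering unchanged
  cr2 <- cbind(cr, c(1.5, 1.5))
  expect_equal(global_ranking(cr2)$gene_id, gl$gene_id)
  expect_error(global_ranking(matrix(c(1, NA), 1)), "missing")
})

test_that("a 10x noisier candidate is ranked last by all methods and the consensus", {
  pan <- data.frame(gene_id = sprintf("R%d", 1:6),
                    sd = c(rep(0.05, 5), 0.5),
                    effect = 0)
  d <- simulate_dataset(sim_config(n_genes = 50, panel_genes = pan,
                                   band_size = 0, band_stable_frac = 0,
                                   frac_global_stable = 0.5, seed = 17))
  rr <- rank_references(d$matrices, d$samples, pan$gene_id)
  for (pn in names(rr$tables)) {
    t <- rr$tables[[pn]]
    noisy <- t[t$gene_id == "R6", ]
    expect_equal(noisy$rank_dct, 6)
    expect_equal(noisy$rank_bk, 6)
    expect_equal(noisy$rank_gn, 6)
    expect_equal(noisy$rank_nf, 6)
    expect_equal(noisy$consensus_rank, 6)
  }
  expect_equal(rr$global$gene_id[6], "R6")
})

test_that("consensus is invariant under monotone transformation of raw scores", {
  x <- toy_panel(seed = 22)
  dct <- delta_ct_stability(x)
  expect_equal(rank(dct), rank(sqrt(dct)))
  expect_equal(rank(dct), rank(log(dct + 1)))
})

test_that("panel stability grid crosses screens with the planted truth", {
  # a zero-effect candidate can still be excluded by the alpha-driven false
  # positive rate of one of the 8 comparisons, so assert on the panel level
  pan <- data.frame(gene_id = c(sprintf("S%d", 1:10), "HOT"),
                    sd = 0.05,
                    effect = c(rep(0, 10), log2(1.4)))
  d <- simulate_dataset(sim_config(n_genes = 60, panel_genes = pan,
                                   band_size = 0, band_stable_frac = 0,
                                   frac_global_stable = 0.6, seed = 23))
  screens <- lapply(names(d$matrices), function(pn)
    stability_screen(d$matrices[[pn]], d$samples, platform = pn))
  names(screens) <- names(d$matrices)
  srg <- stable_reference_genes(screens, pan$gene_id)
  expect_gte(sum(sprintf("S%d", 1:10) %in% srg$stable_panel), 8)
  expect_false("HOT" %in% srg$stable_panel)
  hot_ug <- srg$grid[srg$grid$gene_id == "HOT", "TX: ug vs 1g_IF"]
  expect_equal(hot_ug, "altered")
  expect_error(stable_reference_genes(screens, "ABSENT"), "ABSENT")
  empty <- stable_reference_genes(screens, character(0))
  expect_length(empty$stable_panel, 0)
})
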