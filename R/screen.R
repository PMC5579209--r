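#' Signed fold change from a mean log2 difference
#'
#' Maps the mean log2 difference d (test minus reference) onto the signed
#' linear-scale fold-change convention used throughout gravity-platform
#' screening: `fc = 2^d` for d >= 0 and `-2^(-d)` for d < 0, so
#' `fc` lives in (-Inf, -1] U [+1, Inf) and `|d| <= log2(1.1)` is exactly
#' the stable band `-1.1 <= fc <= +1.1`.
#'
#' @param d Numeric vector of mean log2 differences.
#' @return Signed fold changes, same length as `d`.
#' @examples
#' signed_fold_change(c(0, 1, -1, log2(1.1)))
#' @export
signed_fold_change <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite", call. = FALSE)
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

#' One-way ANOVA with Tukey multiple comparisons for a single gene
#'
#' Replicate values of the platform's condition groups are compared by
#' one-way analysis of variance; pairwise contrasts are adjusted with Tukey's
#' honest significant difference (studentized-range distribution on the
#' pooled within-group variance), as implemented by [stats::aov()] and
#' [stats::TukeyHSD()].
#'
#' @param values Numeric vector of expression values for one gene.
#' @param groups Factor or character vector of condition labels, same length.
#' @param conf.level Confidence level of the Tukey intervals (default 0.95).
#' @return List with `p_omnibus` (ANOVA F-test p) and `pairs`, a data.frame
#'   with columns `test`, `reference`, `diff` and `p_adj` for every group
#'   pair.
#' @examples
#' set.seed(1)
#' anova_tukey(rnorm(9), rep(c("a", "b", "c"), each = 3))
#' @export
anova_tukey <- function(values, groups, conf.level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 values", call. = FALSE)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw <= 0)
    stop("degenerate input: zero within-group variance in every group", call. = FALSE)
  fit <- stats::aov(values ~ groups, data = data.frame(values = values, groups = groups))
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(test = vapply(nm, `[`, "", 1),
                      reference = vapply(nm, `[`, "", 2),
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(p_omnibus = an[["Pr(>F)"]][1], pairs = pairs)
}

# Vectorized one-way ANOVA + Tukey over all genes of one platform matrix.
# Zero within-group variance rows (possible only in noise-free synthetic
# data) are mapped to p = 1 when the compared means are equal and p = 0
# otherwise, so a no-noise, no-effect fixture screens as 100% stable.
.row_anova_tukey <- function(x, groups, pairs) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- as.integer(table(groups))
  names(ns) <- levels(groups)
  N <- sum(ns)
  gm <- vapply(levels(groups), function(g)
    rowMeans(x[, groups == g, drop = FALSE]), numeric(nrow(x)))
  gm <- matrix(gm, nrow = nrow(x), dimnames = list(rownames(x), levels(groups)))
  ssw_pg <- vapply(levels(groups), function(g) {
    xg <- x[, groups == g, drop = FALSE]
    rowSums((xg - rowMeans(xg))^2)
  }, numeric(nrow(x)))
  ssw <- rowSums(matrix(ssw_pg, nrow = nrow(x)))
  msw <- ssw / (N - k)
  grand <- as.vector(gm %*% ns) / N
  ssb <- as.vector(((gm - grand)^2) %*% ns)
  msb <- ssb / (k - 1)
  f <- ifelse(msw > 0, msb / msw, ifelse(ssb > 0, Inf, 0))
  p_omnibus <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  p_omnibus[!is.finite(f)] <- 0
  p_omnibus[msw == 0 & ssb == 0] <- 1
  res <- lapply(pairs, function(cp) {
    d <- gm[, cp[1]] - gm[, cp[2]]
    se <- sqrt(msw / 2 * (1 / ns[[cp[1]]] + 1 / ns[[cp[2]]]))
    q <- ifelse(se > 0, abs(d) / se, ifelse(abs(d) > 0, Inf, 0))
    p_adj <- stats::ptukey(q, k, N - k, lower.tail = FALSE)
    p_adj[se == 0 & abs(d) > 0] <- 0
    p_adj[se == 0 & abs(d) == 0] <- 1
    list(d = d, p_adj = p_adj)
  })
  list(p_omnibus = p_omnibus, pairs = res)
}

#' Classify transcripts into stability bins and stable calls
#'
#' Two notions are kept deliberately distinct. The fold-change *bin*
#' partitions all transcripts by magnitude alone: `stable` when
#' `|fc| <= fc_stable` (default 1.1), `changed` when `|fc| >= fc_changed`
#' (default 1.3), `minimal` in between — so bins always sum to 100% of the
#' array. The stable *call* additionally requires the comparison's p-value to
#' exceed `alpha`: `is_stable = |fc| <= fc_stable & p > alpha`. A transcript
#' with tiny fold change but small p is binned stable yet not called stable.
#'
#' @param fc Signed fold changes (see [signed_fold_change()]).
#' @param p Comparison p-values (Tukey-adjusted in the default screen).
#' @param fc_stable Stable fold-change threshold (boundary included).
#' @param fc_changed Changed fold-change threshold (boundary included).
#' @param alpha Significance level for the stability call (default 0.05).
#' @return data.frame with columns `bin` (factor stable/minimal/changed) and
#'   `is_stable`.
#' @export
classify_transcript <- function(fc, p, fc_stable = 1.1, fc_changed = 1.3,
                                alpha = 0.05) {
  afc <- abs(fc)
  eps <- 1e-12
  bin <- ifelse(afc <= fc_stable + eps, "stable",
         ifelse(afc >= fc_changed - eps, "changed", "minimal"))
  data.frame(bin = factor(bin, levels = c("stable", "minimal", "changed")),
             is_stable = afc <= fc_stable + eps & p > alpha)
}

#' Default group comparisons per platform
#'
#' Each altered-gravity group is compared against the platform's 1 g
#' reference: ground facilities compare clinorotation and 9 g centrifugation
#' to the 1 g control; parabolic flight compares microgravity, 1.8 g
#' hypergravity and the hardware ground control to the 1 g in-flight control;
#' the rocket compares microgravity, launch baseline and hardware control to
#' the 1 g in-flight centrifuge.
#'
#' @param platform One of `"PFC"`, `"TX"`, `"GBF"`.
#' @return List of `c(test, reference)` pairs.
#' @export
default_comparisons <- function(platform) {
  switch(platform,
    PFC = list(c("ug", "1g_IF"), c("1.8g", "1g_IF"), c("1g_HW", "1g_IF")),
    TX  = list(c("ug", "1g_IF"), c("BL", "1g_IF"), c("1g_HW", "1g_IF")),
    GBF = list(c("sim_ug", "1g_GBF"), c("9g", "1g_GBF")),
    stop(sprintf("no default comparisons for platform '%s'; supply them explicitly",
                 platform), call. = FALSE))
}

#' Run the stability screen on one platform
#'
#' For every gene and every requested group comparison the screen computes
#' the mean log2 difference, the signed fold change, the omnibus one-way
#' ANOVA p-value across the platform's compared groups and the
#' Tukey-adjusted pairwise p-value, then classifies the transcript
#' (see [classify_transcript()]). A gene is platform-stable when it is
#' called stable in *every* comparison.
#'
#' @param x Log2-scale [expr_matrix()] of one platform (normalize first).
#' @param samples Sample sheet covering the matrix columns.
#' @param platform Platform name; defaults to the single platform present in
#'   `samples` for the matrix columns.
#' @param comparisons List of `c(test, reference)` pairs; defaults to
#'   [default_comparisons()] for the platform.
#' @param fc_stable,fc_changed,alpha Screen thresholds (defaults 1.1, 1.3,
#'   0.05).
#' @param p_type `"tukey"` (default) uses the Tukey-adjusted pairwise p for
#'   the stability call; `"pooled_t"` uses the unadjusted pooled-variance
#'   two-sample t p-value.
#' @return Object of class `"stability_screen"`: list with `platform`,
#'   `results` (long data.frame: gene_id, comparison, d, fc, p_omnibus,
#'   p_adj, bin, is_stable), `stable_matrix` (genes x comparisons logical),
#'   `stable_set` (gene ids stable in all comparisons), `comparisons`,
#'   `thresholds` and `n_genes`.
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 80, band_size = 10, seed = 3))
#' sc <- stability_screen(d$matrices$GBF, d$samples)
#' summary(sc)
#' @export
stability_screen <- function(x, samples, platform = NULL, comparisons = NULL,
                             fc_stable = 1.1, fc_changed = 1.3, alpha = 0.05,
                             p_type = c("tukey", "pooled_t")) {
  p_type <- match.arg(p_type)
  samples <- validate_sample_sheet(samples, matrix = x)
  samples <- samples[samples$sample_id %in% colnames(x), , drop = FALSE]
  if (is.null(platform)) {
    platform <- unique(samples$platform)
    if (length(platform) != 1)
      stop("matrix columns span multiple platforms; pass 'platform'", call. = FALSE)
  } else {
    samples <- samples[samples$platform == platform, , drop = FALSE]
  }
  if (is.null(comparisons)) comparisons <- default_comparisons(platform)
  conds <- unique(unlist(comparisons))
  missing <- setdiff(conds, samples$condition)
  if (length(missing) > 0)
    stop(sprintf("condition(s) absent from sample sheet: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  keep <- samples$condition %in% conds
  samples <- samples[keep, , drop = FALSE]
  if (any(table(samples$condition) < 2))
    stop("every compared condition needs >= 2 replicates", call. = FALSE)
  xm <- unclass(x)[, samples$sample_id, drop = FALSE]
  groups <- factor(samples$condition, levels = conds)

  av <- .row_anova_tukey(xm, groups, comparisons)
  cmp_names <- vapply(comparisons, function(cp) paste(cp[1], "vs", cp[2]), "")
  res <- vector("list", length(comparisons))
  for (i in seq_along(comparisons)) {
    d <- av$pairs[[i]]$d
    p_adj <- av$pairs[[i]]$p_adj
    p_use <- if (p_type == "tukey") p_adj else
      .row_pooled_t(xm, groups, comparisons[[i]])
    fc <- signed_fold_change(d)
    cl <- classify_transcript(fc, p_use, fc_stable, fc_changed, alpha)
    res[[i]] <- data.frame(gene_id = rownames(xm), comparison = cmp_names[i],
                           d = d, fc = fc, p_omnibus = av$p_omnibus,
                           p_adj = p_adj, bin = cl$bin, is_stable = cl$is_stable,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  stable_matrix <- vapply(res, `[[`, logical(nrow(xm)), "is_stable")
  stable_matrix <- matrix(stable_matrix, nrow = nrow(xm),
                          dimnames = list(rownames(xm), cmp_names))
  structure(list(platform = platform, results = results,
                 stable_matrix = stable_matrix,
                 stable_set = rownames(xm)[rowSums(stable_matrix) == length(comparisons)],
                 comparisons = cmp_names,
                 thresholds = c(fc_stable = fc_stable, fc_changed = fc_changed,
                                alpha = alpha),
                 p_type = p_type, n_genes = nrow(xm)),
            class = "stability_screen")
}

# unadjusted two-sided pooled-variance two-sample t, rowwise
.row_pooled_t <- function(x, groups, cp) {
  x1 <- x[, groups == cp[1], drop = FALSE]
  x2 <- x[, groups == cp[2], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  sp2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (rowMeans(x1) - rowMeans(x2)) / se, 0)
  p <- 2 * stats::pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & abs(rowMeans(x1) - rowMeans(x2)) > 0] <- 0
  p
}

#' @export
print.stability_screen <- function(x, ...) {
  cat(sprintf("Stability screen: platform %s, %d genes, %d comparisons (%s p)\n",
              x$platform, x$n_genes, length(x$comparisons), x$p_type))
  cat(sprintf("  thresholds: |FC| <= %.2f stable, |FC| >= %.2f changed, alpha %.2f\n",
              x$thresholds["fc_stable"], x$thresholds["fc_changed"],
              x$thresholds["alpha"]))
  cat(sprintf("  platform-stable genes: %d (%.1f%%)\n", length(x$stable_set),
              percent_of_array(length(x$stable_set), max(x$n_genes, 1))))
  invisible(x)
}

#' @export
summary.stability_screen <- function(object, ...) {
  cen <- lapply(object$comparisons, function(cn) stability_census(object, cn))
  names(cen) <- object$comparisons
  out <- list(platform = object$platform, census = cen,
              n_stable = length(object$stable_set), n_genes = object$n_genes,
              pct_stable = percent_of_array(length(object$stable_set),
                                            max(object$n_genes, 1)))
  class(out) <- "summary.stability_screen"
  out
}

#' @export
print.summary.stability_screen <- function(x, ...) {
  cat(sprintf("Platform %s: %d of %d genes stable in all comparisons (%.1f%%)\n",
              x$platform, x$n_stable, x$n_genes, x$pct_stable))
  for (cn in names(x$census)) {
    cc <- x$census[[cn]]
    cat(sprintf("  %s: stable %d (%.1f%%), minimal %d (%.1f%%), changed %d (%.2f%%)\n",
                cn, cc$counts["stable"], cc$percent["stable"],
                cc$counts["minimal"], cc$percent["minimal"],
                cc$counts["changed"], cc$percent["changed"]))
  }
  invisible(x)
}

#' Platform stable set
#'
#' Genes called stable in every listed comparison of the platform. Adding a
#' comparison can only shrink this set.
#'
#' @param screen A [stability_screen()] object.
#' @param comparisons Optional subset of comparison names to intersect over
#'   (default: all of them).
#' @return Character vector of gene ids.
#' @export
platform_stable_set <- function(screen, comparisons = NULL) {
  sm <- screen$stable_matrix
  if (is.null(comparisons)) comparisons <- colnames(sm)
  missing <- setdiff(comparisons, colnames(sm))
  if (length(missing) > 0)
    stop(sprintf("comparison(s) not evaluated: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  rownames(sm)[rowSums(sm[, comparisons, drop = FALSE]) == length(comparisons)]
}

#' Intersect named gene sets with Venn region counts
#'
#' @param sets Named list (length >= 2) of character vectors of gene ids.
#' @return List of class `"venn_sets"` with `intersection` (ids common to all
#'   sets), `regions` (named counts for every non-empty membership pattern,
#'   names like `"PFC&TX"`) and `set_sizes`. Region counts sum to the size of
#'   the union.
#' @examples
#' intersect_stable_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
intersect_stable_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets)))
    stop("need a named list of >= 2 sets", call. = FALSE)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  regions <- table(pattern)
  structure(list(intersection = universe[rowSums(member) == length(sets)],
                 regions = as.integer(regions) |> stats::setNames(names(regions)),
                 set_sizes = lengths(sets)),
            class = "venn_sets")
}

#' @export
print.venn_sets <- function(x, ...) {
  cat(sprintf("Gene-set intersection over %d sets (%s)\n",
              length(x$set_sizes), paste(names(x$set_sizes), collapse = ", ")))
  cat(sprintf("  common to all: %d genes\n", length(x$intersection)))
  for (nm in names(x$regions)) cat(sprintf("  region %s: %d\n", nm, x$regions[[nm]]))
  invisible(x)
}

#' Fold-change bin census for one comparison
#'
#' Counts and percentages of transcripts per fold-change bin (stable /
#' minimal / changed, partitioned by |FC| alone so the bins always sum to the
#' transcript total). Percentages are reported at 1 decimal for the stable
#' and minimal bins and 2 decimals for the changed bin, via
#' [percent_of_array()].
#'
#' @param screen A [stability_screen()] object.
#' @param comparison Comparison name (e.g. `"ug vs 1g_IF"`); default first.
#' @param decimals Named vector of decimals per bin.
#' @return List with `comparison`, `counts`, `percent`, `total`.
#' @export
stability_census <- function(screen, comparison = NULL,
                             decimals = c(stable = 1, minimal = 1, changed = 2)) {
  if (is.null(comparison)) comparison <- screen$comparisons[1]
  res <- screen$results[screen$results$comparison == comparison, , drop = FALSE]
  if (nrow(res) == 0)
    stop(sprintf("comparison '%s' not found", comparison), call. = FALSE)
  counts <- table(res$bin)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  pct <- vapply(names(counts), function(b)
    percent_of_array(counts[[b]], total, decimals[[b]]), numeric(1))
  list(comparison = comparison, counts = counts, percent = pct, total = total)
}
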