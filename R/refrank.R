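#' Coefficient of variation per gene
#'
#' Relative standard deviation in percent: 100 times the sample SD divided by
#' the mean, computed over all samples of a platform. The conventional
#' reference-gene criterion is CV <= 25%. Computed on log2 intensities as
#' retrieved from the array console; set `linear = TRUE` to compute on
#' unlogged values instead.
#'
#' @param x Numeric matrix (genes x samples) or a single gene's vector.
#' @param linear If `TRUE`, values are exponentiated (2^x) first.
#' @return Named numeric vector of CV percentages.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
#' @export
coefficient_of_variation <- function(x, linear = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list("gene", NULL))
  if (ncol(x) < 2) stop("need >= 2 values per gene", call. = FALSE)
  if (linear) x <- 2^x
  m <- rowMeans(x)
  if (any(m == 0)) stop("zero mean; CV undefined", call. = FALSE)
  s <- apply(x, 1, stats::sd)
  stats::setNames(100 * s / m, rownames(x))
}

#' Comparative delta-Ct stability score
#'
#' For each candidate i, the mean over all other candidates j of the sample
#' SD of the pairwise log2 difference x_i - x_j. Lower is more stable. The
#' score is invariant to adding a constant to every value of every gene.
#'
#' @param x Numeric matrix of log2 values, candidates in rows (>= 2).
#' @return Named numeric vector of scores.
#' @export
delta_ct_stability <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 candidate genes", call. = FALSE)
  n <- nrow(x)
  sds <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sds[i, j] <- sds[j, i] <- stats::sd(x[i, ] - x[j, ])
  stats::setNames(rowSums(sds) / (n - 1), rownames(x))
}

#' BestKeeper descriptive statistics
#'
#' The BestKeeper index is the per-sample arithmetic mean of the candidates'
#' log2 values (the geometric mean on the linear scale). Each candidate is
#' described by the SD and CV of its log2 values and its Pearson correlation
#' with the index. A zero-variance candidate has undefined correlation: its
#' `r` is `NA` and flagged.
#'
#' @param x Numeric matrix of log2 values, candidates in rows (>= 2),
#'   >= 3 samples.
#' @return data.frame with columns `gene_id`, `sd`, `cv`, `r`,
#'   `r_computable`.
#' @export
bestkeeper_stats <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 candidate genes", call. = FALSE)
  if (ncol(x) < 3) stop("need >= 3 samples", call. = FALSE)
  index <- colMeans(x)
  sd_g <- apply(x, 1, stats::sd)
  cv_g <- coefficient_of_variation(x)
  r <- rep(NA_real_, nrow(x))
  computable <- sd_g > 0 & stats::sd(index) > 0
  r[computable] <- suppressWarnings(
    apply(x[computable, , drop = FALSE], 1, function(v) stats::cor(v, index)))
  computable <- computable & !is.na(r)
  data.frame(gene_id = rownames(x), sd = sd_g, cv = as.numeric(cv_g), r = r,
             r_computable = computable, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' geNorm expression-stability measure M with iterative exclusion
#'
#' M_i is the mean, over all other candidates j, of the SD of the pairwise
#' log2 ratio x_i - x_j (identical to the comparative delta-Ct score on the
#' full candidate set). The least stable gene (highest M) is removed and M is
#' recomputed until two genes remain; the surviving pair cannot be resolved
#' further and shares rank 1.5.
#'
#' @param x Numeric matrix of log2 values, candidates in rows (>= 3).
#' @return List with `m` (M on the full candidate set), `exclusion_order`
#'   (gene ids, least stable first) and `rank` (final ranking, surviving pair
#'   tied at 1.5).
#' @export
genorm_ranking <- function(x) {
  if (nrow(x) < 3) stop("geNorm needs >= 3 candidate genes", call. = FALSE)
  m_full <- delta_ct_stability(x)
  ids <- rownames(x)
  remaining <- ids
  excluded <- character(0)
  while (length(remaining) > 2) {
    m <- delta_ct_stability(x[remaining, , drop = FALSE])
    # deterministic tie-break: first id in input order among the maxima
    worst <- remaining[which.max(m)]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  rk <- stats::setNames(numeric(length(ids)), ids)
  rk[remaining] <- 1.5
  if (length(excluded) > 0)
    rk[excluded] <- seq(length(ids), 3)
  list(m = m_full, exclusion_order = excluded, rank = rk)
}

#' NormFinder stability value
#'
#' Candidates are centered per sample by the mean over all candidates
#' (z_i = x_i - sample mean). Ungrouped: s_i is the SD of z_i over samples.
#' Grouped: with groups g of size n_g, per gene compute the group means m_ig
#' and variances v_ig of z; the intergroup deviation is
#' d_ig = m_ig - mean_g(m_ig) and
#' s_i = mean_g |d_ig| + mean_g sqrt(v_ig / n_g), a transparent
#' (shrinkage-free) form of the published variance-decomposition model.
#'
#' @param x Numeric matrix of log2 values, candidates in rows (>= 3).
#' @param groups Optional condition labels per sample; every group needs
#'   >= 2 samples.
#' @return Named numeric vector of stability values (lower = more stable).
#' @export
normfinder_stability <- function(x, groups = NULL) {
  if (nrow(x) < 3) stop("NormFinder needs >= 3 candidate genes", call. = FALSE)
  z <- sweep(x, 2, colMeans(x))
  if (is.null(groups))
    return(stats::setNames(apply(z, 1, stats::sd), rownames(x)))
  groups <- factor(groups)
  if (length(groups) != ncol(x))
    stop("groups must label every sample", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs >= 2 samples", call. = FALSE)
  gl <- levels(groups)
  m_ig <- vapply(gl, function(g) rowMeans(z[, groups == g, drop = FALSE]),
                 numeric(nrow(x)))
  v_ig <- vapply(gl, function(g) apply(z[, groups == g, drop = FALSE], 1, stats::var),
                 numeric(nrow(x)))
  m_ig <- matrix(m_ig, nrow = nrow(x)); v_ig <- matrix(v_ig, nrow = nrow(x))
  n_g <- as.integer(table(groups))
  d_ig <- m_ig - rowMeans(m_ig)
  s <- rowMeans(abs(d_ig)) + rowMeans(sqrt(sweep(v_ig, 2, n_g, `/`)))
  stats::setNames(s, rownames(x))
}

#' Consensus ranking by geometric mean of method ranks
#'
#' The comprehensive ranking aggregates the four stability algorithms by the
#' geometric mean of a gene's four ranks; the lowest geometric mean is the
#' most stable candidate. Only ranks enter, so the consensus is invariant
#' under any strictly monotone transformation of a method's raw scores.
#'
#' @param ranks Numeric matrix, genes in rows, one column per method, same
#'   candidate set in every column (no missing entries).
#' @return data.frame with `gene_id`, `consensus_score` (geometric mean) and
#'   `consensus_rank` (mid-ranked ties).
#' @examples
#' reffinder_consensus(matrix(c(1, 2, 1, 4, 1, 8, 1, 16), 2,
#'                     dimnames = list(c("a", "b"), NULL)))
#' @export
reffinder_consensus <- function(ranks) {
  if (anyNA(ranks))
    stop("methods ranked different candidate sets (missing ranks)", call. = FALSE)
  score <- exp(rowMeans(log(ranks)))
  data.frame(gene_id = rownames(ranks), consensus_score = score,
             consensus_rank = rank(score), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Global ranking across platforms
#'
#' The geometric mean of a gene's per-platform consensus ranks, ordered
#' ascending. All platforms must rank the same candidate set.
#'
#' @param consensus_ranks Numeric matrix, genes x platforms, of consensus
#'   ranks.
#' @return data.frame with `gene_id`, `global_score`, `global_rank`, ordered
#'   most stable first.
#' @export
global_ranking <- function(consensus_ranks) {
  if (anyNA(consensus_ranks))
    stop("gene missing on a platform", call. = FALSE)
  score <- exp(rowMeans(log(consensus_ranks)))
  out <- data.frame(gene_id = rownames(consensus_ranks), global_score = score,
                    global_rank = rank(score), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$global_score, out$gene_id), , drop = FALSE]
}

#' Rank candidate reference genes per platform and globally
#'
#' Runs the five stability measures (CV%, comparative delta-Ct, BestKeeper,
#' geNorm, NormFinder) on the candidate panel of each platform, aggregates
#' the four algorithms (CV is reported but kept out of the consensus) by
#' geometric-mean consensus, and averages the per-platform consensus ranks
#' into a global ranking. BestKeeper candidates are ranked by SD.
#'
#' @param matrices Named list of log2 [expr_matrix()] objects, one per
#'   platform.
#' @param samples Sample sheet covering all matrices.
#' @param panel Character vector of candidate gene ids present in every
#'   matrix.
#' @param grouped If `TRUE` (default) NormFinder uses the platform's
#'   condition groups.
#' @return Object of class `"ref_rank"`: list with `tables` (one RankTable
#'   data.frame per platform), `global` (global ranking data.frame) and
#'   `panel`.
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 100, band_size = 10, seed = 5))
#' rr <- rank_references(d$matrices, d$samples, default_panel()$gene_id)
#' head(rr$global)
#' @export
rank_references <- function(matrices, samples, panel, grouped = TRUE) {
  if (length(panel) == 0)
    return(structure(list(tables = list(), global = data.frame(), panel = panel),
                     class = "ref_rank"))
  samples <- validate_sample_sheet(samples)
  tables <- list()
  cons <- matrix(NA_real_, nrow = length(panel), ncol = length(matrices),
                 dimnames = list(panel, names(matrices)))
  for (pn in names(matrices)) {
    x <- matrices[[pn]]
    missing <- setdiff(panel, rownames(x))
    if (length(missing) > 0)
      stop(sprintf("panel gene(s) absent from %s matrix: %s", pn,
                   paste(missing, collapse = ", ")), call. = FALSE)
    sh <- samples[samples$platform == pn & samples$sample_id %in% colnames(x), ]
    xp <- unclass(x)[panel, sh$sample_id, drop = FALSE]
    cv <- coefficient_of_variation(xp)
    dct <- delta_ct_stability(xp)
    bk <- bestkeeper_stats(xp)
    gn <- genorm_ranking(xp)
    nf <- normfinder_stability(xp, groups = if (grouped) sh$condition else NULL)
    rk <- cbind(dct = rank(dct), bk = rank(bk$sd), gn = gn$rank, nf = rank(nf))
    cc <- reffinder_consensus(rk)
    tables[[pn]] <- data.frame(
      gene_id = panel, cv_percent = as.numeric(cv), delta_ct = as.numeric(dct),
      bk_sd = bk$sd, bk_cv = bk$cv, bk_r = bk$r, genorm_m = as.numeric(gn$m),
      normfinder_s = as.numeric(nf), rank_cv = rank(cv), rank_dct = rk[, "dct"],
      rank_bk = rk[, "bk"], rank_gn = rk[, "gn"], rank_nf = rk[, "nf"],
      consensus_score = cc$consensus_score, consensus_rank = cc$consensus_rank,
      row.names = NULL, stringsAsFactors = FALSE)
    cons[, pn] <- cc$consensus_rank
  }
  structure(list(tables = tables, global = global_ranking(cons), panel = panel),
            class = "ref_rank")
}

#' @export
print.ref_rank <- function(x, ...) {
  cat(sprintf("Reference-gene ranking: %d candidates, %d platforms\n",
              length(x$panel), length(x$tables)))
  if (nrow(x$global) > 0) {
    cat("Top candidates (global geometric-mean rank):\n")
    print(utils::head(x$global, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.ref_rank <- function(object, ...) {
  cv_ok <- vapply(object$tables, function(t) all(t$cv_percent <= 25), logical(1))
  out <- list(global = object$global, cv_criterion_met = cv_ok)
  class(out) <- "summary.ref_rank"
  out
}

#' @export
print.summary.ref_rank <- function(x, ...) {
  cat("Platforms meeting the CV <= 25% reference criterion for all candidates:\n")
  print(x$cv_criterion_met)
  cat("Global ranking:\n")
  print(x$global, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ref_rank <- function(x, ...) {
  if (nrow(x$global) == 0) return(invisible(x))
  graphics::barplot(stats::setNames(x$global$global_score, x$global$gene_id),
                    las = 2, ylab = "geometric mean consensus rank",
                    main = "Reference-gene global ranking", ...)
  invisible(x)
}

#' Panel genes stable in every screened comparison
#'
#' Crosses the candidate panel with the stability screens of all platforms
#' and reports a gene-by-comparison grid of `stable` / `altered` calls plus
#' the subset of candidates stable everywhere.
#'
#' @param screens Named list of [stability_screen()] objects.
#' @param panel Character vector of candidate gene ids.
#' @return List with `grid` (data.frame gene x comparison, entries
#'   `"stable"`/`"altered"`) and `stable_panel` (ids stable in every
#'   comparison on every platform).
#' @export
stable_reference_genes <- function(screens, panel) {
  if (length(panel) == 0)
    return(list(grid = data.frame(), stable_panel = character(0)))
  cols <- list()
  for (pn in names(screens)) {
    sm <- screens[[pn]]$stable_matrix
    missing <- setdiff(panel, rownames(sm))
    if (length(missing) > 0)
      stop(sprintf("panel gene(s) absent from %s screen: %s", pn,
                   paste(missing, collapse = ", ")), call. = FALSE)
    for (cn in colnames(sm))
      cols[[paste(pn, cn, sep = ": ")]] <- ifelse(sm[panel, cn], "stable", "altered")
  }
  grid <- data.frame(gene_id = panel, cols, check.names = FALSE,
                     stringsAsFactors = FALSE)
  all_stable <- apply(grid[, -1, drop = FALSE], 1, function(r) all(r == "stable"))
  list(grid = grid, stable_panel = panel[all_stable])
}
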