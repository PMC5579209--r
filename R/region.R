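#' Upper hypergeometric tail probability
#'
#' P(X >= k) when drawing `n_band` genes without replacement from a universe
#' of `n_genome` genes containing `n_genome_stable` stable ones. A
#' significance extension to the fold-enrichment report (the enrichment
#' itself is descriptive); delegated to [stats::phyper()].
#'
#' @param n_band_stable Observed stable genes in the band (k).
#' @param n_band Genes in the band.
#' @param n_genome_stable Stable genes in the genome.
#' @param n_genome Genes in the genome.
#' @return Tail probability in \[0, 1\].
#' @examples
#' hypergeometric_tail(0, 3, 4, 10)  # 1
#' @export
hypergeometric_tail <- function(n_band_stable, n_band, n_genome_stable, n_genome) {
  if (n_band_stable < 0 || n_band < 0 || n_band_stable > n_band ||
      n_band > n_genome || n_genome_stable > n_genome ||
      n_band_stable > n_genome_stable)
    stop("inconsistent counts: band must be contained in the genome", call. = FALSE)
  stats::phyper(n_band_stable - 1, n_genome_stable, n_genome - n_genome_stable,
                n_band, lower.tail = FALSE)
}

#' Stability enrichment of a cytogenetic band
#'
#' Compares the stable-gene fraction inside one cytogenetic band (genes with
#' `annotated = TRUE` whose band label matches exactly) against the
#' genome-wide stable fraction. Fractions are reported at one decimal via
#' [percent_of_array()]; the fold enrichment is computed on the unrounded
#' fractions and additionally presented rounded to the nearest integer
#' ("n-fold").
#'
#' @param stable_set Character vector of stable gene ids.
#' @param annotation Gene annotation table (see [read_annotation()]).
#' @param band Band label, e.g. `"11p15.4"`.
#' @param n_genome Genome denominator; default all annotation rows.
#' @param n_genome_stable Genome stable count; default `length(stable_set)`.
#' @return List of class `"band_enrichment"` with `band`, `n_band`,
#'   `n_band_stable`, `band_percent`, `genome_percent`, `fold`,
#'   `fold_rounded`, `p_hyper`.
#' @examples
#' ann <- data.frame(gene_id = c("a", "b", "c", "d"), symbol = "",
#'                   chromosome = "11", band = c("11p15.4", "11p15.4", "11q1.1", "11q1.1"),
#'                   annotated = TRUE)
#' band_enrichment(c("a", "c"), ann, "11p15.4")
#' @export
band_enrichment <- function(stable_set, annotation, band,
                            n_genome = nrow(annotation),
                            n_genome_stable = length(stable_set)) {
  in_band <- annotation$annotated & annotation$band == band
  n_band <- sum(in_band)
  if (n_band == 0)
    stop(sprintf("band '%s' has no annotated genes", band), call. = FALSE)
  if (n_genome_stable <= 0 || n_genome <= 0)
    stop("genome stable fraction must be > 0", call. = FALSE)
  n_band_stable <- sum(annotation$gene_id[in_band] %in% stable_set)
  band_frac <- n_band_stable / n_band
  genome_frac <- n_genome_stable / n_genome
  fold <- band_frac / genome_frac
  structure(list(band = band, n_band = n_band, n_band_stable = n_band_stable,
                 band_percent = percent_of_array(n_band_stable, n_band, 1),
                 genome_percent = percent_of_array(n_genome_stable, n_genome, 1),
                 fold = fold, fold_rounded = round_half_up(fold, 0),
                 p_hyper = hypergeometric_tail(n_band_stable, n_band,
                                               min(n_genome_stable, n_genome),
                                               n_genome)),
            class = "band_enrichment")
}

#' @export
print.band_enrichment <- function(x, ...) {
  cat(sprintf("Band %s: %d of %d genes stable (%.1f%%) vs %.1f%% genome-wide\n",
              x$band, x$n_band_stable, x$n_band, x$band_percent, x$genome_percent))
  cat(sprintf("  enrichment: %.2f-fold (reported \"%d-fold\"), hypergeometric p = %.3g\n",
              x$fold, x$fold_rounded, x$p_hyper))
  invisible(x)
}
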