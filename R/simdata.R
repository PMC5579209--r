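#' Default platform design for the synthetic generator
#'
#' Three platforms emulating the experimental campaigns: parabolic flight
#' (`PFC`, 20 s microgravity; groups 1g in-flight, microgravity, 1.8 g
#' hypergravity baseline, 1 g hardware ground control; 6 replicates each),
#' suborbital ballistic rocket (`TX`, 5 min microgravity; 1g in-flight and
#' microgravity with 9 replicates, launch baseline, hardware control and cell
#' culture control with 7), and ground-based facilities (`GBF`; 1 g control,
#' clinorotation `sim_ug`, 9 g centrifuge and baseline, 6 replicates each).
#'
#' @return Named list of platform descriptors, each a list with elements
#'   `groups` (named integer vector of replicates per condition) and
#'   `reference` (the 1 g reference condition for fold changes).
#' @export
default_platforms <- function() {
  list(
    PFC = list(groups = c("1g_IF" = 6L, "ug" = 6L, "1.8g" = 6L, "1g_HW" = 6L),
               reference = "1g_IF"),
    TX  = list(groups = c("1g_IF" = 9L, "ug" = 9L, "BL" = 7L, "1g_HW" = 7L, "CCC" = 7L),
               reference = "1g_IF"),
    GBF = list(groups = c("1g_GBF" = 6L, "sim_ug" = 6L, "9g" = 6L, "BL_GBF" = 6L),
               reference = "1g_GBF")
  )
}

#' Default candidate reference-gene panel
#'
#' Twenty classic housekeeping candidates. `sd` overrides the per-gene log2
#' noise SD (tight for ribosomal/glycolytic genes, looser for stress-prone
#' ones); `effect` is a planted log2 microgravity response (non-zero entries
#' make the candidate fail the stability screen by construction).
#'
#' @return data.frame with columns `gene_id`, `sd`, `effect`.
#' @export
default_panel <- function() {
  data.frame(
    gene_id = c("ACTB", "GAPDH", "B2M", "HPRT1", "RPL13A", "TBP", "UBC",
                "YWHAZ", "PPIA", "HMBS", "SDHA", "TUBA1A", "ALB", "ABCA5",
                "PLA2G4A", "POLR2A", "GUSB", "HSP90AA1", "RPLP0", "B4GALT6"),
    sd = c(0.05, 0.04, 0.08, 0.06, 0.05, 0.10, 0.08,
           0.09, 0.07, 0.11, 0.10, 0.12, 0.20, 0.06,
           0.07, 0.09, 0.10, 0.15, 0.05, 0.12),
    effect = c(0, 0, 0, 0, 0, 0, 0,
               0, 0, 0, 0, log2(1.15), log2(1.4), 0,
               0, 0, 0, -log2(1.35), 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Default planted microgravity effect sizes
#'
#' Signed log2 effects assigned to responsive genes, bracketing both screen
#' thresholds: log2(1.05) sits inside the |FC| <= 1.1 stable band, log2(1.2)
#' between the 1.1 and 1.3 thresholds, log2(1.4) and log2(1.5) above the
#' changed threshold. Weights keep sub-threshold responders a small minority,
#' as expected of genuine biological responses near the detection limit.
#'
#' @return data.frame with columns `effect` (signed log2) and `weight`.
#' @export
default_effects <- function() {
  e <- c(log2(1.05), log2(1.2), log2(1.4), log2(1.5))
  w <- c(0.02, 0.28, 0.35, 0.35) / 2
  data.frame(effect = c(e, -e), weight = c(w, w))
}

#' Configuration for the synthetic multi-platform dataset
#'
#' Describes the simulated study: per-gene baseline log2 intensities drawn
#' uniformly from `baseline_mean_range`, additive Gaussian noise on the log2
#' scale with per-gene SD drawn from `gene_sd_range`, a fraction
#' `frac_global_stable` of genes with zero effect everywhere, the remainder
#' responsive in the microgravity conditions (`responsive_conditions`) with
#' effects drawn from `responsive_effects`, a candidate reference-gene panel
#' with per-gene SD/effect overrides, and one cytogenetic band whose
#' truly-stable fraction is planted exactly at `band_stable_frac` (by
#' construction, not sampling). `frac_global_stable` is the genome-wide
#' truly-stable fraction including the band, so the planted band fold
#' enrichment is `band_stable_frac / frac_global_stable`.
#'
#' @param n_genes Number of transcripts (default 5000, a scaled-down array).
#' @param platforms Platform descriptors as in [default_platforms()].
#' @param baseline_mean_range Interval for per-gene baseline log2 intensity.
#' @param gene_sd_range Interval for per-gene log2 noise SD.
#' @param frac_global_stable Genome-wide fraction of truly stable genes.
#' @param responsive_effects data.frame(effect, weight) of planted effects.
#' @param responsive_conditions Condition groups the effects attach to;
#'   reference/baseline groups always have zero effect by convention.
#' @param panel_genes data.frame(gene_id, sd, effect) reference candidates.
#' @param band_label Cytogenetic band string (default `"11p15.4"`).
#' @param band_size Number of genes annotated to the band.
#' @param band_stable_frac Truly-stable fraction inside the band.
#' @param seed Integer seed; one seed drives the whole generator.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000,
                       platforms = default_platforms(),
                       baseline_mean_range = c(4, 12),
                       gene_sd_range = c(0.1, 0.1),
                       frac_global_stable = 0.15,
                       responsive_effects = default_effects(),
                       responsive_conditions = c("ug", "sim_ug"),
                       panel_genes = default_panel(),
                       band_label = "11p15.4",
                       band_size = 201,
                       band_stable_frac = 0.45,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), platforms = platforms,
              baseline_mean_range = baseline_mean_range,
              gene_sd_range = gene_sd_range,
              frac_global_stable = frac_global_stable,
              responsive_effects = responsive_effects,
              responsive_conditions = responsive_conditions,
              panel_genes = panel_genes, band_label = band_label,
              band_size = as.integer(band_size),
              band_stable_frac = band_stable_frac, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  stop_field <- function(field, msg)
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)
  with(config, {
    if (is.na(n_genes) || n_genes < 0) stop_field("n_genes", "must be >= 0")
    if (!is.list(platforms) || length(platforms) < 1 || is.null(names(platforms)))
      stop_field("platforms", "must be a named list of platform descriptors")
    for (pn in names(platforms)) {
      p <- platforms[[pn]]
      if (length(p$groups) < 2)
        stop_field("platforms", sprintf("platform %s needs >= 2 condition groups", pn))
      if (any(p$groups < 2))
        stop_field("platforms", sprintf("platform %s needs >= 2 replicates per group", pn))
      if (!p$reference %in% names(p$groups))
        stop_field("platforms", sprintf("platform %s reference group not among its groups", pn))
    }
    if (length(baseline_mean_range) != 2 || diff(baseline_mean_range) < 0)
      stop_field("baseline_mean_range", "must be an increasing interval")
    if (length(gene_sd_range) != 2 || any(gene_sd_range < 0) || diff(gene_sd_range) < 0)
      stop_field("gene_sd_range", "SDs must be >= 0 and form an interval")
    if (frac_global_stable < 0 || frac_global_stable > 1)
      stop_field("frac_global_stable", "must be in [0, 1]")
    if (band_stable_frac < 0 || band_stable_frac > 1)
      stop_field("band_stable_frac", "must be in [0, 1]")
    if (band_size > n_genes) stop_field("band_size", "must be <= n_genes")
    if (nrow(panel_genes) > 0 && any(panel_genes$sd < 0))
      stop_field("panel_genes", "SD overrides must be >= 0")
    if (anyDuplicated(panel_genes$gene_id))
      stop_field("panel_genes", "duplicated candidate gene id")
    if (band_size + nrow(panel_genes) > n_genes)
      stop_field("band_size", "band plus panel exceed n_genes")
    if (round(band_size * band_stable_frac) > round(n_genes * frac_global_stable))
      stop_field("band_stable_frac",
                 "band stable genes exceed the genome-wide stable budget")
    if (nrow(responsive_effects) > 0 && any(responsive_effects$weight < 0))
      stop_field("responsive_effects", "weights must be >= 0")
  })
  config
}

#' Generate a synthetic multi-platform expression dataset
#'
#' Draws one log2 expression matrix per platform under the model
#' `x[g, sample in condition c] ~ Normal(mu_g + delta[g, c], sigma_g)`, where
#' `delta` is the gene's planted effect in the microgravity conditions and
#' zero elsewhere. Gene classes are planted by construction: exactly
#' `round(n_genes * frac_global_stable)` genes are truly stable (all effects
#' zero), of which `round(band_size * band_stable_frac)` sit in the
#' cytogenetic band; every other gene receives an effect drawn from
#' `responsive_effects`. The same seed reproduces the dataset bit for bit.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_dataset"` with elements `matrices` (named
#'   list of [expr_matrix()], log2 scale), `samples` (sample sheet),
#'   `annotation` (gene annotation), `truth` (per-gene class, planted
#'   microgravity effect, `truly_stable` flag and `band_member` flag),
#'   `truth_effects` (gene x platform.condition matrix of true log2 effects)
#'   and `config`.
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 60, band_size = 10, seed = 7))
#' names(d$matrices)
#' table(d$truth$class)
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  panel <- config$panel_genes
  np <- nrow(panel)

  ids <- character(0)
  if (n > 0)
    ids <- c(panel$gene_id,
             sprintf("G%05d", seq_len(n - np)))[seq_len(n)]

  # plant truth: stable budget genome-wide, band stable fraction exact
  n_stable <- round(n * config$frac_global_stable)
  n_band_stable <- round(config$band_size * config$band_stable_frac)
  nonpanel <- setdiff(seq_len(n), seq_len(np))
  band_idx <- if (config$band_size > 0) sort(sample(nonpanel, config$band_size)) else integer(0)
  band_stable <- if (n_band_stable > 0) sort(sample(band_idx, n_band_stable)) else integer(0)

  delta <- rep(NA_real_, n)
  delta[band_stable] <- 0
  delta[setdiff(band_idx, band_stable)] <- .draw_effects(
    length(band_idx) - length(band_stable), config$responsive_effects)
  panel_idx <- seq_len(np)
  delta[panel_idx] <- panel$effect
  free <- which(is.na(delta))
  stable_left <- n_stable - length(band_stable) - sum(panel$effect == 0)
  stable_left <- max(0, min(stable_left, length(free)))
  free_stable <- if (stable_left > 0) sample(free, stable_left) else integer(0)
  delta[free_stable] <- 0
  rest <- which(is.na(delta))
  delta[rest] <- .draw_effects(length(rest), config$responsive_effects)

  mu <- stats::runif(n, config$baseline_mean_range[1], config$baseline_mean_range[2])
  sigma <- stats::runif(n, config$gene_sd_range[1], config$gene_sd_range[2])
  sigma[panel_idx] <- panel$sd

  is_band <- seq_len(n) %in% band_idx
  cls <- ifelse(is_band, "band_member",
         ifelse(delta == 0, "global_stable",
         ifelse(abs(delta) >= log2(1.3), "responsive", "minimal")))

  # per platform.condition true-effect matrix (effects attach to conditions)
  pc <- unlist(lapply(names(config$platforms), function(pn)
    paste(pn, names(config$platforms[[pn]]$groups), sep = ".")))
  truth_eff <- matrix(0, nrow = n, ncol = length(pc), dimnames = list(ids, pc))
  for (col in pc) {
    cond <- sub("^[^.]*\\.", "", col)
    if (cond %in% config$responsive_conditions) truth_eff[, col] <- delta
  }

  matrices <- list(); sheet <- list()
  for (pn in names(config$platforms)) {
    p <- config$platforms[[pn]]
    cols <- unlist(lapply(names(p$groups), function(g)
      sprintf("%s_%s_r%d", pn, g, seq_len(p$groups[[g]]))))
    m <- matrix(NA_real_, nrow = n, ncol = length(cols), dimnames = list(ids, cols))
    off <- 0
    for (g in names(p$groups)) {
      k <- p$groups[[g]]
      d <- truth_eff[, paste(pn, g, sep = "."), drop = TRUE]
      if (n > 0)
        m[, off + seq_len(k)] <- mu + d + matrix(stats::rnorm(n * k, 0, sigma), n, k)
      sheet[[length(sheet) + 1]] <- data.frame(
        sample_id = cols[off + seq_len(k)], platform = pn, condition = g,
        replicate = seq_len(k), stringsAsFactors = FALSE)
      off <- off + k
    }
    matrices[[pn]] <- expr_matrix(m, scale = "log2")
  }
  samples <- do.call(rbind, sheet)

  annotation <- .simulate_annotation(ids, is_band, panel_idx, config$band_label)

  truth <- data.frame(gene_id = ids, class = cls, effect_ug = delta,
                      truly_stable = delta == 0, band_member = is_band,
                      stringsAsFactors = FALSE)

  structure(list(matrices = matrices, samples = samples,
                 annotation = annotation, truth = truth,
                 truth_effects = truth_eff, config = config),
            class = "sim_dataset")
}

.draw_effects <- function(k, effects) {
  if (k == 0) return(numeric(0))
  if (nrow(effects) == 0) return(rep(0, k))
  sample(effects$effect, k, replace = TRUE, prob = effects$weight)
}

.simulate_annotation <- function(ids, is_band, panel_idx, band_label) {
  n <- length(ids)
  chr_band <- sub("[pq].*$", "", band_label)
  chrom <- as.character(sample(c(1:22, "X"), n, replace = TRUE))
  arm <- sample(c("p", "q"), n, replace = TRUE)
  band <- sprintf("%s%s%d.%d", chrom, arm, sample(11:36, n, replace = TRUE) %/% 10,
                  sample(1:5, n, replace = TRUE))
  annotated <- stats::runif(n) < 0.9
  chrom[is_band] <- chr_band
  band[is_band] <- band_label
  annotated[is_band] <- TRUE
  symbol <- rep("", n)
  symbol[panel_idx] <- ids[panel_idx]
  data.frame(gene_id = ids, symbol = symbol, chromosome = chrom, band = band,
             annotated = annotated, stringsAsFactors = FALSE)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic gravity-platform dataset: %d genes, %d platforms, seed %d\n",
              x$config$n_genes, length(x$matrices), x$config$seed))
  for (pn in names(x$matrices))
    cat(sprintf("  %s: %d samples (%s)\n", pn, ncol(x$matrices[[pn]]),
                paste(sprintf("%s n=%d", names(x$config$platforms[[pn]]$groups),
                              x$config$platforms[[pn]]$groups), collapse = ", ")))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a synthetic dataset to plain-text fixture files
#'
#' Matrices become TSV (one per platform), the sample sheet CSV, annotation
#' and truth tables TSV. Files round-trip losslessly through the package
#' readers.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (pn in names(dataset$matrices)) {
    p <- file.path(dir, paste0(pn, ".tsv"))
    write_expression_matrix(dataset$matrices[[pn]], p)
    paths[paste0("matrix_", pn)] <- p
  }
  p <- file.path(dir, "samples.csv")
  utils::write.csv(dataset$samples, p, row.names = FALSE, quote = FALSE)
  paths["samples"] <- p
  p <- file.path(dir, "annotation.tsv")
  utils::write.table(dataset$annotation, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["annotation"] <- p
  p <- file.path(dir, "truth.tsv")
  utils::write.table(dataset$truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth"] <- p
  invisible(paths)
}
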