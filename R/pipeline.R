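#' Run the full stability pipeline
#'
#' Orchestrates the analysis stages: obtain data (synthetic generation from
#' a [sim_config()], or files named under `config$inputs`), quantile-
#' normalize each platform separately, run the stability screen per platform,
#' intersect stable sets across platforms, census the microgravity
#' comparisons, rank the candidate reference panel, and test the cytogenetic
#' band for stability enrichment. When ground truth is available (synthetic
#' data) recovery metrics are added. Writes per-stage TSV outputs and a
#' machine-readable `summary.json`; given the same configuration the summary
#' is byte-identical across runs.
#'
#' @param config A list (or path to a YAML file, read with the `yaml`
#'   package) with elements:
#'   \describe{
#'     \item{sim}{arguments to [sim_config()] (synthetic run), or}
#'     \item{inputs}{list with `matrices` (named paths), `samples`,
#'       `annotation` paths and `scale` of the matrices,}
#'     \item{screen}{optional `fc_stable`, `fc_changed`, `alpha`,
#'       `comparisons` (named list per platform),}
#'     \item{rank}{optional `panel` (gene ids),}
#'     \item{region}{optional `band`, `platforms` (platforms whose
#'       intersection feeds the enrichment, default `c("PFC", "TX")`),}
#'     \item{normalize}{apply per-platform quantile normalization before the
#'       screen (default `TRUE`; synthetic data carries no array-level
#'       technical shifts, so `FALSE` is appropriate there),}
#'     \item{seed}{integer seed for any randomness.}
#'   }
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return List of class `"gravistab_pipeline"` with elements `screens`,
#'   `venn`, `rank`, `enrichment`, `summary` (the summary written to JSON)
#'   and `dataset`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  log_stage <- function(fmt, ...) {
    message(sprintf("[gravistab] %s %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }

  # ---- stage: data --------------------------------------------------------
  truth <- NULL; annotation <- NULL; dataset <- NULL
  if (!is.null(config$sim)) {
    log_stage("simulating dataset")
    sim_args <- config$sim
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    dataset <- simulate_dataset(cfg)
    matrices <- dataset$matrices
    samples <- dataset$samples
    annotation <- dataset$annotation
    truth <- dataset$truth
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$samples))
      stop("configuration error: 'inputs$samples' (sample sheet path) is required",
           call. = FALSE)
    if (is.null(inp$matrices) || is.null(names(inp$matrices)))
      stop("configuration error: 'inputs$matrices' must be named per platform",
           call. = FALSE)
    scale <- if (is.null(inp$scale)) "log2" else inp$scale
    log_stage("reading %d matrices", length(inp$matrices))
    matrices <- lapply(inp$matrices, read_expression_matrix, scale = scale)
    if (scale == "linear") matrices <- lapply(matrices, log2_transform)
    samples <- read_sample_sheet(inp$samples)
    for (m in matrices) validate_sample_sheet(samples, m)
    if (!is.null(inp$annotation))
      annotation <- read_annotation(inp$annotation,
                                    gene_ids = rownames(matrices[[1]]))
  } else {
    stop("configuration error: provide either 'sim' or 'inputs'", call. = FALSE)
  }

  # ---- stage: normalize ---------------------------------------------------
  normalize <- if (is.null(config$normalize)) TRUE else isTRUE(config$normalize)
  if (normalize) {
    log_stage("quantile-normalizing %d platforms", length(matrices))
    matrices <- lapply(matrices, quantile_normalize)
  }

  # ---- stage: screen ------------------------------------------------------
  scfg <- config$screen
  fc_stable <- if (is.null(scfg$fc_stable)) 1.1 else scfg$fc_stable
  fc_changed <- if (is.null(scfg$fc_changed)) 1.3 else scfg$fc_changed
  alpha <- if (is.null(scfg$alpha)) 0.05 else scfg$alpha
  screens <- list()
  for (pn in names(matrices)) {
    log_stage("screening platform %s", pn)
    screens[[pn]] <- stability_screen(
      matrices[[pn]], samples, platform = pn,
      comparisons = scfg$comparisons[[pn]],
      fc_stable = fc_stable, fc_changed = fc_changed, alpha = alpha)
  }

  stable_sets <- lapply(screens, `[[`, "stable_set")
  venn <- if (length(stable_sets) >= 2) intersect_stable_sets(stable_sets) else NULL
  n_total <- screens[[1]]$n_genes

  census <- lapply(screens, function(sc) {
    ug <- grep("^(ug|sim_ug) ", sc$comparisons, value = TRUE)
    if (length(ug) == 0) ug <- sc$comparisons[1]
    stability_census(sc, ug[1])
  })

  # ---- stage: rank --------------------------------------------------------
  panel <- config$rank$panel
  if (is.null(panel) && !is.null(annotation))
    panel <- annotation$gene_id[nzchar(annotation$symbol)]
  ranking <- NULL; panel_grid <- NULL
  if (length(panel) > 0) {
    log_stage("ranking %d reference candidates", length(panel))
    ranking <- rank_references(matrices, samples, panel)
    panel_grid <- stable_reference_genes(screens, panel)
  }

  # ---- stage: region ------------------------------------------------------
  enr <- NULL
  band <- if (is.null(config$region$band)) "11p15.4" else config$region$band
  enr_platforms <- config$region$platforms
  if (is.null(enr_platforms))
    enr_platforms <- intersect(c("PFC", "TX"), names(screens))
  if (!is.null(annotation) && length(enr_platforms) >= 1 &&
      any(annotation$annotated & annotation$band == band)) {
    enr_set <- Reduce(intersect, stable_sets[enr_platforms])
    if (length(enr_set) > 0) {
      log_stage("band enrichment for %s over %s", band,
                paste(enr_platforms, collapse = "&"))
      enr <- band_enrichment(enr_set, annotation, band,
                             n_genome = n_total,
                             n_genome_stable = length(enr_set))
    }
  }

  # ---- summary ------------------------------------------------------------
  summary <- list(
    schema_version = "1.0",
    n_genes = n_total,
    thresholds = list(fc_stable = fc_stable, fc_changed = fc_changed,
                      alpha = alpha),
    platforms = lapply(screens, function(sc) list(
      comparisons = sc$comparisons,
      n_stable = length(sc$stable_set),
      pct_stable = percent_of_array(length(sc$stable_set), n_total, 1))),
    census = lapply(census, function(cc) list(
      comparison = cc$comparison,
      counts = as.list(cc$counts),
      percent = as.list(cc$percent))),
    intersections = if (!is.null(venn)) list(
      all_platforms = length(venn$intersection),
      pct_all_platforms = percent_of_array(length(venn$intersection), n_total, 1),
      regions = as.list(venn$regions)) else NULL,
    reference_ranking = if (!is.null(ranking)) list(
      top5 = utils::head(ranking$global$gene_id, 5),
      stable_panel = panel_grid$stable_panel) else NULL,
    band_enrichment = if (!is.null(enr)) list(
      band = enr$band, n_band = enr$n_band, n_band_stable = enr$n_band_stable,
      band_percent = enr$band_percent, genome_percent = enr$genome_percent,
      fold = round_half_up(enr$fold, 4), fold_rounded = enr$fold_rounded,
      p_hyper = enr$p_hyper) else NULL
  )
  if (!is.null(truth)) summary$recovery <- .recovery_metrics(screens, dataset)

  out <- structure(list(screens = screens, venn = venn, rank = ranking,
                        panel_grid = panel_grid, enrichment = enr,
                        summary = summary, dataset = dataset),
                   class = "gravistab_pipeline")
  if (!is.null(out_dir)) .write_pipeline_outputs(out, matrices, out_dir, log_stage)
  out
}

# sensitivity of the screen against planted truth, at the
# (gene, comparison) level; pinned measurement level for recovery tests
.recovery_metrics <- function(screens, dataset) {
  truth_eff <- dataset$truth_effects
  stable_num <- stable_den <- changed_num <- changed_den <- 0
  for (pn in names(screens)) {
    sc <- screens[[pn]]
    for (cn in sc$comparisons) {
      test_cond <- sub(" vs .*$", "", cn)
      col <- paste(pn, test_cond, sep = ".")
      true_d <- if (col %in% colnames(truth_eff)) truth_eff[, col] else
        stats::setNames(rep(0, nrow(truth_eff)), rownames(truth_eff))
      res <- sc$results[sc$results$comparison == cn, ]
      true_d <- true_d[res$gene_id]
      truly_stable <- dataset$truth$truly_stable[match(res$gene_id,
                                                       dataset$truth$gene_id)]
      stable_num <- stable_num + sum(res$is_stable & truly_stable)
      stable_den <- stable_den + sum(truly_stable)
      big <- abs(true_d) >= log2(1.5) - 1e-9
      changed_num <- changed_num + sum(res$bin == "changed" & big)
      changed_den <- changed_den + sum(big)
    }
  }
  list(stable_sensitivity = if (stable_den > 0) stable_num / stable_den else NA,
       changed_sensitivity = if (changed_den > 0) changed_num / changed_den else NA)
}

.write_pipeline_outputs <- function(out, matrices, out_dir, log_stage) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (pn in names(out$screens)) {
    sc <- out$screens[[pn]]
    utils::write.table(sc$results, file.path(out_dir, paste0(pn, "_screen.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sc$stable_set, file.path(out_dir, paste0(pn, "_stable_set.txt")))
  }
  if (!is.null(out$rank)) {
    for (pn in names(out$rank$tables))
      utils::write.table(out$rank$tables[[pn]],
                         file.path(out_dir, paste0(pn, "_rank_table.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$rank$global, file.path(out_dir, "global_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage("wrote outputs to %s", out_dir)
  invisible(out_dir)
}

#' @export
print.gravistab_pipeline <- function(x, ...) {
  cat("gravistab pipeline run\n")
  for (pn in names(x$screens)) print(x$screens[[pn]])
  if (!is.null(x$venn))
    cat(sprintf("Cross-platform stable intersection: %d genes\n",
                length(x$venn$intersection)))
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}
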