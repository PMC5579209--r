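#' Construct a validated expression matrix
#'
#' An expression matrix is a numeric genes-by-samples matrix of fluorescence
#' intensities with unique row (gene) and column (sample) names and a scale
#' tag recording whether the values are linear intensities or log2-transformed
#' intensities. All downstream statistics operate on the log2 scale.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene ids)
#'   and colnames (sample ids). No missing or non-finite entries are allowed.
#' @param scale Either `"linear"` or `"log2"`. Linear-scale values must be
#'   strictly positive.
#' @return The matrix with attribute `scale` set, classed `"expr_matrix"`.
#' @examples
#' m <- expr_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'                  scale = "linear")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("expression matrix must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (nrow(values) > 0) .check_unique(rownames(values), "gene id")
  if (ncol(values) > 0) .check_unique(colnames(values), "sample id")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  if (scale == "linear" && nrow(values) > 0 && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)
    stop(sprintf("linear-scale intensity must be > 0; offending gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  attr(values, "scale") <- scale
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "log2" else s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show <- unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE]
    print(show, ...)
    if (nrow(x) > 5) cat(sprintf("... %d more genes\n", nrow(x) - 5))
  }
  invisible(x)
}

.check_unique <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("missing or empty %s", what), call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop(sprintf("duplicated %s: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read and write expression matrices as TSV
#'
#' The on-disk format is tab-separated text: first column `gene_id`, remaining
#' columns one per sample. Readers validate rather than coerce: duplicated
#' ids, non-numeric cells and missing values are errors that name the
#' offending row/column, never silently imputed.
#'
#' @param path Path to a TSV file.
#' @param scale Scale of the stored values, `"log2"` (default) or `"linear"`.
#' @return `read_expression_matrix` returns an [expr_matrix()];
#'   `write_expression_matrix` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 1 || names(df)[1] != "gene_id")
    stop(sprintf("%s: first column must be 'gene_id'", path), call. = FALSE)
  ids <- df[[1]]
  .check_unique(names(df)[-1], "sample id")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 ncol = ncol(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (length(ids) > 0 && nrow(bad) > 0)
    stop(sprintf("%s: non-numeric or missing value at gene '%s', sample '%s'",
                 path, ids[bad[1, 1]], colnames(vals)[bad[1, 2]]), call. = FALSE)
  expr_matrix(num, scale = scale)
}

#' @rdname read_expression_matrix
#' @param x An [expr_matrix()] (or plain named numeric matrix).
#' @export
write_expression_matrix <- function(x, path) {
  vals <- format(unclass(x), digits = 15, trim = TRUE, scientific = FALSE)
  if (!is.matrix(vals))
    vals <- matrix(vals, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  df <- data.frame(gene_id = if (nrow(x) > 0) rownames(x) else character(0),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed to write matrix to %s: %s", path, conditionMessage(ok)),
         call. = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a CSV with header `sample_id,platform,condition,replicate`
#' mapping every array to its platform (e.g. `PFC`, `TX`, `GBF`), gravity
#' condition group (e.g. `ug`, `1g_IF`, `BL`, `sim_ug`, `9g`, `CCC`) and
#' replicate number.
#'
#' @param path Path to the CSV file.
#' @param matrix Optional expression matrix; if given, every matrix column must
#'   have exactly one sheet row (cross-validation).
#' @return A data.frame with columns `sample_id`, `platform`, `condition`,
#'   `replicate`.
#' @export
read_sample_sheet <- function(path, matrix = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, matrix)
}

#' @rdname read_sample_sheet
#' @param sheet A data.frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet, matrix = NULL) {
  need <- c("sample_id", "platform", "condition", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0)
    stop(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  .check_unique(sheet$sample_id, "sample id")
  rep <- suppressWarnings(as.integer(sheet$replicate))
  if (nrow(sheet) > 0 && (anyNA(rep) || any(rep < 1)))
    stop("replicate must be a positive integer for every sample", call. = FALSE)
  sheet$replicate <- rep
  if (!is.null(matrix)) {
    cols <- colnames(matrix)
    miss <- setdiff(cols, sheet$sample_id)
    if (length(miss) > 0)
      stop(sprintf("matrix sample(s) absent from sample sheet: %s",
                   paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  sheet[, need]
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id, symbol, chromosome, band, annotated`.
#' `band` is a cytogenetic band label such as `"11p15.4"` and must be empty or
#' begin with the chromosome name. Genes present in `gene_ids` but absent from
#' the table are appended with `annotated = FALSE` and a warning.
#'
#' @param path Path to the TSV file.
#' @param gene_ids Optional character vector of expected gene ids.
#' @return A data.frame with columns `gene_id`, `symbol`, `chromosome`,
#'   `band`, `annotated`.
#' @export
read_annotation <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("gene_id", "symbol", "chromosome", "band", "annotated")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("annotation missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  .check_unique(df$gene_id, "gene id")
  df$annotated <- as.logical(df$annotated)
  if (anyNA(df$annotated))
    stop("annotation column 'annotated' must be TRUE/FALSE", call. = FALSE)
  bad <- nzchar(df$band) & !startsWith(df$band, df$chromosome)
  if (any(bad))
    stop(sprintf("band does not match chromosome for gene '%s' ('%s' vs '%s')",
                 df$gene_id[which(bad)[1]], df$band[which(bad)[1]],
                 df$chromosome[which(bad)[1]]), call. = FALSE)
  if (!is.null(gene_ids)) {
    miss <- setdiff(gene_ids, df$gene_id)
    if (length(miss) > 0) {
      warning(sprintf("%d gene(s) absent from annotation; treated as unannotated",
                      length(miss)), call. = FALSE)
      df <- rbind(df[, need],
                  data.frame(gene_id = miss, symbol = "", chromosome = "",
                             band = "", annotated = FALSE,
                             stringsAsFactors = FALSE))
    }
  }
  df[, need]
}

#' Round a count to a percentage of the array, half-up
#'
#' All reported percentages in screen, census and enrichment outputs go
#' through this one rounding rule so tables agree with each other: the
#' fraction is expressed in percent and rounded half-up at the requested
#' number of decimals (e.g. 15441 of 67528 transcripts at 1 decimal is 22.9).
#'
#' @param count Number of genes in the category, `0 <= count <= total`.
#' @param total Denominator, usually the number of transcripts on the array.
#' @param decimals Decimal places to keep (default 1).
#' @return Numeric percentage.
#' @examples
#' percent_of_array(15441, 67528)        # 22.9
#' percent_of_array(279, 67528, 2)       # 0.41
#' @export
percent_of_array <- function(count, total, decimals = 1) {
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("count must satisfy 0 <= count <= total", call. = FALSE)
  round_half_up(100 * count / total, decimals)
}

#' @rdname percent_of_array
#' @param x Numeric vector to round.
#' @export
round_half_up <- function(x, decimals = 0) {
  p <- 10^decimals
  # nudge past binary representation error so exact halves round up
  floor(x * p + 0.5 + 1e-9) / p
}
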