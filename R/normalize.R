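#' Log2-transform a linear-scale expression matrix
#'
#' @param x An [expr_matrix()] on the linear scale (all values > 0).
#' @return The matrix with `value = log2(value)` and scale tag `"log2"`.
#' @examples
#' m <- expr_matrix(matrix(c(1, 1024), 1, 2,
#'                  dimnames = list("g1", c("s1", "s2"))), "linear")
#' log2_transform(m)   # 0 and 10
#' @export
log2_transform <- function(x) {
  if (expr_scale(x) == "log2")
    stop("matrix is already on the log2 scale", call. = FALSE)
  if (nrow(x) > 0 && any(x <= 0)) {
    bad <- which(unclass(x) <= 0, arr.ind = TRUE)
    stop(sprintf("non-positive intensity at gene '%s', sample '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]), call. = FALSE)
  }
  expr_matrix(log2(unclass(x)), scale = "log2")
}

#' Quantile-normalize a log2 expression matrix across samples
#'
#' Rank-wise replacement: within each sample the highest value is replaced by
#' the across-sample mean of the highest values, the second highest by the
#' mean of the second highest, and so on, equalizing every order statistic
#' across samples while preserving each sample's rank order. Ties within a
#' sample receive the mean of the reference values at the rank positions they
#' occupy (mid-rank convention). Normalization is applied within one platform
#' at a time, never pooled across platforms.
#'
#' The heavy lifting is delegated to [limma::normalizeQuantiles()].
#'
#' @param x An [expr_matrix()] on the log2 scale with at least two samples.
#' @return The normalized [expr_matrix()].
#' @export
quantile_normalize <- function(x) {
  if (expr_scale(x) != "log2")
    stop("quantile normalization expects log2-scale values; apply log2_transform first",
         call. = FALSE)
  if (ncol(x) < 2)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  out <- limma::normalizeQuantiles(unclass(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  expr_matrix(out, scale = "log2")
}
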