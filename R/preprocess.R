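#' Quantile-normalize a counts matrix
#'
#' Forces every sample (column) to share one reference distribution: the
#' vector of row-wise means of the column-sorted matrix.  Ties within a
#' column receive the mean of the reference values at their tied ranks
#' (the `limma` convention).  Each dataset is normalized independently;
#' no cross-dataset normalization is performed.
#'
#' @param x an [expr_matrix()] with `scale = "raw_counts"` (re-applying
#'   to an already normalized matrix is allowed and is a no-op) and at
#'   least two samples.
#' @return An [expr_matrix()] with `scale = "quantile_normalized"`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "log_transformed")
    stop("quantile normalization is applied before the log transform")
  if (ncol(x$values) < 2L)
    stop("quantile normalization needs >= 2 samples (reference distribution undefined)")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expr_matrix(v, x$dataset_label, scale = "quantile_normalized")
}

#' Log10(x + 1) transform
#'
#' The pseudocount keeps zero counts finite and maps them to 0; the
#' transform is strictly monotone, so downstream percentile group
#' membership is unchanged by it.
#'
#' @param x an [expr_matrix()] with non-negative values.
#' @return An [expr_matrix()] with `scale = "log_transformed"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (any(x$values < 0)) stop("log transform requires non-negative values")
  expr_matrix(log10(x$values + 1), x$dataset_label, scale = "log_transformed")
}

#' Principal component scores of samples
#'
#' PCA on gene-centered data (samples as observations, features as
#' variables), as used to inspect batch structure across cohorts.
#' Scores are deterministic up to per-component sign.
#'
#' @param x an [expr_matrix()] (typically log-transformed counts) or a
#'   PAL matrix.
#' @param k number of components, `<= min(samples - 1, features)`.
#' @return A `pca_scores` object: list with `sample_ids`, `scores`
#'   (samples x k), and `explained` (variance fractions, length k,
#'   non-increasing).
#' @export
pca_scores <- function(x, k = 2L) {
  stopifnot(inherits(x, "expr_matrix") || inherits(x, "pal_matrix"))
  v <- x$values
  kmax <- min(ncol(v) - 1L, nrow(v))
  if (k < 1L || k > kmax)
    stop("k must be in [1, ", kmax, "]")
  p <- prcomp(t(v), center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(sample_ids = colnames(v),
                 scores = p$x[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)]),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf("<pca_scores> %d samples x %d components; explained: %s\n",
              length(x$sample_ids), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}
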