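#' Case-to-normal expression ratios
#'
#' Normalizes each sample's profile on the per-gene geometric mean
#' across all samples of the dataset: `CNR(g, s) = value(g, s) /
#' geomean_s(value(g, .))`.  Input values must already be strictly
#' positive (quantile-normalized counts shifted by +1); genes with any
#' non-positive value are excluded with a message.
#'
#' @param x an [expr_matrix()] with strictly positive values.
#' @return A numeric genes x samples matrix of ratios.
#' @export
case_to_normal_ratio <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  ok <- apply(v > 0, 1L, all)
  if (any(!ok))
    message(sum(!ok), " gene(s) with non-positive values excluded from CNR")
  v <- v[ok, , drop = FALSE]
  if (nrow(v) == 0L) stop("no genes with strictly positive values")
  gm <- exp(rowMeans(log(v)))
  v / gm
}

#' Pathway activation levels
#'
#' The PAL of pathway p in sample s is the role-weighted mean of the
#' member genes' log10 case-to-normal ratios:
#' `PAL(p, s) = sum_g ARR(g, p) * log10 CNR(g, s) / sum_g |ARR(g, p)|`,
#' summing over members measured in the matrix.  Positive PAL means the
#' pathway is up-regulated in that sample relative to the dataset's
#' geometric-mean reference, negative means down-regulated.  Pathway
#' membership is first intersected with the measured gene universe;
#' pathways left with fewer than `min_genes` members are dropped with a
#' message.
#'
#' This signed normalized aggregation is this package's reconstruction
#' of the pathway-activation score family used in oncological
#' transcriptomics; it preserves the defining properties (sign tracks
#' up/down-regulation, geometric-mean reference per dataset, minimum
#' pathway size filter) without reproducing any proprietary weighting.
#'
#' @param cnr ratio matrix from [case_to_normal_ratio()].
#' @param pathways a [pathway_collection()].
#' @param min_genes minimum measured members per retained pathway
#'   (default 10).
#' @param dataset_label label attached to the result.
#' @return A `pal_matrix`: list with `values` (pathways x samples),
#'   `dataset_label`, `scale = "pal"`.
#' @export
pal_scores <- function(cnr, pathways, min_genes = 10L,
                       dataset_label = "dataset") {
  stopifnot(is.matrix(cnr), inherits(pathways, "pathway_collection"))
  lcnr <- log10(cnr)
  keep <- list()
  for (id in names(pathways)) {
    w <- pathways[[id]]
    w <- w[names(w) %in% rownames(lcnr)]
    if (length(w) >= min_genes && sum(abs(w)) > 0) keep[[id]] <- w
  }
  dropped <- length(pathways) - length(keep)
  if (dropped > 0L)
    message(dropped, " pathway(s) dropped below the ", min_genes,
            "-gene filter")
  if (length(keep) == 0L) stop("no pathways retained after the size filter")
  values <- matrix(NA_real_, nrow = length(keep), ncol = ncol(lcnr),
                   dimnames = list(names(keep), colnames(cnr)))
  for (i in seq_along(keep)) {
    w <- keep[[i]]
    values[i, ] <- colSums(w * lcnr[names(w), , drop = FALSE]) / sum(abs(w))
  }
  structure(list(values = values, dataset_label = dataset_label,
                 scale = "pal"),
            class = "pal_matrix")
}

#' @export
print.pal_matrix <- function(x, ...) {
  cat(sprintf("<pal_matrix> %s: %d pathways x %d samples\n",
              x$dataset_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.pal_matrix <- function(x) dim(x$values)

#' Survival screen at pathway level
#'
#' Identical contract to [screen_features()], applied to the rows of a
#' PAL matrix; results feed [select_differential()] and the consensus
#' stage unchanged.
#'
#' @param pal a `pal_matrix` from [pal_scores()].
#' @param surv a [survival_table()].
#' @param config a [screen_config()].
#' @return A `screen_result` data frame.
#' @export
screen_pathways <- function(pal, surv, config = screen_config()) {
  stopifnot(inherits(pal, "pal_matrix"))
  screen_features(pal, surv, config)
}
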