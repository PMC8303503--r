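#' Configuration for a synthetic multi-dataset survival study
#'
#' Describes a study of several independent expression datasets with the
#' statistical structure the screening pipeline assumes: negative
#' binomial counts with lognormal gene-level means, a per-dataset
#' multiplicative batch shift on the log scale (so datasets separate on
#' a PCA, as distinct cohorts and sequencing batches do), exponential
#' proportional-hazards survival driven by planted marker genes, and
#' uniform independent censoring.
#'
#' Defaults emulate a multi-cohort glioblastoma study: 4 datasets of
#' 2000 genes x 200 samples, half the gene universe shared by all
#' datasets, a baseline hazard of 0.05 events/month (about 20 months
#' mean survival) with censoring spread uniformly over 60 months of
#' follow-up (roughly two thirds of samples reach the event).
#'
#' @param n_datasets number of datasets (>= 1).
#' @param genes_per_dataset genes measured in each dataset.
#' @param samples_per_dataset integer vector (recycled to `n_datasets`).
#' @param shared_gene_fraction fraction of each dataset's genes drawn
#'   from the universe common to all datasets.
#' @param planted_markers `NULL`, or a data frame with columns
#'   `gene_id` (must be shared-universe ids when planted in several
#'   datasets), `beta` (log hazard ratio per SD of the gene's
#'   standardized log1p count) and `datasets` (`"all"` or a
#'   comma-separated list of dataset labels).
#' @param baseline_hazard events per month for a sample at the average
#'   expression of every planted marker.
#' @param censoring_time_max censoring times are Uniform(0, this) months.
#' @param batch_shift_sd SD of the per-dataset, per-gene normal shift
#'   added to log mean expression.
#' @param nb_dispersion negative binomial dispersion (variance = mu +
#'   dispersion * mu^2).
#' @param mean_log_expression_sd SD of gene-level log-normal mean
#'   expression (natural log scale).
#' @param seed integer seed; the whole study is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_datasets = 4L, genes_per_dataset = 2000L,
                             samples_per_dataset = 200L,
                             shared_gene_fraction = 0.5,
                             planted_markers = NULL,
                             baseline_hazard = 0.05,
                             censoring_time_max = 60,
                             batch_shift_sd = 0.5,
                             nb_dispersion = 0.3,
                             mean_log_expression_sd = 1.5,
                             seed = 1L) {
  stopifnot(n_datasets >= 1, genes_per_dataset >= 1,
            all(samples_per_dataset >= 1),
            shared_gene_fraction >= 0, shared_gene_fraction <= 1,
            baseline_hazard > 0, censoring_time_max > 0,
            batch_shift_sd >= 0, nb_dispersion > 0,
            mean_log_expression_sd >= 0)
  samples_per_dataset <- rep_len(as.integer(samples_per_dataset),
                                 n_datasets)
  if (!is.null(planted_markers)) {
    stopifnot(is.data.frame(planted_markers),
              all(c("gene_id", "beta") %in% names(planted_markers)))
    if (is.null(planted_markers$datasets)) planted_markers$datasets <- "all"
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 genes_per_dataset = as.integer(genes_per_dataset),
                 samples_per_dataset = samples_per_dataset,
                 shared_gene_fraction = shared_gene_fraction,
                 planted_markers = planted_markers,
                 baseline_hazard = baseline_hazard,
                 censoring_time_max = censoring_time_max,
                 batch_shift_sd = batch_shift_sd,
                 nb_dispersion = nb_dispersion,
                 mean_log_expression_sd = mean_log_expression_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Shorthand for planting one marker in every dataset
#'
#' @param gene_id a shared-universe gene id (`"GS0001"` style; shared
#'   ids are `GS` followed by a zero-padded index).
#' @param beta log hazard ratio per SD of standardized log1p count.
#' @return One-row data frame usable as `planted_markers`.
#' @export
plant_marker <- function(gene_id = "GS0001", beta = 1.0) {
  data.frame(gene_id = gene_id, beta = beta, datasets = "all",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-dataset study
#'
#' Counts are drawn gene-wise negative binomial around lognormal gene
#' means (shared genes keep one base mean across datasets so that a
#' consensus marker is the same biological signal everywhere), with a
#' per-dataset log-scale batch shift.  Survival follows an exponential
#' proportional-hazards model: sample i's hazard is `baseline_hazard *
#' exp(sum_planted beta * z_i)` where `z_i` is the sample's standardized
#' `log1p` count of the planted gene in its dataset; censoring is
#' Uniform(0, `censoring_time_max`) and independent.  PFS is generated
#' the same way from an independent draw with the time scale shortened
#' to 0.7x the OS scale.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_study`: list with `datasets` (per label: list
#'   of `counts` ([expr_matrix()]), `os`, `pfs` ([survival_table()]s))
#'   and `truth` (data frame of planted markers; zero rows when none).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_shared <- round(config$shared_gene_fraction * config$genes_per_dataset)
  shared_ids <- sprintf("GS%04d", seq_len(n_shared))
  labels <- sprintf("DS%d", seq_len(config$n_datasets))

  planted <- config$planted_markers
  if (!is.null(planted) && nrow(planted) > 0L) {
    planted_sets <- lapply(seq_len(nrow(planted)), function(i) {
      ds <- planted$datasets[i]
      if (identical(ds, "all")) labels
      else trimws(strsplit(ds, ",", fixed = TRUE)[[1L]])
    })
    if (!all(unlist(planted_sets) %in% labels))
      stop("planted marker refers to unknown dataset label")
    # shared ids are the only ids guaranteed to exist in every dataset
    # a marker may be planted in, so planting is restricted to them
    if (!all(planted$gene_id %in% shared_ids))
      stop("planted gene id outside the generated shared universe")
  } else {
    planted <- data.frame(gene_id = character(), beta = numeric(),
                          datasets = character(), stringsAsFactors = FALSE)
    planted_sets <- list()
  }

  set.seed(config$seed)
  base_meanlog <- rnorm(n_shared, log(100), config$mean_log_expression_sd)
  names(base_meanlog) <- shared_ids

  datasets <- list()
  for (d in seq_len(config$n_datasets)) {
    lbl <- labels[[d]]
    n_s <- config$samples_per_dataset[[d]]
    n_private <- config$genes_per_dataset - n_shared
    private_ids <- if (n_private > 0L)
      sprintf("%sG%04d", lbl, seq_len(n_private)) else character()
    gene_ids <- c(shared_ids, private_ids)
    meanlog <- c(base_meanlog,
                 rnorm(n_private, log(100), config$mean_log_expression_sd))
    shift <- rnorm(length(gene_ids), 0, config$batch_shift_sd)
    mu <- exp(meanlog + shift)
    counts <- matrix(rnbinom(length(gene_ids) * n_s,
                             mu = rep(mu, times = n_s),
                             size = 1 / config$nb_dispersion),
                     nrow = length(gene_ids), ncol = n_s)
    sample_ids <- sprintf("%s_S%03d", lbl, seq_len(n_s))
    dimnames(counts) <- list(gene_ids, sample_ids)

    # linear predictor from markers planted in this dataset
    lp <- numeric(n_s)
    if (nrow(planted) > 0L) {
      for (i in seq_len(nrow(planted))) {
        if (!(lbl %in% planted_sets[[i]])) next
        lv <- log1p(counts[planted$gene_id[i], ])
        s <- stats::sd(lv)
        z <- if (is.finite(s) && s > 0) (lv - mean(lv)) / s else numeric(n_s)
        lp <- lp + planted$beta[i] * z
      }
    }
    draw_endpoint <- function(rate_scale, endpoint) {
      t_event <- rexp(n_s, rate = config$baseline_hazard * rate_scale * exp(lp))
      t_cens <- runif(n_s, 0, config$censoring_time_max)
      time <- pmax(pmin(t_event, t_cens), 1e-6)
      survival_table(sample_ids, time, as.integer(t_event <= t_cens),
                     endpoint = endpoint)
    }
    os <- draw_endpoint(1, "OS")
    pfs <- draw_endpoint(1 / 0.7, "PFS")
    datasets[[lbl]] <- list(
      counts = expr_matrix(counts, dataset_label = lbl, scale = "raw_counts"),
      os = os, pfs = pfs)
  }
  structure(list(datasets = datasets, truth = planted, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d dataset(s), %d planted marker(s), seed %d\n",
              length(x$datasets), nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Null-screen calibration check
#'
#' For a study generated with no planted markers, the fraction of
#' screened features that pass the dual p-value filter; under the null
#' this should not exceed the nominal level (the dual criterion is
#' conservative relative to a single test at the same alpha).
#'
#' @param study a `synthetic_study` whose `truth` is empty.
#' @param results a `screen_result` (or list of them, one per dataset).
#' @param config a [screen_config()].
#' @return Fraction of screened (non-skipped) features with both
#'   p-values below `config$alpha`.
#' @export
null_fraction_check <- function(study, results, config = screen_config()) {
  stopifnot(inherits(study, "synthetic_study"))
  if (nrow(study$truth) > 0L)
    stop("null_fraction_check requires a study with no planted markers")
  if (inherits(results, "data.frame")) results <- list(results)
  if (length(results) == 0L) stop("no screen results supplied")
  pass <- 0L; total <- 0L
  for (r in results) {
    if (nrow(r) == 0L) stop("empty screen result")
    ok <- is.na(r$skip_reason)
    total <- total + sum(ok)
    pass <- pass + sum(ok & !is.na(r$wald_p) & !is.na(r$logrank_p) &
                         r$wald_p < config$alpha & r$logrank_p < config$alpha)
  }
  if (total == 0L) stop("no screened features")
  pass / total
}
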