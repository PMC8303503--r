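#' Pipeline run configuration
#'
#' @param datasets list of dataset specs: each a list with `label`,
#'   `counts` (TSV path) and optional `os` / `pfs` survival TSV paths.
#'   Endpoints missing for a dataset are simply skipped for it, so
#'   cohorts annotated with OS only participate in the OS consensus
#'   alone.
#' @param screen a [screen_config()].
#' @param consensus list with `iterations` and `seed` for the
#'   permutation intersection test.
#' @param pal `NULL`, or list with `pathways` (GMT path) and
#'   `min_genes` to add the pathway-activation branch.
#' @param enrichment `NULL`, or list with `terms` (GMT path) and `fdr`
#'   to enrich non-empty consensus gene sets.
#' @param out_dir output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(datasets, screen = screen_config(),
                       consensus = list(iterations = 1000L, seed = 1L),
                       pal = NULL, enrichment = NULL, out_dir = tempfile()) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  for (ds in datasets) {
    stopifnot(!is.null(ds$label), !is.null(ds$counts))
    if (!file.exists(ds$counts)) stop("counts file not found: ", ds$counts)
    for (ep in c("os", "pfs"))
      if (!is.null(ds[[ep]]) && !file.exists(ds[[ep]]))
        stop(toupper(ep), " survival file not found: ", ds[[ep]])
  }
  structure(list(datasets = datasets, screen = screen,
                 consensus = consensus, pal = pal,
                 enrichment = enrichment, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Thin front end over [run_config()]; the YAML mirrors its arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  sc <- do.call(screen_config, y$screen %||% list())
  run_config(datasets = y$datasets, screen = sc,
             consensus = y$consensus %||% list(iterations = 1000L, seed = 1L),
             pal = y$pal, enrichment = y$enrichment,
             out_dir = y$out_dir %||% tempfile())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(format(as.data.frame(df), digits = 15, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Per dataset: quantile normalization and log10 transform of the raw
#' counts, the per-gene survival screen for each available endpoint,
#' and plus/minus differential selection.  Across datasets (per
#' endpoint and direction): Venn-style intersection counts, the
#' all-dataset consensus intersection and its permutation p-value.
#' Optional branches: pathway activation levels screened the same way,
#' and hypergeometric enrichment of non-empty gene consensus sets
#' against a term GMT (background = the shared screened universe).
#' Every intermediate is written as TSV under `config$out_dir`, plus a
#' single JSON run report; reruns with identical inputs and seeds give
#' byte-identical TSVs.
#'
#' @param config a [run_config()].
#' @return The run report, invisibly (also written as
#'   `run_report.json`): per-dataset differential counts, intersection
#'   reports, consensus members, tool version and seeds.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$screen
  log_msg <- function(stage, lbl, ...)
    message(sprintf("[%s] [%s] %s", stage, lbl, paste0(...)))

  gene_results <- list(OS = list(), PFS = list())
  pal_results <- list(OS = list(), PFS = list())
  counts_cache <- list()

  for (ds in config$datasets) {
    lbl <- ds$label
    log_msg("preprocess", lbl, "reading and normalizing counts")
    mat <- tryCatch(read_counts_matrix(ds$counts, lbl),
                    error = function(e) stop("stage preprocess, dataset ",
                                             lbl, ": ", conditionMessage(e)))
    qn <- quantile_normalize(mat)
    lg <- log_transform(qn)
    counts_cache[[lbl]] <- qn
    for (ep in c("OS", "PFS")) {
      path <- ds[[tolower(ep)]]
      if (is.null(path)) {
        log_msg("screen", lbl, ep, " endpoint not provided; skipped")
        next
      }
      surv <- read_survival_table(path, endpoint = ep)
      res <- screen_features(lg, surv, sc)
      write_tsv(res, file.path(config$out_dir,
                               sprintf("%s_%s_screen.tsv", lbl, ep)))
      gene_results[[ep]][[lbl]] <- res
      log_msg("screen", lbl, ep, ": ", sum(is.na(res$skip_reason)),
              " features screened")
    }
  }

  pal_cache <- list()
  if (!is.null(config$pal)) {
    pathways <- read_gmt(config$pal$pathways)
    min_genes <- config$pal$min_genes %||% 10L
    for (ds in config$datasets) {
      lbl <- ds$label
      qn <- counts_cache[[lbl]]
      shifted <- expr_matrix(qn$values + 1, lbl, scale = "quantile_normalized")
      cnr <- case_to_normal_ratio(shifted)
      pal <- pal_scores(cnr, pathways, min_genes = min_genes,
                        dataset_label = lbl)
      pal_cache[[lbl]] <- pal
      write_tsv(data.frame(pathway_id = rownames(pal$values), pal$values,
                           check.names = FALSE),
                file.path(config$out_dir, sprintf("%s_pal.tsv", lbl)))
      for (ep in c("OS", "PFS")) {
        path <- ds[[tolower(ep)]]
        if (is.null(path)) next
        surv <- read_survival_table(path, endpoint = ep)
        res <- screen_pathways(pal, surv, sc)
        write_tsv(res, file.path(config$out_dir,
                                 sprintf("%s_%s_pal_screen.tsv", lbl, ep)))
        pal_results[[ep]][[lbl]] <- res
      }
    }
  }

  consensus_block <- function(results, tag) {
    out <- list()
    for (ep in names(results)) {
      rs <- results[[ep]]
      if (length(rs) < 2L) next
      fam <- family_from_results(rs, sc)
      for (dir in c("plus", "minus")) {
        vc <- venn_counts(fam, dir)
        write_tsv(vc, file.path(config$out_dir,
                                sprintf("%s_%s_%s_venn.tsv", tag, ep, dir)))
        rep <- permutation_intersection_p(
          fam, names(fam), dir,
          n_iterations = config$consensus$iterations %||% 1000L,
          seed = config$consensus$seed %||% 1L)
        out[[paste(ep, dir, sep = "_")]] <- rep
        log_msg("consensus", tag, ep, " ", dir, ": ", rep$observed_size,
                " common, p = ", format(rep$p_value, digits = 3))
      }
      out[[paste0(ep, "_family")]] <- fam
    }
    out
  }
  gene_consensus <- consensus_block(gene_results, "genes")
  pal_consensus <- if (length(pal_cache) > 0L)
    consensus_block(pal_results, "pal") else list()

  enrich_out <- list()
  if (!is.null(config$enrichment)) {
    terms <- read_gmt(config$enrichment$terms)
    fdr <- config$enrichment$fdr %||% 0.05
    for (key in names(gene_consensus)) {
      rep <- gene_consensus[[key]]
      if (!inherits(rep, "intersection_report") ||
          rep$observed_size == 0L) next
      fam <- gene_consensus[[paste0(sub("_(plus|minus)$", "", key),
                                    "_family")]]
      universe <- Reduce(intersect, lapply(fam, `[[`, "universe"))
      er <- hypergeometric_enrichment(rep$members, terms, universe)
      write_tsv(er, file.path(config$out_dir,
                              sprintf("enrichment_%s.tsv", key)))
      enrich_out[[key]] <- significant_terms(er, fdr)
      log_msg("enrich", key, nrow(enrich_out[[key]]),
              " term(s) below FDR ", fdr)
    }
  }

  diff_counts <- list()
  for (ep in names(gene_results))
    for (lbl in names(gene_results[[ep]])) {
      d <- select_differential(gene_results[[ep]][[lbl]], sc)
      diff_counts[[paste(lbl, ep, sep = "_")]] <-
        list(plus = length(d$plus), minus = length(d$minus))
    }

  report <- list(
    version = as.character(packageVersion("gbmscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    screen = unclass(sc),
    consensus_seed = config$consensus$seed %||% 1L,
    differential_counts = diff_counts,
    intersections = lapply(
      Filter(function(x) inherits(x, "intersection_report"), gene_consensus),
      function(r) list(datasets = r$datasets, direction = r$direction,
                       members = r$members, observed_size = r$observed_size,
                       p_value = r$p_value,
                       n_iterations = r$n_iterations)),
    pal_intersections = lapply(
      Filter(function(x) inherits(x, "intersection_report"), pal_consensus),
      function(r) list(observed_size = r$observed_size,
                       p_value = r$p_value)),
    enriched_terms = lapply(enrich_out, function(e) e$term_id))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Write a synthetic study to disk
#'
#' One counts TSV and one survival TSV per dataset and endpoint, plus a
#' JSON truth file — the file layout [run_config()] consumes.
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param dir output directory.
#' @return Named list of dataset specs suitable for [run_config()],
#'   invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list()
  for (lbl in names(study$datasets)) {
    d <- study$datasets[[lbl]]
    counts <- file.path(dir, paste0(lbl, "_counts.tsv"))
    os <- file.path(dir, paste0(lbl, "_os.tsv"))
    pfs <- file.path(dir, paste0(lbl, "_pfs.tsv"))
    write_counts_matrix(d$counts, counts)
    write_survival_table(d$os, os)
    write_survival_table(d$pfs, pfs)
    specs[[lbl]] <- list(label = lbl, counts = counts, os = os, pfs = pfs)
  }
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(specs)
}
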