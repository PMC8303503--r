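#' Construct a gene expression matrix object
#'
#' The basic expression container: a numeric genes x samples matrix with
#' unique row (gene) and column (sample) identifiers, a dataset label
#' used downstream to keep independent cohorts apart, and a scale tag
#' recording where the values sit in the preprocessing chain.
#'
#' @param values numeric matrix, genes in rows, samples in columns; row
#'   and column names are taken as gene and sample identifiers.
#' @param dataset_label single string naming the dataset (cohort/batch).
#' @param scale one of `"raw_counts"`, `"quantile_normalized"`,
#'   `"log_transformed"`, `"pal"`.
#' @return An object of class `expr_matrix` with elements `values`,
#'   `dataset_label` and `scale`.
#' @export
expr_matrix <- function(values, dataset_label,
                        scale = c("raw_counts", "quantile_normalized",
                                  "log_transformed", "pal")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values in expression matrix")
  if (scale == "raw_counts" && any(values < 0))
    stop("raw counts must be non-negative")
  if (!is.character(dataset_label) || length(dataset_label) != 1L)
    stop("'dataset_label' must be a single string")
  structure(list(values = values, dataset_label = dataset_label,
                 scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d features x %d samples [%s]\n",
              x$dataset_label, nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Construct a survival table
#'
#' Per-sample right-censored time-to-event records for one endpoint.
#' Times are in months and must be strictly positive; the event flag is
#' 1 for an observed event and 0 for censoring.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param time numeric vector of follow-up times (months, > 0).
#' @param event integer/numeric vector with values in {0, 1}.
#' @param endpoint `"OS"` (overall survival) or `"PFS"`
#'   (progression-free survival).
#' @return A `survival_table`: a data frame with columns `sample_id`,
#'   `time`, `event` and an `endpoint` attribute.
#' @export
survival_table <- function(sample_id, time, event, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifiers in survival table")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop("sample_id, time and event must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and strictly positive")
  if (!all(event %in% c(0, 1)))
    stop("event flags must be 0 (censored) or 1 (event)")
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  attr(out, "endpoint") <- endpoint
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Read a raw gene counts matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene
#' identifiers and whose header row holds sample identifiers; the body
#' must be numeric and non-negative.  Input row and column order is
#' preserved.
#'
#' @param path path to the TSV file.
#' @param dataset_label dataset label attached to the result.
#' @return An [expr_matrix()] with `scale = "raw_counts"`.
#' @export
read_counts_matrix <- function(path, dataset_label) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene column plus >= 1 sample")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing entries in counts body")
  rownames(m) <- gene_ids
  expr_matrix(m, dataset_label = dataset_label, scale = "raw_counts")
}

#' Write an expression matrix to TSV
#'
#' Full-precision text serialization; `read_counts_matrix()` of the
#' written file reproduces the values exactly (for raw counts).
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' The file must have columns `sample_id`, `time`, `event`.  Rows with a
#' missing time or event are dropped with a message reporting the count;
#' a non-positive time or an event flag outside {0, 1} is an error.
#'
#' @param path path to the TSV file.
#' @param endpoint endpoint label, `"OS"` or `"PFS"`.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival file must have columns: ", paste(need, collapse = ", "))
  keep <- !is.na(df$time) & !is.na(df$event)
  if (any(!keep))
    message(sum(!keep), " record(s) dropped for missing time/event")
  df <- df[keep, , drop = FALSE]
  survival_table(df$sample_id, df$time, df$event, endpoint = endpoint)
}

#' Write a survival table to TSV
#' @param x a [survival_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  stopifnot(inherits(x, "survival_table"))
  df <- as.data.frame(x)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pathway collection
#'
#' A collection of gene sets with signed member role weights (the
#' activator/repressor role, ARR): +1 marks an activator of the pathway,
#' -1 a repressor.  Plain gene sets (GO terms and the like) are the
#' special case where every weight is +1.
#'
#' @param members named list; each element a named numeric vector of
#'   role weights keyed by gene id, the element name being the
#'   pathway/term id.
#' @param names optional character vector of human-readable names,
#'   parallel to `members`.
#' @return A `pathway_collection` object.
#' @export
pathway_collection <- function(members, names = NULL) {
  if (!is.list(members) || is.null(base::names(members)))
    stop("'members' must be a named list of named numeric vectors")
  if (anyDuplicated(base::names(members)))
    stop("duplicate pathway identifiers")
  for (id in base::names(members)) {
    w <- members[[id]]
    if (length(w) < 1L || is.null(base::names(w)))
      stop("pathway ", id, " must have >= 1 named member")
    if (any(!is.finite(w)))
      stop("pathway ", id, " has non-finite role weights")
    if (all(w == 0))
      stop("pathway ", id, " has all-zero role weights")
  }
  if (is.null(names)) names <- base::names(members)
  structure(members, descriptions = as.character(names),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d set(s); sizes %s\n", length(x),
              paste(range(lengths(unclass(x))), collapse = "-")))
  invisible(x)
}

#' Read gene sets / pathways from a GMT file
#'
#' Standard GMT: one set per line, `id TAB description TAB member ...`.
#' As a local extension, a member may carry a `:+1` or `:-1` suffix
#' giving its signed role weight; unsuffixed members default to +1, so a
#' plain GMT parses as an all-activator collection.
#'
#' @param path path to the GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(pathway_collection(structure(list(), names = character())))
  members <- vector("list", length(lines))
  ids <- character(length(lines))
  descs <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i))
    ids[[i]] <- f[[1L]]
    descs[[i]] <- f[[2L]]
    mem <- f[-(1:2)]
    mem <- mem[nzchar(mem)]
    has_w <- grepl(":[+-]?[0-9.]+$", mem)
    w <- rep(1, length(mem))
    gene <- mem
    if (any(has_w)) {
      gene[has_w] <- sub(":[+-]?[0-9.]+$", "", mem[has_w])
      w[has_w] <- as.numeric(sub("^.*:", "", mem[has_w]))
    }
    members[[i]] <- setNames(w, gene)
  }
  names(members) <- ids
  pathway_collection(members, names = descs)
}

#' Write a pathway collection to GMT
#' @param x a [pathway_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "pathway_collection"))
  descs <- attr(x, "descriptions")
  lines <- vapply(seq_along(x), function(i) {
    w <- x[[i]]
    mem <- sprintf("%s:%+g", names(w), w)
    paste(c(names(x)[i], descs[i], mem), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a packaged fixture table
#'
#' Ships two small clinical tables transcribed from the source cohort's
#' published summary: `table1_clinical` (16 glioblastoma patients:
#' demographics, KPS, OS and time-to-progression in months, therapy and
#' marker annotations) and `table2_readstats` (14 RNA-seq libraries:
#' uniquely mapped and total reads in millions).  Missing clinical
#' values appear as `NA`; free-text columns are carried verbatim.
#'
#' @param name `"table1_clinical"` or `"table2_readstats"`.
#' @return A data frame of class `clinical_table` or `readstats_table`.
#' @export
load_fixture <- function(name = c("table1_clinical", "table2_readstats")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "gbmscreen",
                      mustWork = TRUE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = TRUE,
                   na.strings = c("/", "Not performed", "NA"),
                   stringsAsFactors = FALSE)
  if (name == "table1_clinical") {
    stopifnot(all(df$KPS >= 0 & df$KPS <= 100), all(df$age_at_diagnosis > 0))
    class(df) <- c("clinical_table", "data.frame")
  } else {
    stopifnot(all(df$uniquely_mapped <= df$total_reads),
              all(df$uniquely_mapped > 0))
    class(df) <- c("readstats_table", "data.frame")
  }
  df
}
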