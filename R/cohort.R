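#' Cohort summary statistics
#'
#' Demographic and endpoint summaries of a clinical table: patient
#' count, sex counts and percentages, age mean and range, KPS minimum
#' and median, and per-endpoint (OS / time-to-progression) counts,
#' means and ranges.  Endpoint analysis sets can be restricted by an
#' inclusive range of months, which makes the membership of the
#' summarized set explicit and auditable; missing endpoint values are
#' always excluded, never treated as zero.
#'
#' Full-precision values are retained in the returned object; the print
#' method reports to two decimals (half-even rounding).
#'
#' @param table a `clinical_table` (see [load_fixture()]).
#' @param os_range optional `c(lo, hi)` inclusive months restricting
#'   the OS analysis set.
#' @param pfs_range optional `c(lo, hi)` for time-to-progression.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(table, os_range = NULL, pfs_range = NULL) {
  stopifnot(inherits(table, "data.frame"), nrow(table) > 0L)
  in_range <- function(v, rng) {
    v <- v[!is.na(v)]
    if (!is.null(rng)) v <- v[v >= rng[1L] & v <= rng[2L]]
    v
  }
  os <- in_range(table$OS_months, os_range)
  pfs <- in_range(table$TTP_months, pfs_range)
  n <- nrow(table)
  n_male <- sum(table$sex == "M")
  n_female <- sum(table$sex == "F")
  stopifnot(n_male + n_female == n)
  out <- list(
    n_patients = n,
    n_male = n_male, pct_male = 100 * n_male / n,
    n_female = n_female, pct_female = 100 * n_female / n,
    age_mean = mean(table$age_at_diagnosis),
    age_min = min(table$age_at_diagnosis),
    age_max = max(table$age_at_diagnosis),
    kps_min = min(table$KPS), kps_median = median(table$KPS),
    os_n = length(os), os_mean = mean(os),
    os_min = min(os), os_max = max(os),
    pfs_n = length(pfs), pfs_mean = mean(pfs),
    pfs_min = min(pfs), pfs_max = max(pfs))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d M (%.2f%%), %d F (%.2f%%)\n",
              x$n_patients, x$n_male, x$pct_male, x$n_female, x$pct_female))
  cat(sprintf("Age: mean %.2f, range %g-%g; KPS: min %g, median %g\n",
              round(x$age_mean, 2), x$age_min, x$age_max,
              x$kps_min, x$kps_median))
  cat(sprintf("OS  (n = %d): mean %.1f months, range %g-%g\n",
              x$os_n, round(x$os_mean, 1), x$os_min, x$os_max))
  cat(sprintf("PFS (n = %d): mean %.1f months, range %g-%g\n",
              x$pfs_n, round(x$pfs_mean, 1), x$pfs_min, x$pfs_max))
  invisible(x)
}

#' Sequencing read statistics summary
#'
#' Arithmetic means and ranges of total and uniquely mapped reads
#' (millions) over all libraries.
#'
#' @param table a `readstats_table` (see [load_fixture()]).
#' @return List with `total_mean`, `total_min`, `total_max`,
#'   `mapped_mean`, `mapped_min`, `mapped_max` (full precision).
#' @export
summarize_readstats <- function(table) {
  stopifnot(inherits(table, "data.frame"), nrow(table) > 0L)
  list(total_mean = mean(table$total_reads),
       total_min = min(table$total_reads),
       total_max = max(table$total_reads),
       mapped_mean = mean(table$uniquely_mapped),
       mapped_min = min(table$uniquely_mapped),
       mapped_max = max(table$uniquely_mapped))
}
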