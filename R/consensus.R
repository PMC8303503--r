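#' Differential set family across datasets
#'
#' Bundles, per dataset, the universe of screened features and the
#' plus/minus differential sets selected from it.  Universes are kept
#' per dataset because cohorts measure different gene panels; random
#' draws in the permutation test are taken from each dataset's own
#' universe.
#'
#' @param sets named list (names = dataset labels); each element a list
#'   with `universe`, `plus`, `minus` character vectors.
#' @return A `set_family` object.
#' @export
set_family <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 1L)
  for (lbl in names(sets)) {
    s <- sets[[lbl]]
    if (!all(c("universe", "plus", "minus") %in% names(s)))
      stop("dataset ", lbl, " must have universe, plus and minus sets")
    if (anyDuplicated(s$universe) || anyDuplicated(s$plus) ||
        anyDuplicated(s$minus))
      stop("dataset ", lbl, ": duplicate feature ids in a set")
    if (!all(s$plus %in% s$universe) || !all(s$minus %in% s$universe))
      stop("dataset ", lbl, ": differential sets must be within the universe")
    if (length(intersect(s$plus, s$minus)) > 0L)
      stop("dataset ", lbl, ": plus and minus sets overlap")
  }
  structure(sets, class = "set_family")
}

#' Build a set family from screen results
#'
#' @param results named list of `screen_result` data frames (one per
#'   dataset, names = dataset labels).
#' @param config a [screen_config()].
#' @return A [set_family()]; each universe is the set of features that
#'   were actually screened (skipped features excluded).
#' @export
family_from_results <- function(results, config = screen_config()) {
  sets <- lapply(results, function(r) {
    d <- select_differential(r, config)
    list(universe = r$feature_id[is.na(r$skip_reason)],
         plus = d$plus, minus = d$minus)
  })
  set_family(sets)
}

#' Intersect differential sets across datasets
#'
#' @param family a [set_family()].
#' @param subset character vector of >= 2 dataset labels.
#' @param direction `"plus"` or `"minus"`.
#' @return Character vector: features differential in the chosen
#'   direction in every dataset of `subset`.
#' @export
intersect_sets <- function(family, subset, direction = c("plus", "minus")) {
  direction <- match.arg(direction)
  stopifnot(inherits(family, "set_family"), length(subset) >= 2L)
  missing <- setdiff(subset, names(family))
  if (length(missing) > 0L)
    stop("unknown dataset label(s): ", paste(missing, collapse = ", "))
  Reduce(intersect, lapply(family[subset], `[[`, direction))
}

#' Permutation test for an observed intersection size
#'
#' Each iteration draws, for every dataset in `subset`, a uniform random
#' subset of that dataset's universe with the same cardinality as its
#' observed differential set, intersects the draws, and records the
#' intersection size.  The p-value is the fraction of iterations whose
#' random size is equal to or higher than the observed size; it can
#' therefore be exactly 0 at finite iteration counts, and the report
#' also carries the (count + 1) / (n + 1) corrected value as
#' `p_value_corrected`.
#'
#' @inheritParams intersect_sets
#' @param n_iterations number of random intersections (default 1000).
#' @param seed optional integer seed; recorded in the report.
#' @return An `intersection_report`: list with `datasets`, `direction`,
#'   `members`, `observed_size`, `p_value`, `p_value_corrected`,
#'   `n_iterations`, `seed`.
#' @export
permutation_intersection_p <- function(family, subset,
                                       direction = c("plus", "minus"),
                                       n_iterations = 1000L, seed = NULL) {
  direction <- match.arg(direction)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  members <- intersect_sets(family, subset, direction)
  observed <- length(members)
  # integer-coded universes over the union, so each iteration is a
  # tabulation rather than string set algebra
  universes <- lapply(family[subset], `[[`, "universe")
  sizes <- vapply(family[subset],
                  function(s) length(s[[direction]]), integer(1))
  all_ids <- unique(unlist(universes, use.names = FALSE))
  codes <- lapply(universes, match, table = all_ids)
  k <- length(subset)
  n_union <- length(all_ids)
  rand_sizes <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      cnt <- integer(n_union)
      for (d in seq_len(k)) {
        draw <- codes[[d]][sample.int(length(codes[[d]]), sizes[[d]])]
        cnt[draw] <- cnt[draw] + 1L
      }
      sum(cnt == k)
    }, integer(1))
  })
  hits <- sum(rand_sizes >= observed)
  structure(list(datasets = subset, direction = direction,
                 members = members, observed_size = observed,
                 p_value = hits / n_iterations,
                 p_value_corrected = (hits + 1) / (n_iterations + 1),
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("<intersection_report> %s [%s]: %d common feature(s), p = %.4g (%d iterations)\n",
              paste(x$datasets, collapse = " & "), x$direction,
              x$observed_size, x$p_value, x$n_iterations))
  invisible(x)
}

#' Exact two-dataset intersection-size tail probability
#'
#' Closed-form counterpart of [permutation_intersection_p()] for two
#' datasets: random subsets of sizes `set_sizes` are drawn from
#' universes of sizes `universe_sizes` sharing `shared_universe_size`
#' features.  The number of shared features caught by each draw is
#' hypergeometric, and conditional on those counts the overlap is
#' hypergeometric again on the shared universe; the tail
#' `P(overlap >= observed)` is obtained by summing over both counts.
#'
#' @param universe_sizes integer vector of length 2.
#' @param set_sizes integer vector of length 2, each `<=` its universe.
#' @param shared_universe_size number of features common to both
#'   universes.
#' @param observed observed intersection size, `<= min(set_sizes)`.
#' @return `P(overlap >= observed)` as a number.
#' @export
exact_two_set_p <- function(universe_sizes, set_sizes, shared_universe_size,
                            observed) {
  stopifnot(length(universe_sizes) == 2L, length(set_sizes) == 2L,
            all(set_sizes <= universe_sizes),
            shared_universe_size <= min(universe_sizes))
  if (observed > min(set_sizes))
    stop("observed overlap cannot exceed the smaller set size")
  if (observed <= 0) return(1)
  m <- shared_universe_size
  total <- 0
  for (a in 0:min(m, set_sizes[1L])) {
    pa <- dhyper(a, m, universe_sizes[1L] - m, set_sizes[1L])
    if (pa == 0) next
    for (b in 0:min(m, set_sizes[2L])) {
      pb <- dhyper(b, m, universe_sizes[2L] - m, set_sizes[2L])
      if (pb == 0) next
      # overlap | a, b ~ Hypergeometric(m, a, b)
      tail <- phyper(observed - 1, a, m - a, b, lower.tail = FALSE)
      total <- total + pa * pb * tail
    }
  }
  min(total, 1)
}

#' Venn-style intersection counts over all dataset subsets
#'
#' For every subset of >= 2 datasets, the size of the plain intersection
#' of the chosen direction's differential sets, plus each dataset's own
#' set size.
#'
#' @inheritParams intersect_sets
#' @return Data frame with columns `datasets` (label string,
#'   `&`-joined), `n_datasets`, `size`.
#' @export
venn_counts <- function(family, direction = c("plus", "minus")) {
  direction <- match.arg(direction)
  labels <- names(family)
  rows <- list()
  for (k in seq_along(labels)) {
    for (combo in utils::combn(labels, k, simplify = FALSE)) {
      size <- if (k == 1L) length(family[[combo]][[direction]])
              else length(intersect_sets(family, combo, direction))
      rows[[length(rows) + 1L]] <- data.frame(
        datasets = paste(combo, collapse = "&"),
        n_datasets = k, size = size, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
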