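#' Hypergeometric over-representation analysis
#'
#' One-sided enrichment of a query feature set against term annotations:
#' per term, `p = P(overlap >= observed)` under a hypergeometric draw of
#' `|query|` features from the universe.  Term memberships are first
#' intersected with the universe, which should be the set of features
#' the screen could actually have selected (the shared screened
#' universe), not the whole genome.  BH-adjusted q-values are attached.
#'
#' @param query character vector of features, a subset of `universe`.
#' @param terms a [pathway_collection()] of term annotations (role
#'   weights are ignored; terms are flat sets here).
#' @param universe character vector: the background feature set.
#' @return Data frame of class `enrichment_result`: `term_id`,
#'   `term_name`, `term_size`, `query_size`, `overlap`, `p_value`,
#'   `q_value`, sorted by ascending p.
#' @export
hypergeometric_enrichment <- function(query, terms, universe) {
  stopifnot(inherits(terms, "pathway_collection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0L)
    stop("query features outside the universe: ",
         paste(head(offenders, 10L), collapse = ", "))
  n_u <- length(universe)
  n_q <- length(query)
  term_ids <- names(terms)
  descs <- attr(terms, "descriptions")
  term_size <- integer(length(terms))
  overlap <- integer(length(terms))
  p <- numeric(length(terms))
  for (i in seq_along(terms)) {
    mem <- intersect(names(terms[[i]]), universe)
    term_size[i] <- length(mem)
    overlap[i] <- length(intersect(mem, query))
    p[i] <- phyper(overlap[i] - 1L, term_size[i], n_u - term_size[i],
                   n_q, lower.tail = FALSE)
  }
  out <- data.frame(term_id = term_ids, term_name = descs,
                    term_size = term_size, query_size = n_q,
                    overlap = overlap, p_value = p,
                    q_value = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= i} p_(j) * m / j` over the ascending order, capped
#' at 1 and returned in input order; controls the expected false
#' discovery proportion under independence or positive dependence.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Filter enrichment results by FDR
#'
#' @param results an `enrichment_result` from
#'   [hypergeometric_enrichment()].
#' @param threshold q-value cut-off (default 0.05, strict).
#' @return The rows with `q_value < threshold`, sorted by ascending q
#'   then p.
#' @export
significant_terms <- function(results, threshold = 0.05) {
  stopifnot(inherits(results, "data.frame"))
  out <- results[!is.na(results$q_value) & results$q_value < threshold, ,
                 drop = FALSE]
  out <- out[order(out$q_value, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
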