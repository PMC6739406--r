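# Validated-target extraction, hypergeometric over-representation testing
# and candidate miRNA prioritization.

#' Extract the validated target set of one miRNA
#'
#' Exact-ID lookup in a validated-interaction table: arm-specific IDs match
#' exactly (`hsa-miR-548am-5p` is not `hsa-miR-548am-3p`). An unknown miR
#' yields the empty set.
#'
#' @param mir_id miRNA identifier.
#' @param interactions Interaction tibble from [read_targets()].
#' @return Character vector of target gene symbols (unique, sorted).
#' @export
get_targets <- function(mir_id, interactions) {
  sort(unique(interactions$gene[interactions$mir_id == mir_id]))
}

#' Hypergeometric gene-set over-representation test
#'
#' For each gene set, tests whether the query over-represents the set
#' relative to drawing `n = |query|` genes uniformly without replacement
#' from the background: with `K = |set `&#8745;` background|` and
#' `k = |query `&#8745;` set|`, the p-value is the upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (equivalently a one-sided
#' Fisher test). Every set is intersected with the background before
#' testing; the query must be a subset of the background.
#'
#' @param query Character vector of gene symbols (the test set, e.g. a miR's
#'   validated targets restricted to the background).
#' @param sets Named list of gene sets, e.g. from [read_gmt()].
#' @param background Character vector of gene symbols defining the sampling
#'   universe.
#' @return A tibble sorted by `p_value` (ties by `set_name`) with columns
#'   `set_name`, `k`, `K`, `n`, `N`, `p_value`, `p_adjusted`
#'   (Benjamini-Hochberg across the tested sets).
#' @export
hypergeom_enrich <- function(query, sets, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background is empty", call. = FALSE)
  query <- unique(as.character(query))
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    stop("query gene(s) not in background: ",
         paste(utils::head(stray, 10L), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  res <- tibble::tibble(
    set_name = names(sets),
    k = unname(vapply(sets, function(s) length(intersect(query, intersect(s, background))), integer(1))),
    K = unname(vapply(sets, function(s) length(intersect(unique(s), background)), integer(1))),
    n = n,
    N = N
  )
  res$p_value <- stats::phyper(res$k - 1L, res$K, res$N - res$K, res$n,
                               lower.tail = FALSE)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value, .data$set_name)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, values capped at 1,
#' order preserved.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Rank candidate miRNAs by escape, target and pathway evidence
#'
#' Orders candidates by, in sequence: tissue-supported escape of the host
#' gene; enrichment of the pathway of interest at `p_adjusted <= alpha`;
#' having at least `min_targets` validated targets; the validated target
#' count; and finally miR ID (lexicographic tie-break). Every criterion is
#' kept as an audit column in the output.
#'
#' @param candidates Tibble with columns `mir_id`, `host_gene`,
#'   `tissue_supported` (logical), `n_targets` (integer).
#' @param enrichments Long tibble of per-candidate enrichment results with
#'   columns `mir_id`, `set_name`, `p_adjusted` (as produced by running
#'   [hypergeom_enrich()] per candidate).
#' @param pathway_of_interest Gene-set name the ranking rewards.
#' @param alpha Adjusted-p significance level for enrichment (default 0.05).
#' @param min_targets Minimum evidence depth for the target-count criterion.
#' @return A tibble with the candidate columns plus `pathway_enriched`,
#'   `meets_min_targets`, `enriched_sets` (list-column) and `rank`
#'   (1..m, unique).
#' @export
prioritize <- function(candidates, enrichments, pathway_of_interest,
                       alpha = 0.05, min_targets = 10L) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, pathway_enriched = logical(),
                         meets_min_targets = logical(),
                         enriched_sets = list(), rank = integer()))
  }
  per_mir <- function(id) {
    e <- enrichments[enrichments$mir_id == id & enrichments$p_adjusted <= alpha, ,
                     drop = FALSE]
    sort(unique(e$set_name))
  }
  candidates$enriched_sets <- lapply(candidates$mir_id, per_mir)
  candidates$pathway_enriched <- vapply(
    candidates$enriched_sets, function(s) pathway_of_interest %in% s, logical(1))
  candidates$meets_min_targets <- candidates$n_targets >= min_targets
  ord <- order(-candidates$tissue_supported, -candidates$pathway_enriched,
               -candidates$meets_min_targets, -candidates$n_targets,
               candidates$mir_id)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  candidates
}
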