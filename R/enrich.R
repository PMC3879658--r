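#' Hypergeometric over-representation p-value
#'
#' Probability of observing at least `overlap` annotated genes in a cluster
#' of size `cluster_size` drawn without replacement from a universe of
#' `universe_size` genes of which `term_size` carry the term:
#' \eqn{p = P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, s). Vectorized.
#'
#' @param overlap Observed overlap k.
#' @param cluster_size Cluster size s.
#' @param term_size Number of genes annotated with the term, K.
#' @param universe_size Universe size N.
#' @return Upper-tail p-value(s) in `[0, 1]`.
#' @examples
#' hypergeom_pvalue(3, 3, 5, 10)  # choose(5,3)/choose(10,3) = 1/12
#' @export
hypergeom_pvalue <- function(overlap, cluster_size, term_size, universe_size) {
  bad <- overlap < 0 | overlap > pmin(cluster_size, term_size) |
    pmax(cluster_size, term_size) > universe_size
  if (any(bad)) rlang::abort("inconsistent counts: need 0 <= k <= min(s, K) <= N")
  stats::phyper(overlap - 1, term_size, universe_size - term_size,
                cluster_size, lower.tail = FALSE)
}

#' Annotation-term enrichment of gene clusters
#'
#' Tests every (cluster, term) pair with at least one overlapping gene for
#' over-representation with the hypergeometric upper tail, flagging terms
#' below the significance threshold (raw p-values by default, matching the
#' conventional `p < 0.001` report; Benjamini-Hochberg adjustment available).
#' The universe defaults to all genes present in the assignment.
#'
#' @param assignment A `cocluster_assignment` (from [hard_assignments()]), or
#'   a data frame with columns `gene_id` and `cluster`.
#' @param annotations Data frame with columns `gene_id`, `term_id` (one row
#'   per annotation; a gene may carry several terms).
#' @param threshold Significance threshold on the (possibly adjusted)
#'   p-value.
#' @param correction `"none"` (default) or `"BH"`.
#' @param universe Optional character vector of gene ids to use as the
#'   background set.
#' @return An `enrichment_result` tibble: `cluster`, `term_id`, `overlap`,
#'   `cluster_size`, `term_size`, `universe_size`, `p_value`, `p_adjusted`,
#'   `significant`, sorted by p-value within cluster.
#' @export
enrich_clusters <- function(assignment, annotations, threshold = 0.001,
                            correction = c("none", "BH"), universe = NULL) {
  correction <- match.arg(correction)
  genes <- if (inherits(assignment, "cocluster_assignment")) {
    dplyr::distinct(assignment$rows, .data$gene_id, .data$cluster)
  } else {
    dplyr::distinct(tibble::as_tibble(assignment), .data$gene_id, .data$cluster)
  }
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  if (is.null(universe)) universe <- unique(genes$gene_id)
  if (!length(universe)) rlang::abort("empty gene universe")
  N <- length(universe)
  ann <- dplyr::filter(dplyr::distinct(tibble::as_tibble(annotations)),
                       .data$gene_id %in% universe)
  term_sets <- split(ann$gene_id, ann$term_id)
  cluster_sets <- split(genes$gene_id, genes$cluster)
  res <- purrr::map_dfr(names(cluster_sets), function(cl) {
    cg <- unique(cluster_sets[[cl]])
    purrr::map_dfr(names(term_sets), function(tm) {
      k <- length(intersect(cg, term_sets[[tm]]))
      if (k < 1L) return(NULL)
      tibble::tibble(cluster = as.integer(cl), term_id = tm, overlap = k,
                     cluster_size = length(cg),
                     term_size = length(term_sets[[tm]]), universe_size = N)
    })
  })
  if (!nrow(res)) {
    res <- tibble::tibble(cluster = integer(), term_id = character(),
                          overlap = integer(), cluster_size = integer(),
                          term_size = integer(), universe_size = integer(),
                          p_value = numeric(), p_adjusted = numeric(),
                          significant = logical())
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  res$p_value <- hypergeom_pvalue(res$overlap, res$cluster_size,
                                  res$term_size, res$universe_size)
  res$p_adjusted <- if (correction == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$significant <- res$p_adjusted < threshold
  res <- dplyr::arrange(res, .data$cluster, .data$p_value)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Count significantly enriched terms per cluster
#'
#' @param result An [enrich_clusters()] result.
#' @return Tibble `cluster`, `n_enriched`.
#' @export
enriched_term_counts <- function(result) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(result), .data$cluster),
                   n_enriched = sum(.data$significant), .groups = "drop")
}
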