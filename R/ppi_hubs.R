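# Hub-gene ranking in protein-protein interaction networks built from DEGs.
#
# Maximal Clique Centrality (MCC) scores a node v as the sum of (|C| - 1)!
# over all maximal cliques C containing v; a node in no clique of size >= 2
# scores 0. Edges are unweighted after the confidence-score cutoff.

#' Load a PPI network from a scored edge list
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`,
#'   `combined_score` in \[0, 1\] (STRING-export style).
#' @param score_cutoff minimum confidence score; edges below it are dropped.
#' @param nodes optional full node set (isolated nodes kept in the graph).
#' @return undirected simple `igraph` graph.
#' @export
load_ppi <- function(edges, score_cutoff = 0.5, nodes = NULL) {
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(edges))) {
    stop_("edges must have columns %s", paste(need, collapse = ", "))
  }
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stop_("combined_score must lie in [0, 1]")
  }
  keep <- edges$combined_score >= score_cutoff & edges$gene_a != edges$gene_b
  edges <- edges[keep, , drop = FALSE]
  verts <- nodes %||% sort(unique(c(edges$gene_a, edges$gene_b)))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::simplify(g)
}

#' Maximal Clique Centrality scores
#'
#' Maximal cliques are enumerated exactly (Bron-Kerbosch with pivoting via
#' `igraph::max_cliques`); no approximation is ever used. Graphs whose clique
#' count exceeds `clique_budget` raise an error advising decomposition.
#'
#' @param graph undirected `igraph` graph.
#' @param clique_budget maximum number of maximal cliques to enumerate.
#' @return named numeric vector of MCC scores (integers stored as doubles).
#' @export
mcc_scores <- function(graph, clique_budget = 1e6) {
  n <- igraph::vcount(graph)
  scores <- setNames(numeric(n), igraph::V(graph)$name)
  if (n == 0) return(scores)
  n_cl <- igraph::count_max_cliques(graph, min = 2)
  if (n_cl > clique_budget) {
    stop_(paste("graph has %d maximal cliques (budget %d);",
                "decompose it before scoring"), n_cl, clique_budget)
  }
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

#' Degree scores
#'
#' @param graph undirected `igraph` graph.
#' @return named numeric vector of edge counts per node.
#' @export
degree_scores <- function(graph) {
  igraph::degree(graph)
}

#' Select the top-scoring hub nodes
#'
#' Takes the top `ceiling(fraction * n)` nodes by score, including every node
#' tied with the k-th score (the returned set can therefore exceed k).
#'
#' @param scores named numeric score vector.
#' @param fraction fraction of nodes to call hubs.
#' @return character vector of hub node names.
#' @export
top_hubs <- function(scores, fraction = 0.15) {
  n <- length(scores)
  if (n == 0) return(character(0))
  k <- ceiling(fraction * n)
  thr <- sort(scores, decreasing = TRUE)[k]
  sort(names(scores)[scores >= thr])
}

#' Overlap between two hub sets
#'
#' Both directional percentages are reported (shared as a percentage of each
#' set), since an overlap statement does not fix its denominator.
#'
#' @param hubs_a,hubs_b character vectors of hub ids.
#' @return list with `n_shared`, `pct_of_a`, `pct_of_b` (one decimal; `NA`
#'   for an empty reference set).
#' @export
method_overlap <- function(hubs_a, hubs_b) {
  shared <- length(intersect(hubs_a, hubs_b))
  pct <- function(n) if (n == 0) NA_real_ else round_half_up(100 * shared / n, 1)
  list(n_shared = shared,
       pct_of_a = pct(length(unique(hubs_a))),
       pct_of_b = pct(length(unique(hubs_b))))
}

#' Hub genes with nearby TE insertions
#'
#' One row per hub gene with at least one TE proximity link; hubs whose
#' single linked TE makes the TE the most plausible regulatory candidate are
#' flagged.
#'
#' @param hubs character vector of hub gene ids.
#' @param de_results data.frame from [nb_test()] (for the DEG direction).
#' @param links proximity links from [link_tes_to_genes()].
#' @return data.frame with `gene_id`, `direction`, `n_tes_nearby`, `te_ids`
#'   (comma-separated), `single_te`.
#' @export
hub_te_report <- function(hubs, de_results, links) {
  sub <- links[links$gene_id %in% hubs, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(gene_id = character(0), direction = character(0),
                      n_tes_nearby = integer(0), te_ids = character(0),
                      single_te = logical(0), stringsAsFactors = FALSE))
  }
  by_gene <- split(sub$te_id, sub$gene_id)
  genes <- names(by_gene)
  dir <- de_results$direction[match(genes, de_results$feature_id)]
  data.frame(gene_id = genes,
             direction = ifelse(is.na(dir), "unknown", dir),
             n_tes_nearby = lengths(by_gene),
             te_ids = vapply(by_gene, function(x) paste(sort(unique(x)), collapse = ","),
                             character(1)),
             single_te = lengths(lapply(by_gene, unique)) == 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}
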