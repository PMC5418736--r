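# Protein-interaction network computations, built on igraph: per-set degree
# and clustering summaries, within/between edge partition, connected cores,
# first-order and co-expression expansion, degree nulls, and the
# publication-vs-degree correlation that motivates publication-bias
# correction.

#' Build an undirected interaction graph from an edge table
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (any extra
#'   columns ignored). Self-loops and duplicate unordered pairs are removed.
#' @return an undirected, simple igraph object with upper-cased gene names.
#' @export
interaction_graph <- function(edges) {
  edges <- dedupe_edges(edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

graph_nodes <- function(g) igraph::V(g)$name

#' Degree, clustering and core summary of a gene set in a graph
#'
#' Degree counts all neighbors in the full graph (not only within the set);
#' clustering is the mean local clustering coefficient over set members in
#' the graph, with degree < 2 nodes contributing 0; the core is the largest
#' connected component of the subgraph induced by the set.
#'
#' @param s gene set (character vector or [labeled_gene_set()]).
#' @param g an igraph object from [interaction_graph()].
#' @return list with `set_name`, `n_in_graph`, `mean_degree`,
#'   `mean_clustering`, `core_size` (means are `NA` when no member is in
#'   the graph).
#' @export
set_network_summary <- function(s, g) {
  members <- intersect(set_members(s), graph_nodes(g))
  if (length(members) == 0) {
    return(list(set_name = set_name(s), n_in_graph = 0L,
                mean_degree = NA_real_, mean_clustering = NA_real_,
                core_size = 0L))
  }
  deg <- igraph::degree(g, v = members)
  cc <- igraph::transitivity(g, type = "local", vids = members)
  cc[is.nan(cc) | is.na(cc)] <- 0
  sub <- igraph::induced_subgraph(g, members)
  core <- max(igraph::components(sub)$csize)
  list(set_name = set_name(s), n_in_graph = length(members),
       mean_degree = mean(deg), mean_clustering = mean(cc),
       core_size = as.integer(core))
}

#' Partition induced edges into within-set and cross-set interactions
#'
#' For two disjoint gene sets, classifies every edge of the subgraph induced
#' by their union as within the first set, within the second, or between the
#' two. Genes belonging to both sets are excluded with a warning.
#'
#' @param a,b gene sets (character vectors or [labeled_gene_set()]).
#' @param g an igraph object.
#' @return list with integer fields `within_a`, `within_b`, `cross`.
#' @export
edge_partition <- function(a, b, g) {
  a <- set_members(a); b <- set_members(b)
  both <- intersect(a, b)
  if (length(both) > 0) {
    warning(length(both), " gene(s) in both sets excluded from edge partition")
    a <- setdiff(a, both); b <- setdiff(b, both)
  }
  nodes <- graph_nodes(g)
  a <- intersect(a, nodes); b <- intersect(b, nodes)
  sub <- igraph::induced_subgraph(g, c(a, b))
  el <- igraph::as_edgelist(sub)
  in_a1 <- el[, 1] %in% a; in_a2 <- el[, 2] %in% a
  list(within_a = sum(in_a1 & in_a2),
       within_b = sum(!in_a1 & !in_a2),
       cross = sum(xor(in_a1, in_a2)))
}

#' First-order network expansion of a seed set
#'
#' Returns the seed genes plus every gene directly connected to a seed gene
#' (first-order interaction partners). Seed genes absent from the graph pass
#' through unchanged.
#'
#' @param seed gene set (character vector or [labeled_gene_set()]).
#' @param g an igraph object.
#' @return character vector, a superset of the seed.
#' @export
first_order_expansion <- function(seed, g) {
  members <- set_members(seed)
  present <- intersect(members, graph_nodes(g))
  if (length(present) == 0) return(members)
  nb <- igraph::adjacent_vertices(g, present)
  partners <- unique(unlist(lapply(nb, function(v) v$name), use.names = FALSE))
  unique(c(members, partners))
}

#' Co-expression expansion of a seed set
#'
#' Adds to the seed every gene co-expressed with a seed gene at a
#' Bonferroni-corrected significance threshold of `alpha / genome_n`
#' (0.05 / 20183 ~ 2.5e-06 by default). Pairs are undirected.
#'
#' @param seed gene set (character vector or [labeled_gene_set()]).
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `p`.
#' @param alpha family-wise significance level (default 0.05).
#' @param genome_n genome size used for the Bonferroni correction
#'   (default 20183).
#' @return character vector, a superset of the seed.
#' @export
coexpression_expansion <- function(seed, pairs, alpha = 0.05,
                                   genome_n = 20183) {
  thr <- coexpression_threshold(alpha, genome_n)
  members <- set_members(seed)
  sig <- pairs[pairs$p < thr, , drop = FALSE]
  hit_a <- sig$gene_a %in% members
  hit_b <- sig$gene_b %in% members
  partners <- c(sig$gene_b[hit_a], sig$gene_a[hit_b])
  unique(c(members, partners))
}

#' Random-set mean-degree null distribution
#'
#' Samples uniform node subsets of the given size (without replacement
#' within each draw) and records their mean degrees, giving an empirical
#' null against which an observed set's mean degree can be ranked.
#'
#' @param size subset size (must not exceed the number of nodes).
#' @param g an igraph object.
#' @param draws number of random subsets.
#' @param seed RNG seed (the global RNG state is restored on exit).
#' @return list with `mean_degrees` (numeric vector of length `draws`) and
#'   `percentile(x)`, a function returning the empirical fraction of draws
#'   with mean degree below `x`.
#' @export
random_set_degree_null <- function(size, g, draws = 1000, seed = 1) {
  nodes <- graph_nodes(g)
  if (size > length(nodes)) stop("size exceeds the number of graph nodes")
  stopifnot(draws >= 1)
  deg <- igraph::degree(g)
  means <- with_seed(seed, {
    vapply(seq_len(draws),
           function(i) mean(deg[sample.int(length(nodes), size)]),
           numeric(1))
  })
  list(mean_degrees = means,
       percentile = function(x) mean(means < x))
}

#' Spearman correlation between publication counts and node degree
#'
#' The correlation that quantifies publication bias in interaction data:
#' well-studied genes accumulate annotated interactions. Computed over
#' genes present in the graph, with average-rank tie handling; genes in the
#' graph but missing from the publication table count 0 publications.
#'
#' @param pub_count named publication-count vector or [gene_universe()].
#' @param g an igraph object.
#' @return Spearman rank correlation coefficient.
#' @export
pub_degree_correlation <- function(pub_count, g) {
  nodes <- graph_nodes(g)
  if (length(nodes) < 3) stop("need at least 3 genes in the graph")
  pubs <- publication_counts(pub_count, nodes)
  deg <- igraph::degree(g, v = nodes)
  stats::cor(pubs, deg, method = "spearman")
}
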