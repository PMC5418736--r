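# Shared fixtures, all built in code.

# Square a-b-c-d-a with chord a-c: mean local clustering 5/6.
chorded_square <- function() {
  interaction_graph(data.frame(
    gene_a = c("a", "b", "c", "d", "a"),
    gene_b = c("b", "c", "d", "a", "c")))
}

# Graph in which groups {A1,A2,A3} and {B1,B2,B3} have degrees {5,7,9} and
# {1,2,3}, padded with degree-1 leaf nodes.
degree_fixture_graph <- function() {
  mk <- function(node, deg) {
    data.frame(gene_a = node, gene_b = sprintf("%s_L%d", node, seq_len(deg)))
  }
  interaction_graph(rbind(mk("A1", 5), mk("A2", 7), mk("A3", 9),
                          mk("B1", 1), mk("B2", 2), mk("B3", 3)))
}

# Small disease catalog: three individually included diseases across two
# classes, plus an undersized disease, an eye disease and a respiratory
# (negative-control) disease.
toy_catalog <- function() {
  gene_block <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  disease_catalog(
    diseases = list(
      breast_neoplasm = gene_block("N", 25),
      lung_neoplasm = c(gene_block("N", 10), gene_block("L", 15)),
      alzheimer = gene_block("Z", 22),
      rare_small = gene_block("R", 19),
      cataract = gene_block("E", 21),
      asthma = gene_block("A", 24)
    ),
    disease_class = c(breast_neoplasm = "neoplasms", lung_neoplasm = "neoplasms",
                      alzheimer = "nervous", rare_small = "nervous",
                      cataract = "eye", asthma = "respiratory")
  )
}

# Exact tail oracle: straight binomial-coefficient enumeration of
# P(X >= k) for X ~ Hypergeometric(N, K, n).
enum_tail <- function(k, K, n, N) {
  lo <- max(k, 0, n - (N - K))
  hi <- min(n, K)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - lo:hi)) / choose(N, n)
}

# Exact two-sided rank-sum p-value by enumeration of all group labelings,
# matching the wilcox.test convention min(1, 2 * min(P(W<=w), P(W>=w))).
perm_rank_sum_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(all_v), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
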