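# Properties of common aging-and-disease (CAD) genes: how many diseases or
# disease classes each CAD gene touches, whether CAD genes are network hubs,
# and molecular evolutionary rate (dN/dS) comparisons between gene groups.

#' CAD-gene frequency profile
#'
#' For each gene of an aging set, counts the diseases (or disease classes)
#' whose gene set contains it; this count is the gene's "frequency". Genes
#' with frequency 0 are not CAD genes and are excluded from the histogram.
#'
#' @param aging_set gene set (character vector or [labeled_gene_set()]).
#' @param catalog a filtered [disease_catalog()].
#' @param level `"class"` or `"individual"`.
#' @return list with `counts` (named vector over all aging genes),
#'   `histogram` (table of frequencies over CAD genes), `n_cad`,
#'   `fraction_le3` (fraction of CAD genes touching at most 3 sets) and
#'   `level`.
#' @export
cad_frequency_profile <- function(aging_set, catalog,
                                  level = c("class", "individual")) {
  level <- match.arg(level)
  members <- set_members(aging_set)
  dsets <- disease_gene_sets(catalog, level)
  counts <- stats::setNames(integer(length(members)), members)
  for (d in dsets) {
    hit <- members %in% d
    counts[hit] <- counts[hit] + 1L
  }
  cad <- counts[counts > 0]
  list(counts = counts,
       histogram = table(cad),
       n_cad = length(cad),
       fraction_le3 = if (length(cad)) mean(cad <= 3) else NA_real_,
       level = level)
}

# Wilcoxon rank-sum wrapper: exact permutation distribution when both
# groups are small (<= 8) and untied, normal approximation with tie and
# continuity correction otherwise.
rank_sum_test <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

group_comparison <- function(a, b, m_tests = 1) {
  ht <- rank_sum_test(a, b)
  list(group_a_values = a, group_b_values = b,
       median_a = stats::median(a), median_b = stats::median(b),
       statistic = ht$statistic, p_value = ht$p_value,
       corrected_p = min(1, ht$p_value * m_tests))
}

#' Compare node degree between CAD genes and a control group
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on interaction-network
#' degrees, asking whether CAD genes are hubs relative to the non-common
#' genes. The usual control is `(aging union disease genes) \ CAD` for the
#' class-level analysis, or `disease set \ CAD` per disease.
#'
#' @param cad CAD gene set.
#' @param control control gene set.
#' @param g an igraph object.
#' @param m_tests Bonferroni denominator for the corrected p-value.
#' @return list with group values, medians, statistic, `p_value` and
#'   `corrected_p`.
#' @export
hub_degree_comparison <- function(cad, control, g, m_tests = 1) {
  nodes <- graph_nodes(g)
  cad_in <- intersect(set_members(cad), nodes)
  ctl_in <- intersect(set_members(control), nodes)
  if (length(cad_in) == 0 || length(ctl_in) == 0) {
    stop("hub_degree_comparison: a group has no genes in the graph")
  }
  group_comparison(as.numeric(igraph::degree(g, cad_in)),
                   as.numeric(igraph::degree(g, ctl_in)),
                   m_tests = m_tests)
}

#' dN/dS ratio
#'
#' Ratio of non-synonymous to synonymous substitution rates; the standard
#' proxy for protein-level selection pressure. Genes with dS = 0 have an
#' undefined ratio and return `NA` (they are excluded from comparisons).
#'
#' @param dn,ds non-negative numeric vectors.
#' @return numeric vector of ratios, `NA` where `ds == 0`.
#' @export
dnds_ratio <- function(dn, ds) {
  if (any(dn < 0, na.rm = TRUE) || any(ds < 0, na.rm = TRUE)) {
    stop("dN and dS must be non-negative")
  }
  ifelse(is.na(ds) | ds == 0, NA_real_, dn / ds)
}

universe_dnds <- function(universe) {
  genes <- intersect(names(universe$dn), names(universe$ds))
  stats::setNames(dnds_ratio(as.numeric(universe$dn[genes]),
                             as.numeric(universe$ds[genes])), genes)
}

#' Compare dN/dS ratios between a gene group and its complement
#'
#' Two-sided Mann-Whitney test on per-gene dN/dS ratios (genes without a
#' defined ratio excluded), with an optional Bonferroni correction over
#' `m_tests` parallel comparisons (e.g. m = 4 for the per-organism
#' anti-vs-pro analysis).
#'
#' @param group gene set of interest.
#' @param complement comparison gene set (e.g. rest of the genome).
#' @param universe a [gene_universe()] carrying dN and dS annotations.
#' @param m_tests Bonferroni denominator (default 1).
#' @return list with group values, medians, statistic, `p_value` and
#'   `corrected_p`.
#' @export
compare_dnds <- function(group, complement, universe, m_tests = 1) {
  ratios <- universe_dnds(universe)
  a <- ratios[intersect(set_members(group), names(ratios))]
  b <- ratios[intersect(set_members(complement), names(ratios))]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_dnds: need at least 2 genes with defined ratios per group")
  }
  group_comparison(as.numeric(a), as.numeric(b), m_tests = m_tests)
}
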