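# Overlap engine: one-sided hypergeometric (Fisher) enrichment of aging gene
# sets against disease gene sets, the dual significance rule
# (observed > expected AND p < alpha), background policies, and common
# aging-and-disease (CAD) gene extraction.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts marked items in a draw of `n` from a universe of
#' `N` items of which `K` are marked. This is the one-sided Fisher exact
#' enrichment p-value for an observed overlap of `k` genes between a set of
#' `K` and a set of `n` genes in a background of `N`. Computed in log space
#' (via [stats::phyper()]), vectorized over all arguments.
#'
#' @param k observed overlap (0 <= k <= n).
#' @param K size of the marked set.
#' @param n draw size.
#' @param N universe size.
#' @return numeric vector of tail probabilities in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(is.na(k) | is.na(K) | is.na(n) | is.na(N))) stop("NA parameter")
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("parameters must be non-negative")
  if (any(k > n)) stop("k must not exceed n")
  if (any(n > N)) stop("n must not exceed N")
  if (any(K > N)) stop("K must not exceed N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Two-sided Fisher exact p-value for a 2x2 overlap table
#'
#' Alternative to the default one-sided enrichment tail (minimum-likelihood
#' two-sided rule, as in [stats::fisher.test()]).
#'
#' @inheritParams hypergeometric_tail
#' @return two-sided p-value.
#' @export
fisher_two_sided <- function(k, K, n, N) {
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
  if (any(tab < 0)) stop("inconsistent contingency counts")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Test the overlap of two gene sets against a background
#'
#' Both sets are intersected with the background before testing. The
#' p-value is the one-sided hypergeometric upper tail of the observed
#' overlap (a `two_sided = TRUE` variant uses the two-sided Fisher test).
#' Significance follows the dual rule: the observed number of common genes
#' must exceed the number expected by chance (`n_A * n_B / N`, strict
#' inequality) AND the p-value must fall below `alpha`.
#'
#' @param a first gene set ([labeled_gene_set()] or character vector).
#' @param b second gene set.
#' @param background character vector, the background universe.
#' @param alpha significance level (default 0.05).
#' @param two_sided use the two-sided Fisher test instead of the
#'   enrichment tail.
#' @return an `overlap_result`: a one-row data.frame with columns
#'   `aging_set`, `disease_set`, `background_size`, `n_aging`, `n_disease`,
#'   `observed`, `expected`, `p_value`, `significant`, `cad_genes`
#'   (semicolon-joined).
#' @export
overlap_test <- function(a, b, background, alpha = 0.05, two_sided = FALSE) {
  background <- normalize_genes(background)
  if (length(background) == 0) stop("background must be non-empty")
  a_bg <- intersect(set_members(a), background)
  b_bg <- intersect(set_members(b), background)
  name_a <- set_name(a, "set_a")
  name_b <- set_name(b, "set_b")
  N <- length(background)
  cad <- intersect(a_bg, b_bg)
  if (length(a_bg) == 0 || length(b_bg) == 0) {
    warning(sprintf("overlap_test(%s, %s): empty set after background restriction",
                    name_a, name_b))
    p <- 1
    expected <- 0
  } else {
    expected <- length(a_bg) * length(b_bg) / N
    p <- if (two_sided) {
      fisher_two_sided(length(cad), length(a_bg), length(b_bg), N)
    } else {
      hypergeometric_tail(length(cad), length(a_bg), length(b_bg), N)
    }
  }
  res <- data.frame(
    aging_set = name_a, disease_set = name_b,
    background_size = N, n_aging = length(a_bg), n_disease = length(b_bg),
    observed = length(cad), expected = expected, p_value = p,
    significant = (length(cad) > expected) && (p < alpha),
    cad_genes = paste(sort(cad), collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(res) <- c("overlap_result", class(res))
  res
}

BACKGROUND_POLICIES <- c("genome", "interactome", "seed_union", "seed_interactome")

#' Resolve a background policy to a gene vector
#'
#' * `genome`: all universe genes.
#' * `interactome`: universe genes with at least one annotated interaction.
#' * `seed_union`: interactome plus the seed aging set plus all disease
#'   genes (the default for first-order-expanded analyses).
#' * `seed_interactome`: interactome plus the seed set only (narrower
#'   variant).
#'
#' @param policy one of the policies above.
#' @param universe a [gene_universe()].
#' @param seed seed gene set for the `seed_*` policies.
#' @param disease_genes disease gene union for `seed_union`.
#' @return character vector of background genes.
#' @export
resolve_background <- function(policy, universe, seed = character(0),
                               disease_genes = character(0)) {
  policy <- match.arg(policy, BACKGROUND_POLICIES)
  switch(policy,
    genome = universe$genes,
    interactome = universe$in_interactome,
    seed_union = unique(c(universe$in_interactome, set_members(seed),
                          normalize_genes(disease_genes))),
    seed_interactome = unique(c(universe$in_interactome, set_members(seed)))
  )
}

#' Run the full aging x disease overlap grid
#'
#' Tests every aging set against every disease set at the requested level
#' (disease classes or individual diseases), plus the two union sets
#' `all_diseases` and `all_classes`. A Benjamini-Hochberg column is emitted
#' for reference; the `significant` flag follows the per-test dual rule
#' (observed > expected and raw p < alpha), not the adjusted values.
#'
#' @param aging_sets list of [labeled_gene_set()] objects.
#' @param catalog a filtered [disease_catalog()].
#' @param universe a [gene_universe()].
#' @param background_policy see [resolve_background()].
#' @param level `"class"` or `"individual"`.
#' @param alpha per-test significance level.
#' @param two_sided use the two-sided Fisher test.
#' @return data.frame of overlap results, one row per (aging set, disease
#'   set), with an extra `p_bh` column.
#' @export
run_overlap_grid <- function(aging_sets, catalog, universe,
                             background_policy = "genome",
                             level = c("class", "individual"),
                             alpha = 0.05, two_sided = FALSE) {
  level <- match.arg(level)
  background_policy <- match.arg(background_policy, BACKGROUND_POLICIES)
  dsets <- disease_gene_sets(catalog, level)
  unions <- catalog_union_sets(catalog)
  dsets <- c(dsets, unions)
  all_disease_genes <- unique(unlist(dsets, use.names = FALSE))
  rows <- list()
  for (a in aging_sets) {
    bg <- resolve_background(background_policy, universe,
                             seed = a, disease_genes = all_disease_genes)
    for (dn in names(dsets)) {
      rows[[length(rows) + 1L]] <- {
        r <- overlap_test(a, dsets[[dn]], bg, alpha = alpha,
                          two_sided = two_sided)
        r$disease_set <- dn
        r
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Count significant diseases per aging set
#'
#' The summary behind the grid bar charts: for each aging set, the number of
#' disease sets (union rows excluded) passing the dual significance rule.
#'
#' @param grid output of [run_overlap_grid()].
#' @param drop_unions exclude the `all_diseases`/`all_classes` rows
#'   (default TRUE).
#' @return data.frame with columns `aging_set`, `n_significant`, `n_tested`.
#' @export
summarize_overlap_grid <- function(grid, drop_unions = TRUE) {
  if (drop_unions) {
    grid <- grid[!grid$disease_set %in% c("all_diseases", "all_classes"), ,
                 drop = FALSE]
  }
  agg <- stats::aggregate(significant ~ aging_set, data = grid, FUN = sum)
  cnt <- stats::aggregate(significant ~ aging_set, data = grid, FUN = length)
  out <- data.frame(aging_set = agg$aging_set,
                    n_significant = agg$significant,
                    n_tested = cnt$significant,
                    stringsAsFactors = FALSE)
  out[order(out$aging_set), , drop = FALSE]
}

#' Extract CAD genes from an overlap grid
#'
#' Common aging-and-disease (CAD) genes are the genes shared between an
#' aging set and a disease set within the test background.
#'
#' @param grid output of [run_overlap_grid()] (or any stack of
#'   `overlap_result` rows).
#' @return named list keyed `"<aging_set>|<disease_set>"`, each element a
#'   character vector of CAD genes.
#' @export
extract_cad_genes <- function(grid) {
  stopifnot(nrow(grid) > 0)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$cad_genes[[i]]
    if (!nzchar(g)) character(0) else strsplit(g, ";", fixed = TRUE)[[1]]
  })
  names(out) <- paste(grid$aging_set, grid$disease_set, sep = "|")
  out
}

#' Enrichment-score / p-value transforms
#'
#' Functional-annotation clustering tools report an enrichment score
#' (E.Score), the negative base-10 logarithm of a (geometric-mean)
#' enrichment p-value: an E.Score of 1.3 corresponds to p = 0.05 and 2.5 to
#' p ~ 0.003.
#'
#' @param p p-value(s) in (0, 1].
#' @param escore enrichment score(s).
#' @return the transformed value(s).
#' @export
p_to_escore <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  -log10(p)
}

#' @rdname p_to_escore
#' @export
escore_to_p <- function(escore) 10^(-escore)

#' Bonferroni-corrected co-expression significance threshold
#'
#' The per-pair threshold applied to co-expression p-values: standard alpha
#' divided by the genome size (0.05 / 20183 ~ 2.5e-06 for the human genome).
#'
#' @param alpha family-wise level (default 0.05).
#' @param genome_n genome size (default 20183 annotated protein-coding
#'   genes).
#' @return the per-test threshold alpha / genome_n.
#' @export
coexpression_threshold <- function(alpha = 0.05, genome_n = 20183) {
  if (genome_n <= 0) stop("genome_n must be positive")
  alpha / genome_n
}
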