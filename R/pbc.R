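# Publication-bias correction (PBC): well-studied genes accumulate both
# interaction annotations and trait associations, so overlap statistics can
# reflect research attention rather than biology. PBC drops genes below a
# per-gene publication-count threshold before testing.

#' Filter a gene set by publication count
#'
#' Retains members with at least `threshold` publications. Genes missing
#' from the publication table count as 0 and are removed. Comparison is
#' inclusive (`>=`) by default; set `inclusive = FALSE` for a strict
#' `>` threshold.
#'
#' @param s a [labeled_gene_set()] (or character vector).
#' @param pub_count named publication-count vector, or a [gene_universe()].
#' @param threshold minimum number of publications (default 10).
#' @param inclusive keep genes with exactly `threshold` publications
#'   (default TRUE).
#' @return the filtered set (labels preserved).
#' @export
apply_publication_filter <- function(s, pub_count, threshold = 10,
                                     inclusive = TRUE) {
  stopifnot(threshold >= 0)
  members <- set_members(s)
  counts <- publication_counts(pub_count, members)
  keep <- if (inclusive) counts >= threshold else counts > threshold
  if (inherits(s, "labeled_gene_set")) {
    s$members <- members[keep]
    s
  } else {
    members[keep]
  }
}

#' Sweep publication thresholds over a collection of gene sets
#'
#' For each candidate threshold, reports per-set sizes before and after the
#' publication filter and the fraction of genes lost.
#'
#' @param sets list of [labeled_gene_set()] objects.
#' @param pub_count named publication-count vector or [gene_universe()].
#' @param thresholds integer vector of thresholds to assess (default 8:20).
#' @return data.frame with columns `threshold`, `set_name`, `n_before`,
#'   `n_after`, `fraction_lost`.
#' @export
sweep_thresholds <- function(sets, pub_count, thresholds = 8:20) {
  stopifnot(length(thresholds) > 0)
  rows <- lapply(thresholds, function(t) {
    per <- lapply(sets, function(s) {
      before <- length(set_members(s))
      after <- length(set_members(apply_publication_filter(s, pub_count, t)))
      data.frame(threshold = t, set_name = set_name(s),
                 n_before = before, n_after = after,
                 fraction_lost = if (before > 0) (before - after) / before else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean and median publication count of a gene set
#'
#' @param genes a gene set (character vector or [labeled_gene_set()]);
#'   must be non-empty.
#' @param pub_count named publication-count vector or [gene_universe()].
#' @return list with elements `mean` and `median` (missing genes count 0).
#' @export
publication_summary <- function(genes, pub_count) {
  members <- set_members(genes)
  if (length(members) == 0) stop("publication_summary: empty gene set")
  counts <- publication_counts(pub_count, members)
  list(mean = mean(counts), median = stats::median(counts))
}
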