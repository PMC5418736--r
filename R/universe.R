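#' @keywords internal
"_PACKAGE"

ORGANISMS <- c("human", "mouse", "fly", "worm", "yeast", "all_orthologs")
LONGEVITY_CLASSES <- c("pro", "anti", "human_candidate", "unset")
DISEASE_CLASSES <- c("neoplasms", "nutritional_metabolic", "nervous",
                     "cardiovascular", "musculoskeletal", "respiratory",
                     "immune", "eye", "other")

normalize_genes <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[!is.na(x) & nzchar(x)]
  unique(x)
}

# Restrict a named vector to universe members; extraneous keys are dropped
# with a warning (catalogs are never perfectly synchronized).
restrict_to_universe <- function(map, genes, what = "annotation") {
  if (is.null(map)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop(what, " mapping must be named by gene")
  }
  names(map) <- toupper(names(map))
  if (anyDuplicated(names(map))) {
    dups <- unique(names(map)[duplicated(names(map))])
    stop("duplicate ", what, " entries for gene(s): ",
         paste(utils::head(dups, 5), collapse = ", "))
  }
  extra <- setdiff(names(map), genes)
  if (length(extra) > 0) {
    warning(length(extra), " ", what,
            " entries for genes absent from the universe were dropped")
    map <- map[setdiff(names(map), extra)]
  }
  map
}

#' Build a gene universe
#'
#' The gene universe is the background catalog for every overlap test: the
#' set of genes considered "the genome", with optional per-gene annotations
#' used downstream (publication counts for publication-bias correction,
#' dN and dS substitution rates for molecular-evolution comparisons, and
#' interactome membership for background restriction).
#'
#' Gene identifiers are upper-cased symbols; annotation keys not present in
#' `genes` are dropped with a warning.
#'
#' @param genes character vector of gene identifiers.
#' @param pub_count named non-negative integer vector, publications per gene.
#' @param dn,ds named non-negative numeric vectors of non-synonymous (dN) and
#'   synonymous (dS) substitution rates per site.
#' @param in_interactome character vector (or named logical) of genes with at
#'   least one annotated protein-protein interaction.
#' @return an object of class `gene_universe`.
#' @export
gene_universe <- function(genes, pub_count = NULL, dn = NULL, ds = NULL,
                          in_interactome = NULL) {
  genes <- normalize_genes(genes)
  if (length(genes) == 0) stop("universe must contain at least one gene")
  pub_count <- restrict_to_universe(pub_count, genes, "publication-count")
  if (length(pub_count) && any(pub_count < 0)) {
    stop("publication counts must be non-negative")
  }
  dn <- restrict_to_universe(dn, genes, "dN")
  ds <- restrict_to_universe(ds, genes, "dS")
  if ((length(dn) && any(dn < 0, na.rm = TRUE)) ||
      (length(ds) && any(ds < 0, na.rm = TRUE))) {
    stop("dN and dS values must be non-negative")
  }
  if (is.logical(in_interactome) && !is.null(names(in_interactome))) {
    in_interactome <- names(in_interactome)[in_interactome]
  }
  in_interactome <- intersect(normalize_genes(in_interactome), genes)
  structure(
    list(genes = genes, pub_count = pub_count, dn = dn, ds = ds,
         in_interactome = in_interactome),
    class = "gene_universe"
  )
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("gene_universe:", length(x$genes), "genes;",
      length(x$in_interactome), "in interactome;",
      length(x$pub_count), "with publication counts;",
      length(x$dn), "with dN/dS\n")
  invisible(x)
}

#' Publication counts for a set of genes
#'
#' Genes missing from the universe's publication table count as 0
#' publications (an unstudied gene is an unpublished gene for bias purposes).
#'
#' @param universe a [gene_universe()] (or a bare named vector of counts).
#' @param genes character vector of genes to look up.
#' @return named integer vector, one entry per gene.
#' @export
publication_counts <- function(universe, genes) {
  map <- if (inherits(universe, "gene_universe")) universe$pub_count else universe
  genes <- toupper(genes)
  out <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(genes, names(map))
  out[hit] <- as.numeric(map[hit])
  out
}

#' Construct a labeled gene set
#'
#' A named gene set carrying its source organism and longevity class.
#' Pro-longevity genes are genes whose decreased expression reduces lifespan
#' and/or whose overexpression extends it; anti-longevity genes are the
#' converse. Human candidate aging genes carry no direction and use the
#' `human_candidate` class.
#'
#' @param name set name.
#' @param members character vector of gene identifiers (deduplicated,
#'   upper-cased).
#' @param organism one of human, mouse, fly, worm, yeast, all_orthologs.
#' @param longevity_class one of pro, anti, human_candidate, unset.
#' @return an object of class `labeled_gene_set`.
#' @export
labeled_gene_set <- function(name, members, organism = "human",
                             longevity_class = "unset") {
  organism <- match.arg(organism, ORGANISMS)
  longevity_class <- match.arg(longevity_class, LONGEVITY_CLASSES)
  structure(
    list(name = as.character(name), organism = organism,
         longevity_class = longevity_class, members = normalize_genes(members)),
    class = "labeled_gene_set"
  )
}

#' @export
print.labeled_gene_set <- function(x, ...) {
  cat(sprintf("labeled_gene_set '%s' (%s, %s): %d genes\n",
              x$name, x$organism, x$longevity_class, length(x$members)))
  invisible(x)
}

set_members <- function(s) {
  if (inherits(s, "labeled_gene_set")) s$members else normalize_genes(s)
}

set_name <- function(s, default = "set") {
  if (inherits(s, "labeled_gene_set")) s$name else default
}

#' Drop set members absent from the universe
#'
#' @param s a [labeled_gene_set()].
#' @param universe a [gene_universe()].
#' @param quiet suppress the warning about dropped genes.
#' @return the set restricted to universe members.
#' @export
intersect_with_universe <- function(s, universe, quiet = FALSE) {
  stopifnot(inherits(s, "labeled_gene_set"), inherits(universe, "gene_universe"))
  missing <- setdiff(s$members, universe$genes)
  if (length(missing) > 0 && !quiet) {
    warning(sprintf("set '%s': %d gene(s) absent from the universe dropped",
                    s$name, length(missing)))
  }
  s$members <- intersect(s$members, universe$genes)
  s
}
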