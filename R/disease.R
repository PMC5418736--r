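# Age-related disease (ARD) catalog: disease -> gene sets, disease classes,
# and the inclusion/exclusion rules applied before overlap testing.

#' Construct a disease catalog
#'
#' @param diseases named list mapping disease id to a character vector of
#'   associated genes.
#' @param disease_class named character vector mapping disease id to one of
#'   the recognized disease classes (see `DISEASE_CLASSES`): neoplasms,
#'   nutritional_metabolic, nervous, cardiovascular, musculoskeletal,
#'   respiratory, immune, eye, other.
#' @param negative_control_classes classes treated as negative controls a
#'   priori (default: respiratory tract diseases).
#' @return an object of class `disease_catalog`. Before filtering, every
#'   disease is flagged as included at both the individual and class level.
#' @export
disease_catalog <- function(diseases, disease_class,
                            negative_control_classes = "respiratory") {
  stopifnot(is.list(diseases), length(diseases) > 0)
  ids <- names(diseases)
  if (is.null(ids) || any(!nzchar(ids))) stop("diseases must be named")
  if (!setequal(ids, names(disease_class))) {
    stop("disease_class must be named by the same disease ids as diseases")
  }
  disease_class <- disease_class[ids]
  bad <- setdiff(unique(disease_class), DISEASE_CLASSES)
  if (length(bad) > 0) stop("unknown disease class(es): ", paste(bad, collapse = ", "))
  diseases <- lapply(diseases, normalize_genes)
  structure(
    list(diseases = diseases,
         disease_class = disease_class,
         included_individual = stats::setNames(rep(TRUE, length(ids)), ids),
         included_class = stats::setNames(rep(TRUE, length(ids)), ids),
         negative_control_classes = negative_control_classes,
         filtered = FALSE),
    class = "disease_catalog"
  )
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat("disease_catalog:", length(x$diseases), "diseases,",
      length(unique(x$disease_class)), "classes;",
      sum(x$included_individual), "included individually\n")
  invisible(x)
}

DEFAULT_ARD_CLASSES <- c("neoplasms", "nutritional_metabolic", "nervous",
                         "cardiovascular", "musculoskeletal", "respiratory",
                         "immune")

#' Apply the ARD inclusion rules to a disease catalog
#'
#' Diseases with fewer than `min_genes` associated genes, or whose class is
#' not among `allowed_classes`, are excluded entirely (both individual and
#' class-level analyses). Eye diseases are excluded from the individual
#' disease analysis but retained at the class level. Respiratory tract
#' diseases are retained and tagged as the negative control class.
#'
#' @param catalog a [disease_catalog()].
#' @param min_genes minimum number of associated genes for inclusion
#'   (default 20).
#' @param allowed_classes age-related disease classes analysed individually;
#'   eye diseases are additionally allowed at the class level.
#' @return the catalog with inclusion flags set and `filtered = TRUE`.
#' @export
filter_disease_catalog <- function(catalog, min_genes = 20,
                                   allowed_classes = DEFAULT_ARD_CLASSES) {
  stopifnot(inherits(catalog, "disease_catalog"), min_genes >= 1)
  sizes <- vapply(catalog$diseases, length, integer(1))
  cls <- catalog$disease_class
  big_enough <- sizes >= min_genes
  class_ok <- cls %in% union(allowed_classes, "eye")
  catalog$included_class <- big_enough & class_ok
  catalog$included_individual <- big_enough & cls %in% setdiff(allowed_classes, "eye")
  catalog$filtered <- TRUE
  if (!any(catalog$included_individual)) {
    message("filter_disease_catalog: no disease passes the individual-level filter")
  }
  catalog
}

#' Disease gene sets at a given analysis level
#'
#' At the `individual` level, one set per included disease. At the `class`
#' level, one set per disease class: the union of its included diseases'
#' genes (eye retained here even though excluded individually).
#'
#' @param catalog a (filtered) [disease_catalog()].
#' @param level `"class"` or `"individual"`.
#' @return named list of character vectors.
#' @export
disease_gene_sets <- function(catalog, level = c("class", "individual")) {
  level <- match.arg(level)
  if (level == "individual") {
    catalog$diseases[catalog$included_individual]
  } else {
    keep <- names(catalog$diseases)[catalog$included_class]
    cls <- catalog$disease_class[keep]
    sets <- lapply(split(keep, cls), function(ids) {
      unique(unlist(catalog$diseases[ids], use.names = FALSE))
    })
    sets[order(names(sets))]
  }
}

#' Union gene sets over the catalog
#'
#' `all_diseases` is the union of genes of all individually included
#' diseases; `all_classes` is the union over all class-level sets.
#'
#' @param catalog a (filtered) [disease_catalog()].
#' @return list with elements `all_diseases` and `all_classes`.
#' @export
catalog_union_sets <- function(catalog) {
  list(
    all_diseases = unique(unlist(disease_gene_sets(catalog, "individual"),
                                 use.names = FALSE)),
    all_classes = unique(unlist(disease_gene_sets(catalog, "class"),
                                use.names = FALSE))
  )
}
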