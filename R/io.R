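# Readers/writers for the plain-text interchange formats: GMT gene sets,
# TSV edge lists, TSV gene-pair tables and TSV per-gene annotation tables.

#' Default label policy for GMT set names
#'
#' Parses names such as `worm_pro`, `mouse_anti` or `human` into an organism
#' and a longevity class. `human` with no direction token maps to the
#' `human_candidate` class; `all_orthologs_pro`/`_anti` are recognized.
#'
#' @param name a set name.
#' @return list with elements `organism` and `longevity_class`.
#' @export
parse_set_label <- function(name) {
  low <- tolower(name)
  org <- ORGANISMS[vapply(ORGANISMS, function(o) grepl(o, low, fixed = TRUE),
                          logical(1))]
  cls <- if (grepl("anti", low)) "anti" else if (grepl("pro", low)) "pro" else NA
  if (length(org) == 0) {
    stop("cannot parse organism from set name '", name,
         "'; supply a custom label_policy")
  }
  org <- org[[1]]
  if (is.na(cls)) cls <- if (org == "human") "human_candidate" else "unset"
  list(organism = org, longevity_class = cls)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Genes are upper-cased and deduplicated within a line.
#'
#' @param path GMT file path.
#' @param label_policy a function mapping a set name to
#'   `list(organism, longevity_class)`, or `NULL` to label every set
#'   `human`/`unset`. Defaults to [parse_set_label()].
#' @return list of [labeled_gene_set()] objects.
#' @export
read_gene_sets <- function(path, label_policy = parse_set_label) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    members <- normalize_genes(fields[-(1:2)])
    if (length(members) == 0) {
      stop(sprintf("GMT validation error at line %d ('%s'): empty member list",
                   i, fields[[1]]))
    }
    lab <- if (is.null(label_policy)) {
      list(organism = "human", longevity_class = "unset")
    } else {
      label_policy(fields[[1]])
    }
    out[[i]] <- labeled_gene_set(fields[[1]], members,
                                 organism = lab$organism,
                                 longevity_class = lab$longevity_class)
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [labeled_gene_set()] objects.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- paste(s$organism, s$longevity_class, sep = "|")
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

DEFAULT_EDGE_TYPES <- c("physical association", "direct interaction")

#' Read an undirected edge list
#'
#' Expects a TSV with header and columns `gene_a`, `gene_b` and optionally
#' `interaction_type`. Self-loops are removed and unordered duplicates
#' collapsed. When a type column is present, only the allowed interaction
#' types (by default the two main physical evidence types, `physical
#' association` and `direct interaction`) are kept.
#'
#' @param path TSV file path.
#' @param allowed_types character vector of interaction types to keep, or
#'   `NULL` to keep everything.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_edge_list <- function(path, allowed_types = DEFAULT_EDGE_TYPES) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("edge list must have columns gene_a and gene_b")
  }
  if ("interaction_type" %in% names(df) && !is.null(allowed_types)) {
    df <- df[df$interaction_type %in% allowed_types, , drop = FALSE]
  }
  dedupe_edges(df[, c("gene_a", "gene_b")])
}

dedupe_edges <- function(df) {
  a <- toupper(trimws(as.character(df$gene_a)))
  b <- toupper(trimws(as.character(df$gene_b)))
  keep <- nzchar(a) & nzchar(b) & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  data.frame(gene_a = lo[keep], gene_b = hi[keep], stringsAsFactors = FALSE)
}

#' Read a gene-pair p-value table (co-expression)
#'
#' TSV with header and columns `gene_a`, `gene_b`, `p`.
#'
#' @param path TSV file path.
#' @return data.frame with upper-cased gene columns and numeric `p`.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_a", "gene_b", "p") %in% names(df))) {
    stop("pair table must have columns gene_a, gene_b, p")
  }
  df$gene_a <- toupper(trimws(df$gene_a))
  df$gene_b <- toupper(trimws(df$gene_b))
  df$p <- as.numeric(df$p)
  if (any(is.na(df$p)) || any(df$p < 0 | df$p > 1)) {
    stop("pair table p-values must lie in [0, 1]")
  }
  df
}

#' Read a per-gene annotation table
#'
#' TSV with header: a `gene` column plus one or more numeric value columns.
#' Rows are keyed uniquely by gene; duplicated genes with conflicting values
#' are a validation error.
#'
#' @param path TSV file path.
#' @param value_cols columns to extract; defaults to all non-gene columns.
#' @return a named vector (one value column) or a data.frame keyed by gene.
#' @export
read_annotation_table <- function(path, value_cols = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("annotation table must have a 'gene' column")
  df$gene <- toupper(trimws(df$gene))
  if (is.null(value_cols)) value_cols <- setdiff(names(df), "gene")
  df <- unique(df[, c("gene", value_cols), drop = FALSE])
  if (anyDuplicated(df$gene)) {
    bad <- unique(df$gene[duplicated(df$gene)])
    stop("conflicting annotation rows for gene(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (length(value_cols) == 1) {
    stats::setNames(df[[value_cols]], df$gene)
  } else {
    rownames(df) <- df$gene
    df
  }
}

#' Read a disease catalog from a long-format TSV
#'
#' TSV with header and columns `disease_id`, `class`, `gene` (one row per
#' disease-gene association).
#'
#' @param path TSV file path.
#' @return a [disease_catalog()].
#' @export
read_disease_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("disease_id", "class", "gene") %in% names(df))) {
    stop("disease table must have columns disease_id, class, gene")
  }
  df$gene <- toupper(trimws(df$gene))
  diseases <- lapply(split(df$gene, df$disease_id), function(g) unique(g))
  cls <- vapply(split(df$class, df$disease_id),
                function(x) unique(x)[[1]], character(1))
  dup_cls <- vapply(split(df$class, df$disease_id),
                    function(x) length(unique(x)) > 1, logical(1))
  if (any(dup_cls)) {
    stop("diseases assigned to multiple classes: ",
         paste(names(dup_cls)[dup_cls], collapse = ", "))
  }
  disease_catalog(diseases, cls)
}

# Deterministic TSV writer used by every stage (stable column order, no
# quoting surprises, "." decimal) so reruns are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
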