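# Direction-aware drug repositioning: a drug predicted to extend lifespan
# should suppress anti-longevity genes ('Anti' interactions scored against
# the anti-longevity set) or activate pro-longevity genes ('Pro'
# interactions scored against the pro-longevity set). Each (drug, direction)
# entry gets a one-tailed hypergeometric p-value, Bonferroni-corrected over
# all scored entries.

#' Default interaction-type direction map
#'
#' Classification of common drug-gene interaction-type strings into `Anti`
#' (decrease gene expression or activity), `Pro` (increase) or `Neither`.
#' This is a package-authored default mirroring the interaction vocabularies
#' of public drug-gene interaction databases; replace it with your own TSV
#' (`interaction_type`, `direction`) for other vocabularies.
#'
#' @param path optional path to a replacement TSV.
#' @return named character vector interaction_type -> direction.
#' @export
default_direction_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interaction_direction_map.tsv",
                        package = "gerontome", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("interaction_type", "direction") %in% names(df)))
  bad <- setdiff(unique(df$direction), c("Anti", "Pro", "Neither"))
  if (length(bad)) stop("invalid direction(s) in map: ", paste(bad, collapse = ", "))
  stats::setNames(df$direction, tolower(df$interaction_type))
}

#' Label drug-gene interactions with a longevity direction
#'
#' Adds a `direction` column (`Anti`, `Pro`, `Neither`) to a drug-gene
#' interaction table. Interaction types absent from the map default to
#' `Neither` with a warning; `Neither` rows are excluded from scoring.
#'
#' @param table data.frame with columns `drug`, `gene`, `interaction_type`.
#' @param map named character vector from [default_direction_map()].
#' @return the table with an added `direction` column.
#' @export
classify_interactions <- function(table, map = default_direction_map()) {
  stopifnot(all(c("drug", "gene", "interaction_type") %in% names(table)))
  key <- tolower(trimws(table$interaction_type))
  dir <- unname(map[key])
  unknown <- is.na(dir)
  if (any(unknown)) {
    warning(sum(unknown), " interaction row(s) with unmapped type(s) (",
            paste(utils::head(unique(key[unknown]), 5), collapse = ", "),
            ") classified as Neither")
    dir[unknown] <- "Neither"
  }
  table$gene <- toupper(trimws(table$gene))
  table$direction <- dir
  table
}

#' Score one drug in one direction
#'
#' One-tailed hypergeometric test: of `N` genes in the drug universe, `K`
#' belong to the direction-matched longevity set; the drug's `n` scored
#' targets contain `k` of them; p = P(X >= k).
#'
#' @param drug drug name.
#' @param direction `"Anti"` or `"Pro"`.
#' @param targets the drug's target genes carrying this direction.
#' @param longevity_set the matching longevity gene set (anti-longevity for
#'   `Anti`, pro-longevity for `Pro`).
#' @param universe character vector: the scoring population.
#' @return one-row data.frame with `drug`, `direction`, `k`, `n`, `K`, `N`,
#'   `p_value`.
#' @export
score_drug <- function(drug, direction, targets, longevity_set, universe) {
  universe <- normalize_genes(universe)
  if (length(universe) == 0) stop("score_drug: empty universe")
  targets <- intersect(normalize_genes(targets), universe)
  lset <- intersect(set_members(longevity_set), universe)
  k <- length(intersect(targets, lset))
  data.frame(drug = drug, direction = direction,
             k = k, n = length(targets), K = length(lset),
             N = length(universe),
             p_value = hypergeometric_tail(k, length(lset), length(targets),
                                           length(universe)),
             stringsAsFactors = FALSE)
}

#' Score every drug in a classified interaction table
#'
#' For each drug, its `Anti`-typed interactions are scored against the
#' anti-longevity set and its `Pro`-typed interactions against the
#' pro-longevity set; a drug carrying both interaction directions is scored
#' twice. The scoring universe defaults to the genes appearing in the
#' interaction table (optionally intersected with a gene universe).
#'
#' @param interactions output of [classify_interactions()].
#' @param anti_set,pro_set anti- and pro-longevity gene sets.
#' @param universe optional [gene_universe()] (or character vector) to
#'   intersect the drug-annotated gene population with; `NULL` uses the
#'   table's genes as-is.
#' @return data.frame of per-(drug, direction) scores.
#' @export
score_drugs <- function(interactions, anti_set, pro_set, universe = NULL) {
  scored <- interactions[interactions$direction %in% c("Anti", "Pro"), ,
                         drop = FALSE]
  pop <- unique(scored$gene)
  if (!is.null(universe)) {
    ug <- if (inherits(universe, "gene_universe")) universe$genes
          else normalize_genes(universe)
    pop <- intersect(pop, ug)
  }
  if (length(pop) == 0) stop("score_drugs: empty drug-gene universe")
  sets <- list(Anti = anti_set, Pro = pro_set)
  keys <- unique(scored[, c("drug", "direction")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- keys$drug[[i]]; dir <- keys$direction[[i]]
    targets <- scored$gene[scored$drug == d & scored$direction == dir]
    score_drug(d, dir, targets, sets[[dir]], pop)
  })
  do.call(rbind, rows)
}

#' Rank drug scores by ascending p-value
#'
#' Stable tie-break by drug name then direction. Bonferroni correction uses
#' m = number of scored (drug, direction) entries; a drug is significant
#' when its corrected p-value is below `alpha`.
#'
#' @param scores output of [score_drugs()].
#' @param alpha family-wise significance level (default 0.05).
#' @return the scores ordered by p, with added `bonferroni_p`, `significant`
#'   and `rank` columns.
#' @export
rank_drugs <- function(scores, alpha = 0.05) {
  m <- nrow(scores)
  scores$bonferroni_p <- pmin(1, scores$p_value * m)
  scores$significant <- scores$bonferroni_p < alpha
  ord <- order(scores$p_value, scores$drug, scores$direction)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(m)
  rownames(scores) <- NULL
  scores
}
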