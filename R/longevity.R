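# Assembly of pro-/anti-longevity gene sets from raw per-organism
# classification tables.

MODEL_ORGANISMS <- c("mouse", "fly", "worm", "yeast")

#' Assemble longevity gene sets from a raw classification table
#'
#' Takes a long table of `(gene, organism, class_annotation)` rows, where the
#' annotation is `pro`, `anti` or `unclear` (a gene reported with both
#' directions simply appears as two rows). Per organism, genes annotated with
#' both classes are excluded from both sets, and unclassified (`unclear`)
#' genes are excluded. Two union sets over the four model organisms
#' (`all_orthologs_anti`, `all_orthologs_pro`) are appended.
#'
#' @param raw data.frame with columns `gene`, `organism`, `class_annotation`.
#' @return named list of [labeled_gene_set()] objects (`<organism>_anti`,
#'   `<organism>_pro`, plus the two `all_orthologs` unions).
#' @export
assemble_longevity_sets <- function(raw) {
  stopifnot(all(c("gene", "organism", "class_annotation") %in% names(raw)))
  raw$gene <- toupper(trimws(raw$gene))
  raw$organism <- tolower(trimws(raw$organism))
  raw$class_annotation <- tolower(trimws(raw$class_annotation))
  bad_org <- setdiff(unique(raw$organism), MODEL_ORGANISMS)
  if (length(bad_org) > 0) {
    stop("unknown organism token(s): ", paste(bad_org, collapse = ", "))
  }
  bad_cls <- setdiff(unique(raw$class_annotation), c("pro", "anti", "unclear"))
  if (length(bad_cls) > 0) {
    stop("unknown class annotation(s): ", paste(bad_cls, collapse = ", "))
  }
  out <- list()
  for (org in intersect(MODEL_ORGANISMS, unique(raw$organism))) {
    sub <- raw[raw$organism == org, , drop = FALSE]
    pro <- unique(sub$gene[sub$class_annotation == "pro"])
    anti <- unique(sub$gene[sub$class_annotation == "anti"])
    dual <- intersect(pro, anti)
    pro <- setdiff(pro, dual)
    anti <- setdiff(anti, dual)
    out[[paste0(org, "_anti")]] <-
      structure(list(name = paste0(org, "_anti"), organism = org,
                     longevity_class = "anti", members = anti),
                class = "labeled_gene_set")
    out[[paste0(org, "_pro")]] <-
      structure(list(name = paste0(org, "_pro"), organism = org,
                     longevity_class = "pro", members = pro),
                class = "labeled_gene_set")
  }
  for (cls in c("anti", "pro")) {
    members <- unique(unlist(lapply(out, function(s) {
      if (s$longevity_class == cls) s$members else character(0)
    }), use.names = FALSE))
    nm <- paste0("all_orthologs_", cls)
    out[[nm]] <- structure(
      list(name = nm, organism = "all_orthologs", longevity_class = cls,
           members = members),
      class = "labeled_gene_set")
  }
  out
}
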