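# End-to-end orchestration: load a benchmark-format input bundle, run every
# analysis stage in the canonical order (baseline overlap grid, grid with
# publication-bias correction, interactome-restricted grid, first-order
# expansion grid, co-expression expansion grid, network summaries, CAD-gene
# properties, dN/dS comparisons, drug ranking) and write per-stage TSVs plus
# one JSON run summary.

#' Pipeline run configuration
#'
#' @param input_dir directory containing the input bundle
#'   (`universe.tsv`, `ppi.tsv`, `pubs.tsv`, `aging.gmt`, `diseases.tsv`,
#'   `coexpr.tsv`, `drugs.tsv`, `dnds.tsv`; see [generate_benchmark()]).
#' @param out_dir output directory for stage TSVs and the run summary.
#' @param pbc_threshold publication-count threshold for the PBC stages.
#' @param background_policy background for the baseline grid
#'   (see [resolve_background()]).
#' @param alpha per-test significance level, in (0, 1).
#' @param min_genes minimum disease-set size for catalog inclusion.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir, out_dir, pbc_threshold = 10,
                       background_policy = "genome", alpha = 0.05,
                       min_genes = 20) {
  stopifnot(alpha > 0, alpha < 1)
  needed <- c("universe.tsv", "ppi.tsv", "pubs.tsv", "aging.gmt",
              "diseases.tsv", "coexpr.tsv", "drugs.tsv", "dnds.tsv")
  missing <- needed[!file.exists(file.path(input_dir, needed))]
  if (length(missing) > 0) {
    stop("input bundle incomplete, missing: ", paste(missing, collapse = ", "))
  }
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 pbc_threshold = pbc_threshold,
                 background_policy = match.arg(background_policy,
                                               BACKGROUND_POLICIES),
                 alpha = alpha, min_genes = min_genes),
            class = "run_config")
}

#' Load an input bundle from disk
#'
#' Reads the benchmark-format files back into analysis-ready objects.
#'
#' @param input_dir bundle directory.
#' @return list with `universe`, `graph`, `aging_sets`, `catalog` (already
#'   filtered is NOT applied here), `coexpr`, `drug_table`.
#' @export
load_bundle <- function(input_dir) {
  uni_df <- utils::read.delim(file.path(input_dir, "universe.tsv"),
                              stringsAsFactors = FALSE)
  pubs <- read_annotation_table(file.path(input_dir, "pubs.tsv"))
  dnds <- utils::read.delim(file.path(input_dir, "dnds.tsv"),
                            stringsAsFactors = FALSE)
  edges <- read_edge_list(file.path(input_dir, "ppi.tsv"))
  g <- interaction_graph(edges)
  universe <- gene_universe(
    uni_df$gene, pub_count = pubs,
    dn = stats::setNames(dnds$dn, dnds$gene),
    ds = stats::setNames(dnds$ds, dnds$gene),
    in_interactome = toupper(uni_df$gene[uni_df$in_interactome == 1])
  )
  list(universe = universe, graph = g,
       aging_sets = read_gene_sets(file.path(input_dir, "aging.gmt")),
       catalog = read_disease_catalog(file.path(input_dir, "diseases.tsv")),
       coexpr = read_pair_table(file.path(input_dir, "coexpr.tsv")),
       drug_table = utils::read.delim(file.path(input_dir, "drugs.tsv"),
                                      stringsAsFactors = FALSE))
}

expand_sets <- function(sets, how, graph = NULL, coexpr = NULL,
                        alpha = 0.05, genome_n = 20183) {
  lapply(sets, function(s) {
    s$members <- switch(how,
      none = s$members,
      first_order = first_order_expansion(s, graph),
      coexpression = coexpression_expansion(s, coexpr, alpha = alpha,
                                            genome_n = genome_n))
    s
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the bundle in `cfg$input_dir` and writes stage
#' TSVs plus `run_summary.json` under `cfg$out_dir`. All stages are
#' deterministic, so re-running an identical configuration reproduces the
#' outputs byte for byte.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) the run summary list.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  b <- stage("load", load_bundle(cfg$input_dir))
  catalog <- stage("catalog",
                   filter_disease_catalog(b$catalog, min_genes = cfg$min_genes))
  aging <- lapply(b$aging_sets, intersect_with_universe, b$universe,
                  quiet = TRUE)
  genome_n <- length(b$universe$genes)

  grids <- list()
  for (level in c("class", "individual")) {
    grids[[paste0("baseline_", level)]] <- stage("baseline", run_overlap_grid(
      aging, catalog, b$universe, cfg$background_policy, level, cfg$alpha))
  }
  aging_pbc <- lapply(aging, apply_publication_filter, b$universe,
                      threshold = cfg$pbc_threshold)
  aging_pbc <- Filter(function(s) length(s$members) > 0, aging_pbc)
  for (level in c("class", "individual")) {
    grids[[paste0("pbc_", level)]] <- stage("pbc", run_overlap_grid(
      aging_pbc, catalog, b$universe, cfg$background_policy, level,
      cfg$alpha))
  }
  grids$interactome_class <- stage("interactome", run_overlap_grid(
    aging, catalog, b$universe, "interactome", "class", cfg$alpha))
  first_order <- expand_sets(aging_pbc, "first_order", graph = b$graph)
  grids$first_order_class <- stage("first_order", run_overlap_grid(
    first_order, catalog, b$universe, "seed_union", "class", cfg$alpha))
  coexp <- expand_sets(aging, "coexpression", coexpr = b$coexpr,
                       alpha = cfg$alpha, genome_n = genome_n)
  grids$coexpression_class <- stage("coexpression", run_overlap_grid(
    coexp, catalog, b$universe, "genome", "class", cfg$alpha))

  for (nm in names(grids)) {
    write_tsv(grids[[nm]], file.path(cfg$out_dir, paste0("overlap_", nm, ".tsv")))
  }

  net <- stage("network", {
    rows <- lapply(aging, function(s) {
      as.data.frame(set_network_summary(s, b$graph), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  write_tsv(net, file.path(cfg$out_dir, "network_summary.tsv"))

  cad <- stage("cad", {
    human <- aging_pbc[vapply(aging_pbc,
                              function(s) s$longevity_class == "human_candidate",
                              logical(1))]
    if (length(human) == 0) human <- aging_pbc[1]
    human <- human[[1]]
    prof <- cad_frequency_profile(human, catalog, "class")
    freq <- data.frame(gene = names(prof$counts),
                       level = "class",
                       count = as.integer(prof$counts),
                       stringsAsFactors = FALSE)
    cad_genes <- names(prof$counts)[prof$counts > 0]
    pool <- unique(c(human$members,
                     unlist(disease_gene_sets(catalog, "class"),
                            use.names = FALSE)))
    control <- setdiff(pool, cad_genes)
    hub <- if (length(intersect(cad_genes, graph_nodes(b$graph))) > 0 &&
               length(intersect(control, graph_nodes(b$graph))) > 0) {
      hub_degree_comparison(cad_genes, control, b$graph)
    } else NULL
    list(freq = freq, profile = prof, hub = hub, set = human$name)
  })
  write_tsv(cad$freq, file.path(cfg$out_dir, "cad_frequency.tsv"))

  dnds_cmp <- stage("dnds", {
    ard <- catalog_union_sets(catalog)$all_classes
    aging_union <- unique(unlist(lapply(aging, `[[`, "members"),
                                 use.names = FALSE))
    genome <- b$universe$genes
    rows <- list(
      c(list(comparison = "ard_vs_genome"),
        strip_values(compare_dnds(ard, setdiff(genome, ard), b$universe))),
      c(list(comparison = "aging_vs_genome"),
        strip_values(compare_dnds(aging_union, setdiff(genome, aging_union),
                                  b$universe)))
    )
    orgs <- unique(vapply(aging, `[[`, character(1), "organism"))
    orgs <- setdiff(orgs, c("human", "all_orthologs"))
    for (org in orgs) {
      anti <- unlist(lapply(aging, function(s)
        if (s$organism == org && s$longevity_class == "anti") s$members
        else character(0)), use.names = FALSE)
      pro <- unlist(lapply(aging, function(s)
        if (s$organism == org && s$longevity_class == "pro") s$members
        else character(0)), use.names = FALSE)
      if (length(anti) >= 2 && length(pro) >= 2) {
        rows[[length(rows) + 1L]] <- c(
          list(comparison = paste0(org, "_anti_vs_pro")),
          strip_values(compare_dnds(anti, pro, b$universe,
                                    m_tests = length(orgs))))
      }
    }
    do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  })
  write_tsv(dnds_cmp, file.path(cfg$out_dir, "dnds_comparisons.tsv"))

  drugs <- stage("drugs", {
    classified <- classify_interactions(b$drug_table)
    anti <- unlist(lapply(aging, function(s)
      if (s$organism == "all_orthologs" && s$longevity_class == "anti")
        s$members else character(0)), use.names = FALSE)
    pro <- unlist(lapply(aging, function(s)
      if (s$organism == "all_orthologs" && s$longevity_class == "pro")
        s$members else character(0)), use.names = FALSE)
    rank_drugs(score_drugs(classified, anti, pro, universe = b$universe),
               alpha = cfg$alpha)
  })
  write_tsv(drugs, file.path(cfg$out_dir, "drug_ranking.tsv"))

  summary <- list(
    config = list(pbc_threshold = cfg$pbc_threshold,
                  background_policy = cfg$background_policy,
                  alpha = cfg$alpha, min_genes = cfg$min_genes),
    significant_counts = lapply(grids, function(gr) {
      s <- summarize_overlap_grid(gr)
      stats::setNames(as.list(s$n_significant), s$aging_set)
    }),
    cad = list(set = cad$set, n_cad = cad$profile$n_cad,
               fraction_le3 = cad$profile$fraction_le3,
               hub_p = if (is.null(cad$hub)) NA else cad$hub$p_value),
    n_significant_drugs = sum(drugs$significant)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

strip_values <- function(cmp) {
  cmp[c("median_a", "median_b", "statistic", "p_value", "corrected_p")]
}
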