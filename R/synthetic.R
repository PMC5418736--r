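# Synthetic benchmark generator. Emulates the structure of the real inputs
# (gene catalog, heavy-tailed interactome, publication counts correlated
# with degree, aging sets enriched for hubs, disease sets with planted
# overlap odds ratios, sparse small-p co-expression pairs, drug-target
# tables with planted direction-matched drugs, and dN/dS values with a
# location shift for disease genes) so that every pipeline stage can be
# exercised and scored offline against a known planted truth.

#' Default synthetic aging-set layout
#'
#' Mimics the relative sizes of the curated aging catalogs at 1/4 scale
#' (one human candidate set plus anti/pro sets per model organism).
#'
#' @return data.frame with columns `name`, `organism`, `class`, `size`.
#' @export
default_aging_layout <- function() {
  data.frame(
    name = c("human", "mouse_anti", "mouse_pro", "fly_anti", "fly_pro",
             "worm_anti", "worm_pro", "yeast_anti", "yeast_pro"),
    organism = c("human", "mouse", "mouse", "fly", "fly",
                 "worm", "worm", "yeast", "yeast"),
    class = c("human_candidate", "anti", "pro", "anti", "pro",
              "anti", "pro", "anti", "pro"),
    size = c(75L, 6L, 15L, 12L, 22L, 95L, 72L, 10L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic disease layout
#'
#' Seven age-related disease classes (respiratory as the a-priori negative
#' control, planted odds ratio 1) plus an eye class, two to three diseases
#' each. `planted_or` is the odds ratio at which disease membership favors
#' aging genes.
#'
#' @return data.frame with columns `name`, `class`, `size`, `planted_or`.
#' @export
default_disease_layout <- function() {
  data.frame(
    name = c("breast_neoplasm", "lung_neoplasm", "colorectal_neoplasm",
             "type2_diabetes", "obesity",
             "alzheimer", "parkinson",
             "atherosclerosis", "coronary_disease",
             "osteoporosis", "osteoarthritis",
             "rheumatoid_arthritis", "hypersensitivity",
             "asthma", "copd",
             "macular_degeneration", "glaucoma"),
    class = c("neoplasms", "neoplasms", "neoplasms",
              "nutritional_metabolic", "nutritional_metabolic",
              "nervous", "nervous",
              "cardiovascular", "cardiovascular",
              "musculoskeletal", "musculoskeletal",
              "immune", "immune",
              "respiratory", "respiratory",
              "eye", "eye"),
    size = c(80L, 60L, 55L, 70L, 50L, 65L, 45L, 60L, 50L,
             40L, 35L, 45L, 30L, 40L, 30L, 15L, 12L),
    planted_or = c(6, 6, 6, 6, 6, 4, 4, 4, 4, 3, 3, 1.5, 1.5, 1, 1, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic drug layout
#'
#' A handful of direction-matched drugs (a large fraction of their targets
#' drawn from the matching longevity set) among a background of drugs with
#' random targets.
#'
#' @param n_background number of unmatched background drugs.
#' @return data.frame with columns `name`, `direction`, `n_targets`,
#'   `frac_matched`.
#' @export
default_drug_layout <- function(n_background = 37) {
  matched <- data.frame(
    name = c("geromir_a", "geromir_b", "geromir_c"),
    direction = c("Anti", "Pro", "Anti"),
    n_targets = c(10L, 12L, 8L),
    frac_matched = c(0.8, 0.75, 0.8),
    stringsAsFactors = FALSE
  )
  bg <- data.frame(
    name = sprintf("drug_%02d", seq_len(n_background)),
    direction = rep(c("Anti", "Pro"), length.out = n_background),
    n_targets = rep(c(5L, 8L, 12L, 15L, 20L), length.out = n_background),
    frac_matched = 0,
    stringsAsFactors = FALSE
  )
  rbind(matched, bg)
}

#' Synthetic benchmark configuration
#'
#' The defaults state the benchmark's world: genome of 5,000 genes (about
#' 1/4 of the 20,183-gene human genome, to keep the full pipeline fast),
#' 74% of it in the interactome, preferential-attachment interactome with 2
#' edges per new node (mean degree ~4, matching the heavy-tailed, sparse
#' real interactome), negative-binomial publication counts whose mean
#' scales with degree (calibrated so the publication-degree Spearman
#' correlation is ~0.67), aging sets mildly enriched for hubs, disease sets
#' planted at class-specific odds ratios (respiratory = 1, the negative
#' control), sparse co-expression pairs, and lognormal dN/dS with a +50%
#' location shift for disease genes (0.137 vs 0.091 medians).
#'
#' @param seed master seed; every component derives its own sub-seed, so
#'   identical configs yield byte-identical bundles.
#' @param n_genes genome size.
#' @param interactome_fraction fraction of the genome in the interactome.
#' @param ppi_attachment preferential-attachment edges per new node.
#' @param pubs_scale,pubs_degree_exponent,pubs_dispersion publication-count
#'   model: counts ~ NegBin(mu = scale * (degree+1)^exponent,
#'   size = dispersion).
#' @param aging_hub_bias exponent of the degree weight used when sampling
#'   aging genes (0 = uniform).
#' @param aging_sets,disease_sets,drugs layout data.frames (see
#'   [default_aging_layout()], [default_disease_layout()],
#'   [default_drug_layout()]).
#' @param coexpr_n_random number of background co-expression pairs.
#' @param coexpr_planted_pairs number of planted significant pairs attached
#'   to aging genes.
#' @param dnds_lognormal_mu,dnds_lognormal_sigma lognormal parameters of the
#'   genome dN/dS ratio distribution.
#' @param disease_shift multiplicative dN/dS shift applied to disease genes.
#' @param ds_zero_fraction fraction of genes with dS = 0 (undefined ratio).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 5000,
                       interactome_fraction = 0.74,
                       ppi_attachment = 2,
                       pubs_scale = 2.2,
                       pubs_degree_exponent = 1,
                       pubs_dispersion = 20,
                       aging_hub_bias = 1,
                       aging_sets = default_aging_layout(),
                       disease_sets = default_disease_layout(),
                       drugs = default_drug_layout(),
                       coexpr_n_random = 2000,
                       coexpr_planted_pairs = 150,
                       dnds_lognormal_mu = log(0.091),
                       dnds_lognormal_sigma = 0.6,
                       disease_shift = 1.5,
                       ds_zero_fraction = 0.01) {
  cfg <- list(seed = seed, n_genes = as.integer(n_genes),
              interactome_fraction = interactome_fraction,
              ppi_attachment = as.integer(ppi_attachment),
              pubs_scale = pubs_scale,
              pubs_degree_exponent = pubs_degree_exponent,
              pubs_dispersion = pubs_dispersion,
              aging_hub_bias = aging_hub_bias,
              aging_sets = aging_sets, disease_sets = disease_sets,
              drugs = drugs,
              coexpr_n_random = as.integer(coexpr_n_random),
              coexpr_planted_pairs = as.integer(coexpr_planted_pairs),
              dnds_lognormal_mu = dnds_lognormal_mu,
              dnds_lognormal_sigma = dnds_lognormal_sigma,
              disease_shift = disease_shift,
              ds_zero_fraction = ds_zero_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 10) stop("n_genes too small")
  if (cfg$ppi_attachment < 1) stop("ppi_attachment must be >= 1")
  if (cfg$interactome_fraction <= 0 || cfg$interactome_fraction > 1) {
    stop("interactome_fraction must lie in (0, 1]")
  }
  if (any(cfg$aging_sets$size > cfg$n_genes) ||
      any(cfg$disease_sets$size > cfg$n_genes)) {
    stop("a configured set size exceeds n_genes")
  }
  if (any(cfg$disease_sets$planted_or < 1)) {
    stop("planted odds ratios must be >= 1")
  }
  if (any(cfg$drugs$frac_matched < 0 | cfg$drugs$frac_matched > 1)) {
    stop("frac_matched must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Generate a preferential-attachment interaction graph
#'
#' Barabasi-Albert-style growth: each new node attaches to `attachment`
#' existing nodes with probability proportional to degree, yielding the
#' heavy-tailed degree distribution characteristic of protein interaction
#' networks. The result is connected, simple and undirected, with mean
#' degree approaching `2 * attachment`.
#'
#' @param n number of nodes (> attachment).
#' @param attachment edges added per new node (>= 1).
#' @param seed RNG seed.
#' @return an igraph object with vertices named `V1..Vn`.
#' @export
generate_ppi <- function(n, attachment, seed = 1) {
  if (attachment < 1) stop("attachment must be >= 1")
  if (n <= attachment) stop("n must exceed attachment")
  g <- with_seed(seed, {
    igraph::sample_pa(n, power = 1, m = attachment, directed = FALSE)
  })
  igraph::V(g)$name <- paste0("V", seq_len(n))
  igraph::simplify(g)
}

#' Sample a gene set with a planted membership odds ratio
#'
#' Weighted sampling without replacement in which genes of `base` carry
#' `or_` times the membership odds of genes outside it; `or_ = 1` is a
#' uniform draw, and as `or_` grows the sample concentrates inside `base`.
#'
#' @param universe character vector to sample from.
#' @param base character vector of favored genes.
#' @param size sample size.
#' @param or_ membership odds ratio (>= 0).
#' @param seed RNG seed.
#' @return character vector of `size` sampled genes.
#' @export
plant_overlap <- function(universe, base, size, or_ = 1, seed = 1) {
  if (size > length(universe)) stop("size exceeds universe")
  w <- ifelse(universe %in% base, or_, 1)
  with_seed(seed, sample(universe, size, replace = FALSE, prob = w))
}

# Sample aging sets hub-biased and disjointly within an organism.
sample_aging_sets <- function(cfg, genes, deg_all, seed) {
  layout <- cfg$aging_sets
  w <- (deg_all + 1)^cfg$aging_hub_bias
  sets <- list()
  with_seed(seed, {
    taken_by_org <- list()
    for (i in seq_len(nrow(layout))) {
      org <- layout$organism[[i]]
      avail <- setdiff(genes, taken_by_org[[org]])
      idx <- match(avail, genes)
      members <- sample(avail, layout$size[[i]], prob = w[idx])
      taken_by_org[[org]] <- c(taken_by_org[[org]], members)
      sets[[layout$name[[i]]]] <- labeled_gene_set(
        layout$name[[i]], members, organism = org,
        longevity_class = layout$class[[i]])
    }
  })
  for (cls in c("anti", "pro")) {
    members <- unique(unlist(lapply(sets, function(s) {
      if (s$longevity_class == cls && s$organism != "human") s$members
      else character(0)
    }), use.names = FALSE))
    nm <- paste0("all_orthologs_", cls)
    sets[[nm]] <- labeled_gene_set(nm, members, organism = "all_orthologs",
                                   longevity_class = cls)
  }
  sets
}

#' Generate the full synthetic benchmark bundle
#'
#' Produces every input the pipeline consumes, plus a manifest recording the
#' planted truth (enriched disease sets and their odds ratios, matched
#' drugs, dN/dS shift). With `out_dir` set, writes the plain-text bundle:
#' `universe.tsv`, `ppi.tsv`, `pubs.tsv`, `aging.gmt`, `diseases.tsv`,
#' `coexpr.tsv`, `drugs.tsv`, `dnds.tsv`, `manifest.json`. Identical
#' configurations yield byte-identical bundles.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory (created if needed).
#' @return (invisibly, when writing) a list with components `universe`
#'   ([gene_universe()]), `graph` (igraph), `edges`, `pub_count`,
#'   `aging_sets`, `catalog` ([disease_catalog()]), `coexpr`, `drug_table`,
#'   `dnds`, `manifest`.
#' @export
generate_benchmark <- function(cfg, out_dir = NULL) {
  validate_sim_config(cfg)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_ppi <- round(cfg$n_genes * cfg$interactome_fraction)

  g <- generate_ppi(n_ppi, cfg$ppi_attachment,
                    seed = component_seed(cfg$seed, "ppi"))
  interactome_genes <- genes[seq_len(n_ppi)]
  igraph::V(g)$name <- interactome_genes

  deg_all <- stats::setNames(rep(0, cfg$n_genes), genes)
  deg_all[interactome_genes] <- igraph::degree(g)

  pubs <- with_seed(component_seed(cfg$seed, "pubs"), {
    mu <- cfg$pubs_scale * (deg_all + 1)^cfg$pubs_degree_exponent
    stats::setNames(stats::rnbinom(cfg$n_genes, size = cfg$pubs_dispersion,
                                   mu = mu), genes)
  })

  aging_sets <- sample_aging_sets(cfg, genes, deg_all,
                                  component_seed(cfg$seed, "aging"))
  aging_union <- unique(unlist(lapply(aging_sets, `[[`, "members"),
                               use.names = FALSE))

  layout <- cfg$disease_sets
  diseases <- list()
  for (i in seq_len(nrow(layout))) {
    diseases[[layout$name[[i]]]] <- plant_overlap(
      genes, aging_union, layout$size[[i]], layout$planted_or[[i]],
      seed = component_seed(cfg$seed, paste0("disease_", layout$name[[i]])))
  }
  catalog <- disease_catalog(diseases,
                             stats::setNames(layout$class, layout$name))
  disease_union <- unique(unlist(diseases, use.names = FALSE))

  coexpr <- with_seed(component_seed(cfg$seed, "coexpr"), {
    thr <- coexpression_threshold(0.05, cfg$n_genes)
    seeds <- sample(aging_union, cfg$coexpr_planted_pairs, replace = TRUE)
    partners <- sample(setdiff(genes, aging_union),
                       cfg$coexpr_planted_pairs, replace = TRUE)
    planted <- data.frame(gene_a = seeds, gene_b = partners,
                          p = stats::runif(cfg$coexpr_planted_pairs,
                                           0, thr / 10),
                          stringsAsFactors = FALSE)
    rnd <- data.frame(gene_a = sample(genes, cfg$coexpr_n_random, TRUE),
                      gene_b = sample(genes, cfg$coexpr_n_random, TRUE),
                      p = stats::runif(cfg$coexpr_n_random),
                      stringsAsFactors = FALSE)
    out <- rbind(planted, rnd)
    out[out$gene_a != out$gene_b, , drop = FALSE]
  })

  anti_all <- aging_sets$all_orthologs_anti$members
  pro_all <- aging_sets$all_orthologs_pro$members
  drug_table <- with_seed(component_seed(cfg$seed, "drugs"), {
    anti_types <- c("inhibitor", "antagonist", "blocker")
    pro_types <- c("agonist", "activator", "inducer")
    rows <- lapply(seq_len(nrow(cfg$drugs)), function(i) {
      d <- cfg$drugs[i, ]
      matched_set <- if (d$direction == "Anti") anti_all else pro_all
      n_match <- round(d$n_targets * d$frac_matched)
      tmatch <- sample(matched_set, min(n_match, length(matched_set)))
      trest <- sample(setdiff(genes, tmatch), d$n_targets - length(tmatch))
      types <- if (d$direction == "Anti") anti_types else pro_types
      data.frame(drug = d$name, gene = c(tmatch, trest),
                 interaction_type = sample(types, d$n_targets, TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  dnds <- with_seed(component_seed(cfg$seed, "dnds"), {
    ds <- stats::rlnorm(cfg$n_genes, meanlog = log(0.2), sdlog = 0.5)
    ratio <- stats::rlnorm(cfg$n_genes, meanlog = cfg$dnds_lognormal_mu,
                           sdlog = cfg$dnds_lognormal_sigma)
    shift <- ifelse(genes %in% disease_union, cfg$disease_shift, 1)
    zero <- stats::runif(cfg$n_genes) < cfg$ds_zero_fraction
    ds[zero] <- 0
    data.frame(gene = genes, dn = ratio * shift * ds, ds = ds,
               stringsAsFactors = FALSE)
  })

  universe <- gene_universe(genes, pub_count = pubs,
                            dn = stats::setNames(dnds$dn, dnds$gene),
                            ds = stats::setNames(dnds$ds, dnds$gene),
                            in_interactome = interactome_genes)

  manifest <- list(
    seed = cfg$seed, n_genes = cfg$n_genes,
    disease_truth = layout,
    drug_truth = cfg$drugs,
    disease_shift = cfg$disease_shift,
    aging_layout = cfg$aging_sets
  )

  bundle <- list(universe = universe, graph = g,
                 edges = as.data.frame(stats::setNames(
                   as.data.frame(igraph::as_edgelist(g),
                                 stringsAsFactors = FALSE),
                   c("gene_a", "gene_b"))),
                 pub_count = pubs, aging_sets = aging_sets,
                 catalog = catalog, coexpr = coexpr,
                 drug_table = drug_table, dnds = dnds, manifest = manifest)
  if (!is.null(out_dir)) write_benchmark(bundle, out_dir)
  invisible(bundle)
}

write_benchmark <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  u <- bundle$universe
  write_tsv(data.frame(gene = u$genes,
                       in_interactome = as.integer(u$genes %in% u$in_interactome)),
            file.path(out_dir, "universe.tsv"))
  edges <- bundle$edges
  edges$interaction_type <- "physical association"
  write_tsv(edges, file.path(out_dir, "ppi.tsv"))
  write_tsv(data.frame(gene = names(bundle$pub_count),
                       pub_count = as.integer(bundle$pub_count)),
            file.path(out_dir, "pubs.tsv"))
  write_gene_sets(bundle$aging_sets, file.path(out_dir, "aging.gmt"))
  dis <- bundle$catalog$diseases
  long <- data.frame(
    disease_id = rep(names(dis), lengths(dis)),
    class = rep(unname(bundle$catalog$disease_class[names(dis)]), lengths(dis)),
    gene = unlist(dis, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(long, file.path(out_dir, "diseases.tsv"))
  write_tsv(bundle$coexpr, file.path(out_dir, "coexpr.tsv"))
  write_tsv(bundle$drug_table, file.path(out_dir, "drugs.tsv"))
  write_tsv(bundle$dnds, file.path(out_dir, "dnds.tsv"))
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
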