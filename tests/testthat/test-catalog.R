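test_that("GMT reading dedups, case-normalizes and enforces the line format", {
  path <- write_lines_tmp(c(
    "worm_pro\tdesc\tDAF16\tdaf16",
    "mouse_anti\tdesc\tIGF1R\tTP53\tMTOR"
  ), ext = ".gmt")
  sets <- read_gene_sets(path)
  expect_length(sets, 2)
  expect_equal(sets[[1]]$members, "DAF16")
  expect_equal(sets[[1]]$organism, "worm")
  expect_equal(sets[[1]]$longevity_class, "pro")
  expect_equal(sets[[2]]$organism, "mouse")
  expect_setequal(sets[[2]]$members, c("IGF1R", "TP53", "MTOR"))

  bad <- write_lines_tmp(c("ok_human\td\tG1", "two_fields\tonly"), ext = ".gmt")
  expect_error(read_gene_sets(bad), "line 2")
  empty <- write_lines_tmp("human\tdesc\t\t ", ext = ".gmt")
  expect_error(read_gene_sets(empty), "empty member list")
})

test_that("the canonical 11-set naming scheme parses into 11 labeled sets", {
  names11 <- c("human", "mouse_anti", "mouse_pro", "fly_anti", "fly_pro",
               "worm_anti", "worm_pro", "yeast_anti", "yeast_pro",
               "all_orthologs_anti", "all_orthologs_pro")
  path <- write_lines_tmp(sprintf("%s\tdesc\tG%d\tG%d", names11,
                                  seq_along(names11), 100 + seq_along(names11)),
                          ext = ".gmt")
  sets <- read_gene_sets(path)
  expect_length(sets, 11)
  expect_equal(vapply(sets, `[[`, character(1), "name"), names11)
  expect_equal(sets[[1]]$longevity_class, "human_candidate")
  expect_equal(sets[[10]]$organism, "all_orthologs")
})

test_that("assemble_longevity_sets applies the exclusion rules", {
  raw <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    organism = c("worm", "worm", "worm", "mouse"),
    class_annotation = c("pro", "anti", "pro", "unclear"))
  sets <- assemble_longevity_sets(raw)
  expect_equal(sets$worm_pro$members, "G2")
  expect_length(sets$worm_anti$members, 0)
  expect_length(sets$mouse_pro$members, 0)
  expect_length(sets$mouse_anti$members, 0)
  expect_error(assemble_longevity_sets(
    data.frame(gene = "g", organism = "zebrafish", class_annotation = "pro")),
    "unknown organism")
})

test_that("all-ortholog unions pool the model organisms and stay disjoint per organism", {
  raw <- data.frame(
    gene = c("a", "b", "c", "d", "a"),
    organism = c("mouse", "fly", "worm", "yeast", "worm"),
    class_annotation = c("pro", "pro", "anti", "anti", "pro"))
  sets <- assemble_longevity_sets(raw)
  expect_setequal(sets$all_orthologs_pro$members, c("A", "B"))
  expect_setequal(sets$all_orthologs_anti$members, c("C", "D"))
  for (org in c("mouse", "fly", "worm", "yeast")) {
    expect_length(intersect(sets[[paste0(org, "_pro")]]$members,
                            sets[[paste0(org, "_anti")]]$members), 0)
  }
})

test_that("disease catalog filtering enforces size, class and eye/control rules", {
  cat20 <- filter_disease_catalog(toy_catalog(), min_genes = 20)
  ind <- disease_gene_sets(cat20, "individual")
  # 19-gene disease out, 20+ retained
  expect_false("rare_small" %in% names(ind))
  expect_true(all(c("breast_neoplasm", "lung_neoplasm", "alzheimer",
                    "asthma") %in% names(ind)))
  # eye excluded individually but present at class level
  expect_false("cataract" %in% names(ind))
  cls <- disease_gene_sets(cat20, "class")
  expect_true("eye" %in% names(cls))
  # respiratory retained, tagged negative control
  expect_true("respiratory" %in% names(cls))
  expect_equal(cat20$negative_control_classes, "respiratory")
  # boundary: exactly min_genes retained
  expect_true(all(lengths(ind) >= 20))
})

test_that("catalog union sets satisfy their set identities", {
  cat20 <- filter_disease_catalog(toy_catalog(), min_genes = 20)
  unions <- catalog_union_sets(cat20)
  ind <- disease_gene_sets(cat20, "individual")
  expect_setequal(unions$all_diseases, unique(unlist(ind)))
  expect_lte(length(unions$all_diseases), sum(lengths(ind)))
  cls <- disease_gene_sets(cat20, "class")
  expect_setequal(unions$all_classes, unique(unlist(cls)))
  for (cn in names(cls)) {
    ids <- names(cat20$diseases)[cat20$disease_class == cn &
                                 cat20$included_class]
    expect_setequal(cls[[cn]], unique(unlist(cat20$diseases[ids])))
  }
})

test_that("edge lists are deduplicated, de-looped and type-filtered", {
  path <- write_lines_tmp(c(
    "gene_a\tgene_b\tinteraction_type",
    "a\tb\tphysical association",
    "b\ta\tdirect interaction",
    "a\ta\tphysical association",
    "a\tc\tcolocalization"))
  edges <- read_edge_list(path)
  expect_equal(nrow(edges), 1)
  expect_setequal(unlist(edges[1, ]), c("A", "B"))
  all_edges <- read_edge_list(path, allowed_types = NULL)
  expect_equal(nrow(all_edges), 2)
})

test_that("annotation tables are keyed uniquely and read back identically", {
  path <- write_lines_tmp(c("gene\tpub_count", "g1\t12", "g2\t3"))
  pubs <- read_annotation_table(path)
  expect_equal(unname(pubs["G1"]), 12)
  conflict <- write_lines_tmp(c("gene\tpub_count", "g1\t12", "G1\t5"))
  expect_error(read_annotation_table(conflict), "G1")
})

test_that("tables round-trip losslessly up to row order", {
  sets <- list(labeled_gene_set("worm_pro", c("a", "b"), "worm", "pro"),
               labeled_gene_set("human", c("x", "y", "z"), "human",
                                "human_candidate"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, gmt)
  back <- read_gene_sets(gmt)
  expect_equal(lapply(back, `[[`, "members"), lapply(sets, `[[`, "members"))
  expect_equal(vapply(back, `[[`, character(1), "longevity_class"),
               vapply(sets, `[[`, character(1), "longevity_class"))
})

test_that("universe construction drops foreign annotations with a warning", {
  expect_warning(
    u <- gene_universe(c("g1", "g2"), pub_count = c(G1 = 5, GX = 2)),
    "dropped")
  expect_equal(unname(publication_counts(u, c("g1", "g2", "g3"))), c(5, 0, 0))
  expect_error(gene_universe("g1", pub_count = c(G1 = -1)), "non-negative")
})
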