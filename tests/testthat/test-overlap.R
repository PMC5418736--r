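test_that("hypergeometric tail matches exact enumeration on anchor cases", {
  # C(5,3)C(15,1) + C(5,4)C(15,0) over C(20,4) = 155/4845
  expect_equal(hypergeometric_tail(3, 5, 4, 20), 155 / 4845, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(0, 7, 3, 20), 1.0)
  expect_equal(hypergeometric_tail(3, 10, 3, 10), 1.0)  # overlap forced
  expect_error(hypergeometric_tail(4, 5, 3, 20), "k must not exceed n")
  expect_error(hypergeometric_tail(1, 25, 3, 20), "K must not exceed N")
})

test_that("overlap_test fills the contingency and applies the dual rule", {
  bg <- sprintf("g%02d", 1:20)
  A <- labeled_gene_set("aging", bg[1:5], "worm", "pro")
  B <- bg[3:6]
  r <- overlap_test(A, B, bg)
  expect_equal(r$background_size, 20)
  expect_equal(r$n_aging, 5)
  expect_equal(r$n_disease, 4)
  expect_equal(r$observed, 3)
  expect_equal(r$expected, 1.0)
  expect_equal(r$p_value, 155 / 4845, tolerance = 1e-12)
  expect_true(r$significant)
  expect_equal(strsplit(r$cad_genes, ";")[[1]], toupper(bg[3:5]))

  # rule i fails: nothing observed
  r0 <- overlap_test(bg[1:5], bg[11:14], bg)
  expect_equal(r0$observed, 0)
  expect_false(r0$significant)

  # observed below expectation is never significant, whatever p does
  r2 <- overlap_test(bg[1:10], c(bg[10], bg[11:19]), bg)
  expect_lt(r2$observed, r2$expected)
  expect_false(r2$significant)

  # empty set after background restriction: warning, p = 1
  expect_warning(re <- overlap_test("zz", bg[1:3], bg), "empty set")
  expect_equal(re$p_value, 1)
  expect_false(re$significant)
})

test_that("overlap p-value is symmetric in the two sets", {
  set.seed(5)
  bg <- sprintf("g%03d", 1:300)
  for (i in 1:10) {
    A <- sample(bg, sample(10:60, 1))
    B <- sample(bg, sample(10:60, 1))
    expect_equal(overlap_test(A, B, bg)$p_value,
                 overlap_test(B, A, bg)$p_value, tolerance = 1e-12)
  }
})

test_that("the overlap grid enumerates sets, unions and background policies", {
  bg_genes <- sprintf("g%02d", 1:80)
  diseases <- list(d1 = bg_genes[1:25], d2 = bg_genes[20:45],
                   d3 = bg_genes[40:65])
  catalog <- filter_disease_catalog(disease_catalog(
    diseases, c(d1 = "neoplasms", d2 = "nervous", d3 = "cardiovascular")))
  universe <- gene_universe(bg_genes, in_interactome = bg_genes[1:50])
  aging <- list(labeled_gene_set("s1", bg_genes[1:10], "worm", "pro"),
                labeled_gene_set("s2", bg_genes[30:42], "worm", "anti"))
  grid <- run_overlap_grid(aging, catalog, universe, "genome", "individual")
  expect_equal(nrow(grid), 2 * (3 + 2))
  expect_true(all(c("all_diseases", "all_classes") %in% grid$disease_set))
  expect_true(all(grid$background_size == 80))
  # interactome policy shrinks N but the grid shape is unchanged
  grid_i <- run_overlap_grid(aging, catalog, universe, "interactome",
                             "individual")
  expect_equal(nrow(grid_i), nrow(grid))
  expect_true(all(grid_i$background_size == 50))
  # observed counts can only shrink when the background shrinks
  expect_true(all(grid_i$observed <= grid$observed))
  # seed_union adds the seed and disease genes to the interactome
  bg_su <- resolve_background("seed_union", universe, seed = aging[[2]],
                              disease_genes = unlist(diseases))
  expect_setequal(bg_su, toupper(unique(c(bg_genes[1:50], aging[[2]]$members,
                                          unlist(diseases)))))
  bg_si <- resolve_background("seed_interactome", universe, seed = aging[[2]])
  expect_true(all(bg_si %in% bg_su))
  expect_error(run_overlap_grid(aging, catalog, universe, "nonsense"),
               "'arg'")
})

test_that("CAD extraction returns the stored intersections", {
  bg <- sprintf("g%02d", 1:40)
  catalog <- filter_disease_catalog(disease_catalog(
    list(d1 = bg[1:22], d2 = bg[19:40]),
    c(d1 = "neoplasms", d2 = "nervous")))
  universe <- gene_universe(bg)
  aging <- list(labeled_gene_set("s1", bg[15:24], "mouse", "pro"))
  grid <- run_overlap_grid(aging, catalog, universe, "genome", "individual")
  cad <- extract_cad_genes(grid)
  expect_equal(length(cad), nrow(grid))
  for (i in seq_len(nrow(grid))) {
    expect_length(cad[[i]], grid$observed[[i]])
  }
  expect_setequal(cad[["s1|d1"]], toupper(bg[15:22]))
  # disjoint sets give the empty set
  grid2 <- run_overlap_grid(list(labeled_gene_set("s2", bg[30:35])),
                            catalog, universe, "genome", "individual")
  expect_length(extract_cad_genes(grid2)[["s2|d1"]], 0)
})

test_that("grid summaries count significant diseases per aging set", {
  bg <- sprintf("g%03d", 1:500)
  catalog <- filter_disease_catalog(disease_catalog(
    list(hit = bg[1:30], miss = bg[301:330]),
    c(hit = "neoplasms", miss = "nervous")))
  universe <- gene_universe(bg)
  aging <- list(labeled_gene_set("a", bg[1:25], "worm", "pro"))
  grid <- run_overlap_grid(aging, catalog, universe, "genome", "individual")
  s <- summarize_overlap_grid(grid)
  expect_equal(s$n_tested, 2)
  expect_equal(s$n_significant, 1)
})

test_that("escore transforms and the co-expression threshold are exact", {
  expect_equal(p_to_escore(0.05), -log10(0.05))
  expect_equal(escore_to_p(p_to_escore(0.003)), 0.003, tolerance = 1e-12)
  expect_equal(coexpression_threshold(0.05, 20183), 0.05 / 20183)
  expect_error(p_to_escore(0), "\\(0, 1\\]")
  expect_error(coexpression_threshold(0.05, 0), "positive")
})
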