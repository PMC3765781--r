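# Cross-extraction concordance, presence/absence, dilution ratios, Fisher.

test_that("cross-extraction classification assigns the documented categories", {
  focal <- make_de_result(
    c("g1", "g2", "g3", "g4", "g5"),
    call = c("DE", "DE", "DE", "DE", "not_DE"),
    direction = c("up_in_nurse", "up_in_nurse", "up_in_forager",
                  "up_in_nurse", "none"))
  comp <- make_de_result(
    c("g1", "g2", "g3"),
    call = c("not_DE", "DE", "DE"),
    direction = c("none", "up_in_nurse", "up_in_nurse"),
    extraction = "composite")
  ct <- classify_cross_extraction(focal, comp)
  cats <- stats::setNames(ct$categories$category, ct$categories$gene_id)
  expect_equal(unname(cats["g1"]), "not_sig")            # not DE in composite
  expect_equal(unname(cats["g2"]), "same_direction")
  expect_equal(unname(cats["g3"]), "opposite_direction") # direction flipped
  expect_equal(unname(cats["g4"]), "not_sig")            # absent from composite
  expect_false("g5" %in% names(cats))                    # only focal-DE genes
  # partition invariant
  expect_equal(ct$n_focal_de,
               ct$n_not_sig + ct$n_same_direction + ct$n_opposite_direction)
  expect_equal(ct$n_focal_de, 4)
})

test_that("classification refuses to compare across methods", {
  focal <- make_de_result("g1", "DE", "up_in_nurse", method = "nb_exact")
  comp <- make_de_result("g1", "DE", "up_in_nurse", method = "noiseq_like",
                         extraction = "composite")
  expect_error(classify_cross_extraction(focal, comp), "like with like")
})

test_that("subset analysis restricts and degenerates correctly", {
  focal <- make_de_result(c("g1", "g2", "g3"), rep("DE", 3),
                          rep("up_in_nurse", 3))
  comp <- make_de_result(c("g1", "g2", "g3"), rep("not_DE", 3), rep("none", 3),
                         extraction = "composite")
  full <- classify_cross_extraction(focal, comp)
  all_genes <- subset_analysis(focal, comp, c("g1", "g2", "g3"))
  expect_equal(all_genes$n_not_sig, full$n_not_sig)
  disjoint <- subset_analysis(focal, comp, "g999") |> suppressWarnings()
  expect_equal(disjoint$n_focal_de, 0)
  expect_warning(subset_analysis(focal, comp, c("g1", "gX")), "not found")
  expect_error(subset_analysis(focal, comp, character(0)), "non-empty")
})

test_that("presence/absence sets are disjoint, binned, and respect tau", {
  # g1: focal 15 / composite 5 -> focal-only; g2 above tau in both;
  # g3 composite-only; g4 high-expression focal-only
  rpkm <- cbind(f = c(15, 30, 5, 800), c = c(5, 30, 12, 5))
  rownames(rpkm) <- paste0("g", 1:4)
  x <- structure(list(
    rpkm = rpkm,
    samples = data.frame(sample_id = c("f", "c"),
                         extraction = c("focal", "composite"),
                         condition = "nurse", replicate = 1L),
    gene_lengths = stats::setNames(rep(1000, 4), rownames(rpkm))),
    class = "rpkm_matrix")
  pa <- presence_absence_table(x, "focal", "composite", "nurse", tau = 10)
  expect_setequal(pa$focal_only$gene_id, c("g1", "g4"))
  expect_equal(pa$composite_only$gene_id, "g3")
  expect_equal(as.character(pa$composite_only$bin), "(10,30]")
  expect_length(intersect(pa$focal_only$gene_id, pa$composite_only$gene_id), 0)
  # g4 present at 800 RPKM in focal -> top bin
  expect_equal(as.character(pa$focal_only$bin[pa$focal_only$gene_id == "g4"]),
               "(300,Inf]")
  expect_equal(sum(pa$focal_only_bins), nrow(pa$focal_only))
  expect_error(presence_absence_table(x, "focal", "composite", "nurse",
                                      tau = -1), "positive")
})

test_that("a high-expression tissue-exclusive gene can vanish from the
           composite transcriptome", {
  m <- excl_model(w1 = 0.02, n_shared = 2000, excl_abundance = 20,
                  base_seed = 3)
  cm <- combine_count_matrices(
    simulate_extraction_counts(m, "gland", "nurse", 2, 2e5, seed = 8),
    simulate_extraction_counts(m, "composite", "nurse", 2, 2e5, seed = 8))
  rp <- compute_rpkm(cm)
  pa <- presence_absence_table(rp, "gland", "composite", "nurse")
  hit <- pa$focal_only[pa$focal_only$gene_id == "g2001", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$rpkm, 100)
})

test_that("dilution ratios partition genes with the documented boundaries", {
  rpkm <- cbind(f = c(50, 100, 30, 0), c = c(50, 0, 10, 5))
  rownames(rpkm) <- paste0("g", 1:4)
  x <- structure(list(
    rpkm = rpkm,
    samples = data.frame(sample_id = c("f", "c"),
                         extraction = c("focal", "composite"),
                         condition = "nurse", replicate = 1L),
    gene_lengths = stats::setNames(rep(1000, 4), rownames(rpkm))),
    class = "rpkm_matrix")
  dr <- dilution_ratios(x, "focal", "composite", "nurse", paste0("g", 1:4))
  expect_equal(dr$n_above_1, 1)        # g3: 30/10 = 3
  expect_equal(dr$n_at_or_below_1, 2)  # g1: exactly 1; g4: 0/5 = 0
  expect_equal(dr$n_undefined, 1)      # g2: composite RPKM 0
  expect_equal(dr$n_above_1 + dr$n_at_or_below_1 + dr$n_undefined, 4)
  expect_error(dilution_ratios(x, "focal", "composite", "nurse",
                               character(0)), "non-empty")
})

test_that("Fisher's exact test matches enumeration and handles edge tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  fr <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))
  expect_equal(fr$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(fr$odds_ratio, 9)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "margin")
  # infinity convention for the sample odds ratio
  expect_identical(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$odds_ratio, Inf)
})

test_that("Fisher p is invariant to jointly swapping rows and columns", {
  set.seed(15)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20), 2)
    p1 <- fisher_exact_2x2(tab)$p_value
    p2 <- fisher_exact_2x2(tab[2:1, 2:1])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("focal-tissue comparisons build the documented 2x2 tables", {
  a <- concordance_table(20, 8, 2, focal = "gland")
  b <- concordance_table(40, 16, 4, focal = "gut")
  fr <- compare_focal_tissues(a, b)
  expect_equal(unname(fr$table),
               rbind(c(20, 10), c(40, 20)))
  expect_gte(fr$p_value, 0.99)   # literally proportional tables
  da <- dilution_ratio_set(30, 10)
  db <- dilution_ratio_set(60, 20)
  expect_gte(compare_focal_tissues(da, db)$p_value, 0.99)
  expect_error(compare_focal_tissues(a, db), "same type")
})

test_that("constructors validate counts and reconcile per-gene categories", {
  expect_error(concordance_table(-1, 0, 0), "non-negative")
  expect_error(dilution_ratio_set(1.5, 0), "non-negative")
  cats <- data.frame(gene_id = c("g1", "g2"),
                     category = c("not_sig", "same_direction"))
  expect_error(concordance_table(2, 0, 0, categories = cats), "reconcile")
  ok <- concordance_table(1, 1, 0, categories = cats)
  expect_equal(ok$n_focal_de, 2)
})
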