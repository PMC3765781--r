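# Tissue-mixture model construction and homogenization sampling.

test_that("model construction rejects invalid inputs", {
  bad <- data.frame(name = c("a", "b"), mass_fraction = c(0.5, 0.6),
                    dispersion = 0.1)
  expect_error(build_mixture_model(effect_config(n_genes = 10), bad),
               "sum to 1")
  expect_error(effect_config(n_genes = 0), "positive integer")
  expect_error(effect_config(de_fraction = 1.2),
               class = "compexr_validation_error")
  expect_error(effect_config(exclusive_fraction = 0.7,
                             opposite_fraction = 0.4), "<= 1")
  lam <- array(0, dim = c(2, 1, 2))
  lam[1, 1, ] <- 1   # gene 2 has zero abundance everywhere
  expect_error(mixture_model(lam, c(1000, 1000),
                             data.frame(name = "t", mass_fraction = 1,
                                        dispersion = 0.1)),
               "positive abundance")
})

test_that("a no-effect configuration produces a flat model", {
  eff <- effect_config(n_genes = 10, de_fraction = 0, seed = 1)
  m <- build_mixture_model(eff, data.frame(name = "t", mass_fraction = 1,
                                           dispersion = 0.1))
  expect_true(all(m$truth$label == "not_DE"))
  expect_equal(m$abundance[, , 1], m$abundance[, , 2])
})

test_that("model construction and count simulation are deterministic", {
  eff <- effect_config(n_genes = 100, seed = 3)
  expect_identical(build_mixture_model(eff), build_mixture_model(eff))
  m <- build_mixture_model(eff)
  c1 <- simulate_extraction_counts(m, "gland", "nurse", 2, 1e5, seed = 5)
  c2 <- simulate_extraction_counts(m, "gland", "nurse", 2, 1e5, seed = 5)
  expect_identical(c1$counts, c2$counts)
})

test_that("truth labels agree with abundances and effect sizes match the
           configured distribution", {
  eff <- effect_config(n_genes = 1000, de_fraction = 0.1,
                       log2fc_location = 2, log2fc_scale = 0.5,
                       exclusive_fraction = 0, opposite_fraction = 0,
                       seed = 21)
  m <- build_mixture_model(eff, data.frame(name = "t", mass_fraction = 1,
                                           dispersion = 0.1))
  # labels recomputed from abundances
  l1 <- m$abundance[, 1, 1]; l2 <- m$abundance[, 1, 2]
  expect_identical(m$truth$label == "up_in_nurse", unname(l1 > l2))
  expect_identical(m$truth$label == "up_in_forager", unname(l1 < l2))
  de <- m$truth[m$truth$label != "not_DE", ]
  expect_equal(nrow(de), 100)
  # oracle: E|N(2, 0.5)| = 2 up to Monte-Carlo error at n = 100
  expect_lt(abs(mean(abs(de$log2fc)) - 2), 0.15)
})

test_that("homogenization fractions behave at the grain-count limits", {
  w <- c(a = 0.3, b = 0.7)
  expect_identical(sample_homogenization_fractions(homogenization_spec(Inf), w),
                   w)
  f1 <- sample_homogenization_fractions(homogenization_spec(1, seed = 4), w)
  expect_equal(sort(unname(f1)), c(0, 1))
  expect_equal(sum(f1), 1)
  expect_error(homogenization_spec(0), "positive integer")
})

test_that("realized fractions have binomial variance, shrinking in grains", {
  w <- c(0.02, 0.98)
  set.seed(1)
  fr <- replicate(10000,
                  sample_homogenization_fractions(homogenization_spec(100), w)[1])
  expect_lt(abs(var(fr) / (0.02 * 0.98 / 100) - 1), 0.15)
  vars <- vapply(c(10, 100, 1000, 10000), function(G) {
    set.seed(2)
    var(replicate(2000,
                  sample_homogenization_fractions(homogenization_spec(G), w)[1]))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("expected composite RPKM is the mass-weighted mean of tissue RPKMs", {
  set.seed(8)
  n <- 50
  lam <- array(0, dim = c(n, 2, 2))
  a1 <- rlnorm(n); a2 <- rlnorm(n)
  lam[, 1, 1] <- a1; lam[, 1, 2] <- a1
  lam[, 2, 1] <- a2; lam[, 2, 2] <- a2
  lens <- sample(500:3000, n)
  m <- mixture_model(lam, lens,
                     data.frame(name = c("t1", "t2"),
                                mass_fraction = c(0.3, 0.7),
                                dispersion = 0.1))
  er_c <- expected_rpkm(m, "composite", "condition1")
  er_1 <- expected_rpkm(m, "t1", "condition1")
  er_2 <- expected_rpkm(m, "t2", "condition1")
  expect_equal(er_c, 0.3 * er_1 + 0.7 * er_2, tolerance = 1e-9)
})

test_that("a composite with all mass in one tissue reduces to that tissue", {
  set.seed(12)
  n <- 30
  lam <- array(rlnorm(n * 2 * 2), dim = c(n, 2, 2))
  m <- mixture_model(lam, rep(1000, n),
                     data.frame(name = c("t1", "t2"),
                                mass_fraction = c(1, 0),
                                dispersion = c(0.05, 0.5)))
  for (cc in m$conditions)
    expect_equal(expected_rpkm(m, "composite", cc),
                 expected_rpkm(m, "t1", cc), tolerance = 1e-12)
})

test_that("genes with zero abundance yield zero counts in every replicate", {
  m <- excl_model()   # last gene exclusive to gland -> zero in "rest"
  cm <- simulate_extraction_counts(m, "rest", "nurse", 3, 1e5, seed = 9)
  expect_true(all(cm$counts["g0101", ] == 0))
})

test_that("simulated library sizes are conserved around the target depth", {
  m <- excl_model(phi = 0.1)
  depth <- 1e5
  for (ex in c("gland", "composite")) {
    cm <- simulate_extraction_counts(m, ex, "nurse", 4, depth, seed = 31)
    lam <- expected_rpkm(m, ex, "nurse")   # proportional to share / length
    mu <- depth * (lam * m$gene_lengths) / sum(lam * m$gene_lengths)
    phi <- if (ex == "composite")
      sum(m$tissues$mass_fraction * m$tissues$dispersion)
    else m$tissues$dispersion[1]
    sd_total <- sqrt(sum(mu + phi * mu^2))
    expect_true(all(abs(colSums(cm$counts) - depth) < 5 * sd_total))
    expect_true(all(cm$counts >= 0) && all(cm$counts == floor(cm$counts)))
  }
})

test_that("a tissue-exclusive gene's expected dilution is the inverse mass
           fraction", {
  m <- excl_model(w1 = 0.02)
  r <- expected_rpkm(m, "gland", "nurse")["g0101"] /
    expected_rpkm(m, "composite", "nurse")["g0101"]
  expect_equal(unname(r), 50, tolerance = 1e-9)
})

test_that("unknown extraction or non-positive depth are rejected", {
  m <- excl_model()
  expect_error(simulate_extraction_counts(m, "kidney", "nurse"), "unknown")
  expect_error(simulate_extraction_counts(m, "gland", "nurse", depth = 0),
               "depth")
})
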