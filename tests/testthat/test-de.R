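# Differential-expression machinery: dispersion estimation, the exact
# conditional NB test, the nonparametric signal-vs-noise probability,
# BH adjustment and the calling rules.

test_that("dispersion estimation recovers zero variance and flags missing
           replication", {
  counts <- matrix(rep(c(10, 20, 30, 40), each = 4), nrow = 4, byrow = TRUE)
  cm <- mk_cm(counts)
  expect_equal(estimate_common_dispersion(cm, floor = 1)$phi, 0)
  single <- mk_cm(matrix(c(10, 20), nrow = 1), cond = c("A", "B"))
  expect_error(estimate_common_dispersion(single), "explicitly")
})

test_that("dispersion estimate is near zero for Poisson data", {
  set.seed(3)
  mu <- rlnorm(2000, log(100), 1)
  counts <- matrix(rpois(2000 * 4, rep(mu, 4)), 2000, 4)
  expect_lte(estimate_common_dispersion(mk_cm(counts))$phi, 0.02)
})

test_that("the exact test gives p = 1 at a symmetric split and respects
           validation", {
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), phi = 0.1), 1)  # untestable
  expect_error(nb_exact_test(c(-1), c(2)), "non-negative")
  expect_error(nb_exact_test(c(1), c(2), phi = -1), "non-negative")
})

test_that("at phi = 0 with equal sizes the exact test is a two-sided
           binomial test", {
  for (a in c(0, 2, 7, 10)) {
    p_pkg <- nb_exact_test(a, 20 - a, phi = 0)
    expect_equal(p_pkg, binom_oracle_p(a, 20, 0.5), tolerance = 1e-12)
  }
  # unequal replicate numbers shift the conditional probability
  p <- nb_exact_test(c(9, 9), c(2), phi = 0)
  expect_equal(p, binom_oracle_p(18, 20, 2 / 3), tolerance = 1e-12)
})

test_that("the exact test matches full-split enumeration", {
  # the example case: s = 20, phi = 0.1, observed (18, 2)
  expect_equal(nb_exact_test(18, 2, phi = 0.1),
               nb_oracle_p(18, 2, 1, 1, 0.1), tolerance = 1e-10)
  for (s in c(5, 20, 50)) for (phi in c(0.05, 0.5)) for (a in 0:s)
    expect_equal(nb_exact_test(a, s - a, phi = phi),
                 nb_oracle_p(a, s - a, 1, 1, phi), tolerance = 1e-10)
})

test_that("signal-vs-noise probability hits its limit cases", {
  # flat gene: M = 0, D = 0 -> q = 0 (strict dominance)
  x <- rbind(c(10, 10, 10, 10),
             c(100, 100, 0, 0),
             c(5, 5, 5, 5))
  rownames(x) <- c("flat", "strong", "flat2")
  q <- noiseq_like_probability(x, c("A", "A", "B", "B"))
  expect_equal(unname(q["flat"]), 0)
  # a gene dominating the whole noise pool -> q = 1
  expect_equal(unname(q["strong"]), 1)
})

test_that("signal-vs-noise probabilities match a double-loop recount", {
  set.seed(11)
  x <- matrix(rlnorm(200 * 6, log(20), 1), 200, 6)
  x[1:20, 1:3] <- x[1:20, 1:3] * 6
  group <- rep(c("A", "B"), each = 3)
  q <- noiseq_like_probability(x, group)
  expect_equal(unname(q), noiseq_oracle(x, group), tolerance = 1e-12)
  expect_error(noiseq_like_probability(x[, c(1, 4)], c("A", "B")),
               "noise pool")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  set.seed(4)
  for (n in c(1, 7, 100)) {
    p <- runif(n)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
})

test_that("DE calling respects its threshold boundary conventions", {
  res <- data.frame(gene_id = c("a", "b", "c"), M = c(1, -1, 0),
                    p_or_q = c(0.01, 0.01, 0.01),
                    q_adj = c(0.05, 0.2, 0.001))
  out <- call_de(res, de_config("nb_exact", alpha = 0.05))
  expect_equal(out$call, c("DE", "not_DE", "not_DE"))  # inclusive alpha; M=0 never DE
  expect_equal(out$direction, c("up_in_condition1", "up_in_condition2", "none"))
  res2 <- data.frame(gene_id = c("a", "b"), M = c(1, 1),
                     p_or_q = c(0.8, 0.81))
  out2 <- call_de(res2, de_config("noiseq_like", q_cut = 0.8))
  expect_equal(out2$call, c("not_DE", "DE"))           # strict q_cut
})

test_that("swapping condition labels negates M and preserves p", {
  set.seed(19)
  counts <- matrix(rnbinom(200 * 4, mu = 80, size = 10), 200, 4)
  counts[1:20, 1:2] <- counts[1:20, 1:2] * 4
  cm <- mk_cm(counts)
  for (method in c("nb_exact", "noiseq_like")) {
    cfg <- de_config(method, dispersion = 0.1)
    fwd <- de_test(cm, "x", c("A", "B"), cfg)
    rev <- de_test(cm, "x", c("B", "A"), cfg)
    expect_equal(fwd$M, -rev$M)
    expect_equal(fwd$p_or_q, rev$p_or_q)
    expect_equal(fwd$call, rev$call)
  }
})

test_that("recall is monotone in simulated effect size", {
  set.seed(17)
  n <- 1300
  mu <- rlnorm(n, log(100), 0.5)
  fc <- rep(0, n)
  blocks <- list(1:100, 101:200, 201:300, 301:400)
  sizes <- c(0.5, 1, 2, 3)
  for (i in 1:4)
    fc[blocks[[i]]] <- sizes[i] * sample(c(1, -1), 100, replace = TRUE)
  mu1 <- mu * 2^(fc / 2); mu2 <- mu * 2^(-fc / 2)
  counts <- cbind(matrix(rnbinom(n * 3, mu = rep(mu1, 3), size = 20), n, 3),
                  matrix(rnbinom(n * 3, mu = rep(mu2, 3), size = 20), n, 3))
  r <- de_test(mk_cm(counts), "x", c("A", "B"), de_config("nb_exact"))
  recall <- vapply(blocks, function(b) mean(r$call[b] == "DE"), numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[4], 0.9)
})

test_that("the two methods agree on strong signals", {
  set.seed(23)
  n <- 500
  mu <- rlnorm(n, log(300), 0.5)
  fc <- rep(0, n)
  fc[1:100] <- 3 * sample(c(1, -1), 100, replace = TRUE)
  mu1 <- mu * 2^(fc / 2); mu2 <- mu * 2^(-fc / 2)
  counts <- cbind(matrix(rnbinom(n * 2, mu = rep(mu1, 2), size = 20), n, 2),
                  matrix(rnbinom(n * 2, mu = rep(mu2, 2), size = 20), n, 2))
  cm <- mk_cm(counts)
  r_nb <- de_test(cm, "x", c("A", "B"), de_config("nb_exact", dispersion = 0.05))
  r_nq <- de_test(cm, "x", c("A", "B"), de_config("noiseq_like"))
  expect_gte(mean(r_nb$call == r_nq$call), 0.9)
  # both methods find essentially all true effects
  expect_gt(mean(r_nb$call[1:100] == "DE"), 0.95)
  expect_gt(mean(r_nq$call[1:100] == "DE"), 0.95)
})
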