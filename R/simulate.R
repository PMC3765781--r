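# Simulation of extraction-level read counts from a tissue-mixture model.
# A "composite" extraction mixes tissue abundances by realized RNA mass
# fractions (drawn under the incomplete-homogenization model per replicate);
# a tissue extraction uses that tissue's abundances alone.  Counts are
# negative-binomial around depth times the gene's read share.

#' Simulate read counts for one extraction and condition
#'
#' For a single tissue the expected read share of gene g is proportional to
#' abundance x length.  For `"composite"`, per-replicate realized tissue
#' fractions are drawn from the homogenization model and the share is
#' proportional to the realized-mass-weighted abundance times length.  Counts
#' are drawn per gene from a negative-binomial with mean depth x share and
#' the extraction's dispersion (composite: nominal-mass-weighted mean of
#' tissue dispersions); dispersion 0 falls back to Poisson.  Column sums
#' therefore vary stochastically around `depth`.
#'
#' Each replicate draws from its own stream derived by stable hashing of
#' (extraction, condition, replicate) with the master seed, so adding
#' replicates or samples never changes existing ones.
#'
#' @param model A `mixture_model`.
#' @param extraction A tissue name in the model or `"composite"`.
#' @param condition One of `model$conditions`.
#' @param n_replicates Number of biological replicates to simulate.
#' @param depth Target total reads per sample (default 12e6, a typical
#'   equalized depth for bulk libraries).
#' @param homogenization A [homogenization_spec()]; only affects composite
#'   extractions.  Default `Inf` grains (perfect homogenization).
#' @param seed Master integer seed.
#' @return A `count_matrix` whose sample metadata records the extraction,
#'   condition and replicate; the model's truth table is attached as
#'   attribute `"truth"`.
#' @export
simulate_extraction_counts <- function(model, extraction, condition,
                                       n_replicates = 2,
                                       depth = 12e6,
                                       homogenization = homogenization_spec(),
                                       seed = 1L) {
  assert_that(inherits(model, "mixture_model"), "model must be a mixture_model")
  assert_that(identical(extraction, "composite") ||
                extraction %in% model$tissues$name,
              sprintf("unknown extraction '%s'", extraction))
  assert_that(condition %in% model$conditions,
              sprintf("unknown condition '%s'", condition))
  assert_that(is_count(n_replicates), "n_replicates must be a positive integer")
  assert_that(is.numeric(depth) && length(depth) == 1 && depth >= 1,
              "depth must be >= 1")
  assert_that(inherits(homogenization, "homogenization_spec"),
              "homogenization must be a homogenization_spec")

  w <- stats::setNames(model$tissues$mass_fraction, model$tissues$name)
  phi <- if (identical(extraction, "composite")) {
    sum(model$tissues$mass_fraction * model$tissues$dispersion)
  } else {
    model$tissues$dispersion[match(extraction, model$tissues$name)]
  }

  n <- length(model$gene_ids)
  counts <- matrix(0L, n, n_replicates,
                   dimnames = list(model$gene_ids, NULL))
  for (r in seq_len(n_replicates)) {
    with_seed(derive_seed(seed, extraction, condition, r), {
      if (identical(extraction, "composite")) {
        wr <- if (is.infinite(homogenization$grains)) w else {
          g <- as.vector(rmultinom(1, homogenization$grains, w))
          stats::setNames(g / homogenization$grains, names(w))
        }
        lam <- extraction_abundance(model, "composite", condition,
                                    mass_fractions = wr)
      } else {
        lam <- extraction_abundance(model, extraction, condition)
      }
      weight <- lam * model$gene_lengths
      tot <- sum(weight)
      assert_that(tot > 0, sprintf(
        "no expressed genes in extraction '%s', condition '%s'",
        extraction, condition))
      mu <- depth * weight / tot
      counts[, r] <- if (phi < 1e-12) rpois(n, mu)
                     else rnbinom(n, mu = mu, size = 1 / phi)
    })
  }
  sample_ids <- sprintf("%s_%s_r%d", extraction, condition,
                        seq_len(n_replicates))
  colnames(counts) <- sample_ids
  samples <- data.frame(sample_id = sample_ids, extraction = extraction,
                        condition = condition,
                        replicate = seq_len(n_replicates))
  out <- count_matrix(counts, samples, model$gene_lengths)
  attr(out, "truth") <- model$truth
  out
}

#' Simulate a full multi-extraction experiment
#'
#' Convenience wrapper running [simulate_extraction_counts()] over every
#' requested extraction and both conditions and combining the results.
#'
#' @inheritParams simulate_extraction_counts
#' @param extractions Character vector of extraction names (tissue names
#'   and/or `"composite"`).
#' @return A combined `count_matrix` with the truth table attached.
#' @export
simulate_experiment <- function(model,
                                extractions = c(model$tissues$name, "composite"),
                                n_replicates = 2,
                                depth = 12e6,
                                homogenization = homogenization_spec(),
                                seed = 1L) {
  parts <- list()
  for (ex in extractions)
    for (cond in model$conditions)
      parts[[paste(ex, cond)]] <- simulate_extraction_counts(
        model, ex, cond, n_replicates = n_replicates, depth = depth,
        homogenization = homogenization, seed = seed)
  out <- combine_count_matrices(parts)
  attr(out, "truth") <- model$truth
  out
}
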