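# Generative tissue-mixture model: the ground truth behind every simulated
# extraction.  A composite structure (e.g. a whole insect abdomen) is modelled
# as a mass-weighted mixture of its internal tissues; each tissue carries its
# own per-gene expected relative abundance in each of two conditions.

#' Effect configuration for the synthetic mixture model
#'
#' Describes how many genes to simulate and how differential expression is
#' distributed across them: what fraction of genes are DE per tissue, the
#' distribution of log2 effect sizes, what fraction of DE genes are exclusive
#' to their tissue (zero abundance elsewhere), and what fraction additionally
#' carry an opposite-direction effect in a second tissue -- the gene classes
#' whose composite-extraction behaviour the package is built to study.
#'
#' @param n_genes Number of genes to simulate.
#' @param de_fraction Fraction of genes differentially expressed per tissue.
#' @param log2fc_location,log2fc_scale Location and scale of the normal
#'   distribution from which absolute log2 fold changes are drawn.
#' @param exclusive_fraction Fraction of each tissue's DE genes expressed only
#'   in that tissue (abundance zero in every other tissue).
#' @param opposite_fraction Fraction of each tissue's DE genes that also
#'   receive an equal-magnitude, opposite-direction effect in the
#'   largest-mass other tissue.  `exclusive_fraction + opposite_fraction`
#'   must not exceed 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   expected abundance (arbitrary units, later normalized per tissue).
#' @param length_meanlog,length_sdlog Log-normal parameters of transcript
#'   length in bp (lengths are rounded and floored at 200 bp).
#' @param conditions Character vector of the two condition names.
#' @param seed Integer seed making model construction deterministic.
#' @return An object of class `effect_config` (a validated list).
#' @export
effect_config <- function(n_genes = 10000,
                          de_fraction = 0.1,
                          log2fc_location = 2,
                          log2fc_scale = 0.5,
                          exclusive_fraction = 0.2,
                          opposite_fraction = 0.05,
                          baseline_meanlog = log(50),
                          baseline_sdlog = 1.5,
                          length_meanlog = log(1500),
                          length_sdlog = 0.4,
                          conditions = c("nurse", "forager"),
                          seed = 1L) {
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  for (f in c(de_fraction, exclusive_fraction, opposite_fraction))
    assert_that(is.numeric(f) && length(f) == 1 && f >= 0 && f <= 1,
                "fractions must lie in [0, 1]")
  assert_that(exclusive_fraction + opposite_fraction <= 1,
              "exclusive_fraction + opposite_fraction must be <= 1")
  assert_that(log2fc_scale >= 0, "log2fc_scale must be non-negative")
  assert_that(baseline_sdlog >= 0 && length_sdlog >= 0,
              "log-normal sd parameters must be non-negative")
  assert_that(is.character(conditions) && length(conditions) == 2 &&
                !anyDuplicated(conditions),
              "conditions must be two distinct names")
  structure(list(n_genes = as.integer(n_genes),
                 de_fraction = de_fraction,
                 log2fc_location = log2fc_location,
                 log2fc_scale = log2fc_scale,
                 exclusive_fraction = exclusive_fraction,
                 opposite_fraction = opposite_fraction,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 conditions = conditions,
                 seed = as.integer(seed)),
            class = "effect_config")
}

#' Incomplete-homogenization specification
#'
#' Grinding a composite structure to powder before subsampling for RNA
#' extraction does not guarantee each internal tissue is represented at its
#' true mass fraction: the powder grains are finite.  The model draws `grains`
#' grains, each falling in tissue t with probability equal to its mass
#' fraction; the realized fraction is the grain count divided by `grains`.
#' `grains = Inf` means perfect homogenization (realized equals nominal).
#'
#' @param grains Positive integer number of grains, or `Inf`.
#' @param seed Optional integer seed used when fractions are sampled
#'   standalone via [sample_homogenization_fractions()].
#' @return An object of class `homogenization_spec`.
#' @export
homogenization_spec <- function(grains = Inf, seed = NULL) {
  assert_that(length(grains) == 1 && is.numeric(grains) &&
                (is.infinite(grains) || (grains >= 1 && grains == floor(grains))),
              "grains must be a positive integer or Inf")
  structure(list(grains = grains,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "homogenization_spec")
}

#' Draw realized tissue fractions under incomplete homogenization
#'
#' @param spec A [homogenization_spec()].
#' @param mass_fractions Numeric vector of nominal tissue mass fractions
#'   (non-negative, summing to 1).
#' @return Numeric vector of realized fractions, same length and names as
#'   `mass_fractions`, summing to 1.  With `grains = Inf` the nominal
#'   fractions are returned unchanged.
#' @export
sample_homogenization_fractions <- function(spec, mass_fractions) {
  assert_that(inherits(spec, "homogenization_spec"),
              "spec must be a homogenization_spec")
  check_mass_fractions(mass_fractions)
  if (is.infinite(spec$grains)) return(mass_fractions)
  draw <- function() {
    g <- as.vector(rmultinom(1, size = spec$grains, prob = mass_fractions))
    stats::setNames(g / spec$grains, names(mass_fractions))
  }
  if (!is.null(spec$seed)) with_seed(spec$seed, draw()) else draw()
}

check_mass_fractions <- function(w) {
  assert_that(is.numeric(w) && length(w) >= 1 && all(is.finite(w)) &&
                all(w >= 0), "mass fractions must be non-negative numbers")
  assert_that(abs(sum(w) - 1) <= 1e-9, "mass fractions must sum to 1")
  invisible(TRUE)
}

#' Low-level tissue-mixture model constructor
#'
#' Assembles and validates a mixture model from explicit components.  Most
#' users should call [build_mixture_model()] instead; this constructor exists
#' for fully controlled models in analyses and tests.
#'
#' @param abundance 3-d numeric array `gene x tissue x condition` of expected
#'   relative transcript abundances (non-negative; every gene positive in at
#'   least one tissue/condition slice).  Dimnames are used for gene, tissue
#'   and condition names.
#' @param gene_lengths Numeric vector of transcript lengths in bp (>= 1),
#'   one per gene.
#' @param tissues Data frame with columns `name`, `mass_fraction` (summing to
#'   1) and `dispersion` (negative-binomial dispersion phi, variance
#'   mu + phi mu^2, per tissue).
#' @param normalize If `TRUE` (default) abundances are rescaled per tissue so
#'   every tissue has the same total abundance-length product, averaged over
#'   the two conditions.  This makes abundance a per-unit-RNA-mass quantity,
#'   so the composite's expected RPKM is exactly the mass-weighted mean of
#'   the tissue RPKMs, while leaving within-tissue fold changes untouched.
#' @return An object of class `mixture_model` with elements `gene_ids`,
#'   `gene_lengths`, `tissues`, `conditions`, `abundance` and `truth` (a data
#'   frame gene_id/tissue/label/log2fc recording ground-truth DE status).
#' @export
mixture_model <- function(abundance, gene_lengths, tissues, normalize = TRUE) {
  assert_that(is.array(abundance) && length(dim(abundance)) == 3,
              "abundance must be a gene x tissue x condition array")
  d <- dim(abundance)
  assert_that(d[1] >= 1, "model must contain at least one gene")
  assert_that(d[3] == 2, "exactly two conditions are supported")
  assert_that(all(is.finite(abundance)) && all(abundance >= 0),
              "abundances must be finite and non-negative")
  assert_that(all(apply(abundance, 1, max) > 0),
              "every gene must have positive abundance somewhere")
  assert_that(is.data.frame(tissues) &&
                all(c("name", "mass_fraction", "dispersion") %in% names(tissues)),
              "tissues must have columns name, mass_fraction, dispersion")
  assert_that(nrow(tissues) == d[2],
              "tissues rows must match abundance's second dimension")
  assert_that(!anyDuplicated(tissues$name), "tissue names must be unique")
  check_mass_fractions(tissues$mass_fraction)
  assert_that(all(tissues$dispersion >= 0) && all(is.finite(tissues$dispersion)),
              "dispersions must be finite and non-negative")
  assert_that(is.numeric(gene_lengths) && length(gene_lengths) == d[1] &&
                all(gene_lengths >= 1), "gene_lengths must be >= 1 per gene")

  gene_ids <- dimnames(abundance)[[1]]
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(d[1]))
  assert_that(!anyDuplicated(gene_ids), "gene ids must be unique")
  conditions <- dimnames(abundance)[[3]]
  if (is.null(conditions)) conditions <- c("condition1", "condition2")
  dimnames(abundance) <- list(gene_ids, tissues$name, conditions)
  gene_lengths <- stats::setNames(as.numeric(gene_lengths), gene_ids)

  if (normalize) {
    target <- 1e6
    for (t in seq_len(d[2])) {
      tot <- mean(vapply(1:2, function(cc)
        sum(abundance[, t, cc] * gene_lengths), numeric(1)))
      if (tot > 0) abundance[, t, ] <- abundance[, t, ] * (target / tot)
    }
  }

  truth <- do.call(rbind, lapply(seq_len(d[2]), function(t) {
    l1 <- abundance[, t, 1]; l2 <- abundance[, t, 2]
    label <- ifelse(l1 > l2, paste0("up_in_", conditions[1]),
                    ifelse(l1 < l2, paste0("up_in_", conditions[2]), "not_DE"))
    lfc <- ifelse(l1 == l2, 0, log2(l1 / l2))
    data.frame(gene_id = gene_ids, tissue = tissues$name[t],
               label = label, log2fc = lfc, row.names = NULL)
  }))

  structure(list(gene_ids = gene_ids,
                 gene_lengths = gene_lengths,
                 tissues = tissues,
                 conditions = conditions,
                 abundance = abundance,
                 truth = truth),
            class = "mixture_model")
}

#' Build a tissue-mixture model from an effect configuration
#'
#' Draws baseline abundances, assigns per-tissue DE genes with random
#' direction and log-normal baseline expression, marks a subset of each
#' tissue's DE genes as tissue-exclusive and another (disjoint) subset as
#' carrying an opposite-direction effect in the largest-mass other tissue,
#' then normalizes abundances per tissue (see [mixture_model()]).
#' Deterministic given `effects$seed`.
#'
#' @param effects An [effect_config()].
#' @param tissues Data frame with columns `name`, `mass_fraction`,
#'   `dispersion`; mass fractions must sum to 1.
#' @return A `mixture_model` with ground-truth labels derived from the final
#'   abundances (a gene is labelled up in the condition where its abundance
#'   is strictly larger).
#' @export
build_mixture_model <- function(effects,
                                tissues = data.frame(
                                  name = c("gland", "gut", "remainder"),
                                  mass_fraction = c(0.02, 0.30, 0.68),
                                  dispersion = c(0.05, 0.05, 0.05))) {
  assert_that(inherits(effects, "effect_config"),
              "effects must be an effect_config")
  n <- effects$n_genes
  nt <- nrow(tissues)
  check_mass_fractions(tissues$mass_fraction)

  with_seed(effects$seed, {
    lens <- pmax(200, round(rlnorm(n, effects$length_meanlog,
                                   effects$length_sdlog)))
    lambda <- array(0, dim = c(n, nt, 2))
    for (t in seq_len(nt)) {
      base <- rlnorm(n, effects$baseline_meanlog, effects$baseline_sdlog)
      lambda[, t, 1] <- base
      lambda[, t, 2] <- base
    }
    exclusive <- matrix(FALSE, n, nt)
    n_de <- round(effects$de_fraction * n)
    for (t in seq_len(nt)) {
      if (n_de == 0) next
      de_idx <- sample.int(n, n_de)
      mag <- abs(rnorm(n_de, effects$log2fc_location, effects$log2fc_scale))
      dir <- sample(c(1, -1), n_de, replace = TRUE)
      lambda[de_idx, t, 1] <- lambda[de_idx, t, 1] * 2^( dir * mag / 2)
      lambda[de_idx, t, 2] <- lambda[de_idx, t, 2] * 2^(-dir * mag / 2)
      n_ex <- round(effects$exclusive_fraction * n_de)
      n_op <- round(effects$opposite_fraction * n_de)
      if (n_ex > 0) exclusive[de_idx[seq_len(n_ex)], t] <- TRUE
      if (n_op > 0 && nt > 1) {
        others <- setdiff(seq_len(nt), t)
        t2 <- others[which.max(tissues$mass_fraction[others])]
        op_idx <- de_idx[n_ex + seq_len(n_op)]
        op_mag <- mag[n_ex + seq_len(n_op)]
        op_dir <- dir[n_ex + seq_len(n_op)]
        base2 <- lambda[op_idx, t2, 1]
        lambda[op_idx, t2, 1] <- base2 * 2^(-op_dir * op_mag / 2)
        lambda[op_idx, t2, 2] <- base2 * 2^( op_dir * op_mag / 2)
      }
    }
    # A gene can be drawn as DE in several tissues; exclusivity to more than
    # one is contradictory, so the first tissue wins.
    multi <- which(rowSums(exclusive) > 1)
    for (g in multi) {
      first <- which(exclusive[g, ])[1]
      exclusive[g, ] <- FALSE
      exclusive[g, first] <- TRUE
    }
    # Tissue-exclusive genes vanish from every other tissue.
    for (t in seq_len(nt)) {
      ex <- which(exclusive[, t])
      if (length(ex)) lambda[ex, setdiff(seq_len(nt), t), ] <- 0
    }
    dimnames(lambda) <- list(sprintf("g%05d", seq_len(n)), tissues$name,
                             effects$conditions)
    mixture_model(lambda, lens, tissues)
  })
}

#' Analytic expected RPKM under the mixture model
#'
#' The noise-free RPKM implied by the model for one extraction and condition:
#' the gene's share of sequenced reads is proportional to abundance times
#' length (mass-weighted across tissues for the composite), and RPKM is
#' 1e9 times that share divided by gene length.
#'
#' @param model A `mixture_model`.
#' @param extraction A tissue name in the model, or `"composite"`.
#' @param condition One of `model$conditions`.
#' @return Named numeric vector of expected RPKM per gene.
#' @export
expected_rpkm <- function(model, extraction, condition) {
  lam <- extraction_abundance(model, extraction, condition)
  share <- lam * model$gene_lengths / sum(lam * model$gene_lengths)
  1e9 * share / model$gene_lengths
}

# Mixture abundance vector for one extraction/condition.
extraction_abundance <- function(model, extraction, condition,
                                 mass_fractions = NULL) {
  assert_that(inherits(model, "mixture_model"), "model must be a mixture_model")
  assert_that(condition %in% model$conditions,
              sprintf("unknown condition '%s'", condition))
  cc <- match(condition, model$conditions)
  if (identical(extraction, "composite")) {
    w <- if (is.null(mass_fractions)) model$tissues$mass_fraction else mass_fractions
    lam <- model$abundance[, , cc, drop = FALSE]
    dim(lam) <- dim(lam)[1:2]
    stats::setNames(as.vector(lam %*% w), model$gene_ids)
  } else {
    assert_that(extraction %in% model$tissues$name,
                sprintf("unknown extraction '%s'", extraction))
    model$abundance[, match(extraction, model$tissues$name), cc]
  }
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: %d genes, %d tissues (%s), conditions %s\n",
              length(x$gene_ids), nrow(x$tissues),
              paste(sprintf("%s w=%.3g", x$tissues$name,
                            x$tissues$mass_fraction), collapse = ", "),
              paste(x$conditions, collapse = " vs ")))
  n_de <- sum(x$truth$label != "not_DE")
  cat(sprintf("  ground-truth DE labels: %d gene-tissue pairs\n", n_de))
  invisible(x)
}
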