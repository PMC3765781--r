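# Differential expression between two conditions within one extraction.
# Two method families:
#   nb_exact     - an exact conditional negative-binomial count test with
#                  Benjamini-Hochberg FDR adjustment (called at FDR <= alpha);
#   noiseq_like  - a nonparametric signal-versus-noise probability on RPKM,
#                  comparing each gene's (|M|, D) statistic against a noise
#                  pool built from within-condition replicate contrasts
#                  (called at probability > q_cut, conventionally 0.8).

#' Differential-expression test configuration
#'
#' @param method `"nb_exact"` or `"noiseq_like"`.
#' @param alpha FDR threshold for the exact test (inclusive: DE iff
#'   adjusted q <= alpha).  Default 0.05.
#' @param q_cut Probability cutoff for the nonparametric method (exclusive:
#'   DE iff q > q_cut).  Default 0.8, the conventional cutoff.
#' @param pseudo_count Pseudo-count k (RPKM) added inside log ratios so the
#'   fold change M is always finite.  Default 0.5.
#' @param dispersion Either `NULL` (estimate a common dispersion from the
#'   data via [estimate_common_dispersion()]) or a single non-negative
#'   number to use directly.
#' @param dispersion_floor Mean-normalized-count floor used when estimating
#'   the common dispersion (genes below it are ignored).  Default 5.
#' @return An object of class `de_config`.
#' @export
de_config <- function(method = c("nb_exact", "noiseq_like"),
                      alpha = 0.05, q_cut = 0.8, pseudo_count = 0.5,
                      dispersion = NULL, dispersion_floor = 5) {
  method <- match.arg(method)
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  assert_that(q_cut > 0 && q_cut < 1, "q_cut must lie in (0, 1)")
  assert_that(pseudo_count > 0, "pseudo_count must be positive")
  if (!is.null(dispersion))
    assert_that(is.numeric(dispersion) && length(dispersion) == 1 &&
                  is.finite(dispersion) && dispersion >= 0,
                "dispersion must be a single non-negative number")
  structure(list(method = method, alpha = alpha, q_cut = q_cut,
                 pseudo_count = pseudo_count, dispersion = dispersion,
                 dispersion_floor = dispersion_floor),
            class = "de_config")
}

#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments per gene within each condition on depth-normalized
#' counts (columns scaled to the mean library size):
#' phi_g = max(0, (s2_g - mean_g) / mean_g^2), averaged over conditions with
#' replication; the common dispersion is the median over genes whose overall
#' mean normalized count is at least `floor`.
#'
#' @param x A `count_matrix` or a numeric counts matrix.
#' @param group Factor/vector of condition labels, one per column.
#'   Defaults to the `condition` metadata of a `count_matrix`.
#' @param floor Minimum mean normalized count for a gene to enter the median.
#' @param estimator Summary over per-gene estimates: `"median"` (default) or
#'   `"mean"`.
#' @return Object of class `dispersion_estimate`: list with `phi`,
#'   `n_genes_used` and `group_sizes`.
#' @export
estimate_common_dispersion <- function(x, group = NULL, floor = 5,
                                       estimator = c("median", "mean")) {
  estimator <- match.arg(estimator)
  if (inherits(x, "count_matrix")) {
    if (is.null(group)) group <- x$samples$condition
    x <- x$counts
  }
  assert_that(is.matrix(x) && !is.null(group) && length(group) == ncol(x),
              "group must label every column")
  group <- as.factor(group)
  sizes <- table(group)
  assert_that(any(sizes >= 2), paste(
    "no condition has replication; cannot estimate dispersion --",
    "supply a dispersion value explicitly (de_config(dispersion = ...))"))
  N <- colSums(x)
  norm <- sweep(x, 2, mean(N) / N, "*")
  per_gene <- matrix(NA_real_, nrow(x), nlevels(group))
  for (j in seq_len(nlevels(group))) {
    cols <- which(group == levels(group)[j])
    if (length(cols) < 2) next
    sub <- norm[, cols, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    per_gene[, j] <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  }
  phi_g <- rowMeans(per_gene, na.rm = TRUE)
  keep <- rowMeans(norm) >= floor & is.finite(phi_g)
  assert_that(any(keep),
              "no genes above the abundance floor; lower `floor`")
  phi <- if (estimator == "median") median(phi_g[keep]) else mean(phi_g[keep])
  structure(list(phi = phi, n_genes_used = sum(keep),
                 group_sizes = as.integer(sizes)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion phi = %.4g (from %d genes; group sizes %s)\n",
              x$phi, x$n_genes_used, paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Exact conditional negative-binomial test for one gene
#'
#' Replicate counts are scaled to a common effective library size (the
#' geometric mean of the supplied sizes), summed within condition and
#' rounded, giving condition totals (a, b).  Conditional on s = a + b the
#' split follows a negative hypergeometric law with sizes n1/phi and n2/phi
#' (n1, n2 = replicate numbers); the two-sided p-value is the minimum-
#' likelihood rule: the sum of point probabilities of every split no more
#' likely than the observed one (ties included within relative tolerance
#' 1e-7).  With phi < 1e-8 the conditional law degenerates to
#' binomial(s, n1/(n1+n2)).
#'
#' @param x1,x2 Non-negative integer replicate counts for the gene in
#'   conditions 1 and 2.
#' @param lib_sizes1,lib_sizes2 Library sizes for the replicates; default
#'   all equal.
#' @param phi Common negative-binomial dispersion (>= 0).
#' @return Two-sided p-value in (0, 1].  A total of zero reads returns 1
#'   (untestable gene).
#' @export
nb_exact_test <- function(x1, x2, lib_sizes1 = NULL, lib_sizes2 = NULL,
                          phi = 0) {
  assert_that(all(c(x1, x2) >= 0) && all(c(x1, x2) == floor(c(x1, x2))),
              "counts must be non-negative integers")
  assert_that(is.numeric(phi) && length(phi) == 1 && is.finite(phi) &&
                phi >= 0, "phi must be a non-negative number")
  n1 <- length(x1); n2 <- length(x2)
  if (is.null(lib_sizes1)) lib_sizes1 <- rep(1, n1)
  if (is.null(lib_sizes2)) lib_sizes2 <- rep(1, n2)
  assert_that(all(c(lib_sizes1, lib_sizes2) > 0),
              "library sizes must be positive")
  common <- exp(mean(log(c(lib_sizes1, lib_sizes2))))
  a <- round(sum(x1 * common / lib_sizes1))
  b <- round(sum(x2 * common / lib_sizes2))
  s <- a + b
  if (s == 0) return(1)
  lp <- nb_conditional_logprob(s, n1, n2, phi)
  p <- sum(exp(lp[lp <= lp[a + 1] + log1p(1e-7)]))
  min(1, max(p, .Machine$double.xmin))
}

# Log point probabilities of the conditional split distribution for
# a = 0..s.  phi >= 1e-8: negative hypergeometric with sizes r1 = n1/phi,
# r2 = n2/phi:  P(a|s) = C(a+r1-1, a) C(s-a+r2-1, s-a) / C(s+r1+r2-1, s).
# phi < 1e-8: Poisson-conditional limit, binomial(s, n1/(n1+n2)).
nb_conditional_logprob <- function(s, n1, n2, phi) {
  av <- 0:s
  if (phi < 1e-8) return(dbinom(av, s, n1 / (n1 + n2), log = TRUE))
  r1 <- n1 / phi; r2 <- n2 / phi
  lgamma(av + r1) - lgamma(av + 1) - lgamma(r1) +
    lgamma(s - av + r2) - lgamma(s - av + 1) - lgamma(r2) -
    (lgamma(s + r1 + r2) - lgamma(s + 1) - lgamma(r1 + r2))
}

#' Nonparametric signal-versus-noise DE probability
#'
#' For each gene the signal is M_g = log2((xbar1+k)/(xbar2+k)) and
#' D_g = |xbar1 - xbar2| on the RPKM scale.  The noise distribution pools,
#' over all genes and every within-condition replicate pair, the same
#' statistics computed between replicates.  The probability
#' q_g is the fraction of noise points strictly dominated by the gene's
#' signal (|M*| < |M_g| and D* < D_g); a gene indistinguishable from
#' replicate noise gets q near 0, a gene whose contrast exceeds all
#' replicate noise gets q = 1.
#'
#' @param x An `rpkm_matrix`, or a numeric RPKM matrix.
#' @param group Condition labels per column (two levels, each with >= 2
#'   replicates).  Defaults to the `condition` metadata of an
#'   `rpkm_matrix`.
#' @param pseudo_count Pseudo-count k (RPKM) in the log ratio; default 0.5.
#' @return Named numeric vector q_g in [0, 1].
#' @export
noiseq_like_probability <- function(x, group = NULL, pseudo_count = 0.5) {
  if (inherits(x, "rpkm_matrix")) {
    if (is.null(group)) group <- x$samples$condition
    x <- x$rpkm
  }
  assert_that(is.matrix(x) && !is.null(group) && length(group) == ncol(x),
              "group must label every column")
  assert_that(pseudo_count > 0, "pseudo_count must be positive")
  group <- as.factor(group)
  assert_that(nlevels(group) == 2, "exactly two conditions are required")
  assert_that(all(table(group) >= 2), paste(
    "the nonparametric method needs >= 2 replicates per condition",
    "to build a noise pool"))
  k <- pseudo_count
  g1 <- which(group == levels(group)[1])
  g2 <- which(group == levels(group)[2])
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  M <- log2((m1 + k) / (m2 + k))
  D <- abs(m1 - m2)

  Mstar <- numeric(0); Dstar <- numeric(0)
  for (cols in list(g1, g2)) {
    pairs <- utils::combn(cols, 2)
    for (p in seq_len(ncol(pairs))) {
      xi <- x[, pairs[1, p]]; xj <- x[, pairs[2, p]]
      Mstar <- c(Mstar, log2((xi + k) / (xj + k)))
      Dstar <- c(Dstar, abs(xi - xj))
    }
  }

  absM <- abs(M)
  absMstar <- abs(Mstar)
  q <- numeric(length(M))
  # blockwise so the comparison runs vectorized without a genes x pool matrix
  idx_blocks <- split(seq_along(M), ceiling(seq_along(M) / 256))
  for (ix in idx_blocks) {
    dom <- outer(absMstar, absM[ix], "<") & outer(Dstar, D[ix], "<")
    q[ix] <- colMeans(dom)
  }
  stats::setNames(q, rownames(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving and
#' never below the raw p-value.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply DE calls and directions to a test-result table
#'
#' nb_exact: DE iff adjusted q <= alpha (inclusive).  noiseq_like: DE iff
#' q > q_cut (strict).  Direction follows the sign of M; a gene with M
#' exactly 0 can never be called DE (its direction would be undefined), and
#' indeed gets q_g = 0 under the nonparametric method and sits at the mode
#' of the exact test.
#'
#' @param results Data frame with columns `gene_id`, `M`, and `p_or_q`
#'   (raw p for nb_exact, probability for noiseq_like); nb_exact results
#'   also need `q_adj`.
#' @param config A [de_config()] naming the method the results came from.
#' @return The data frame with `call` (`"DE"`/`"not_DE"`) and `direction`
#'   (`up_in_<condition1>`, `up_in_<condition2>`, `none`) columns filled in,
#'   using attribute `conditions` of `results` when present.
#' @export
call_de <- function(results, config) {
  assert_that(inherits(config, "de_config"), "config must be a de_config")
  assert_that(is.data.frame(results) &&
                all(c("gene_id", "M", "p_or_q") %in% names(results)),
              "results must have gene_id, M and p_or_q columns")
  conds <- attr(results, "conditions")
  if (is.null(conds)) conds <- c("condition1", "condition2")
  de <- if (config$method == "nb_exact") {
    assert_that("q_adj" %in% names(results),
                "nb_exact results need a q_adj column")
    results$q_adj <= config$alpha
  } else {
    results$p_or_q > config$q_cut
  }
  de <- de & results$M != 0
  results$call <- ifelse(de, "DE", "not_DE")
  results$direction <- ifelse(results$M > 0, paste0("up_in_", conds[1]),
                              ifelse(results$M < 0,
                                     paste0("up_in_", conds[2]), "none"))
  results
}

#' Run a two-condition DE test within one extraction
#'
#' Orchestrates the full per-extraction comparison: subsets the samples,
#' computes RPKM summaries (M, D), runs the configured test and applies the
#' calling rule.
#'
#' @param x A `count_matrix` containing the extraction's samples.
#' @param extraction Extraction name to test within.
#' @param conditions Length-2 character vector; condition 1 over condition 2
#'   defines the sign of M.  Defaults to the two conditions present.
#' @param config A [de_config()].
#' @return Object of class `de_result`: a data frame with columns gene_id,
#'   mean1, mean2, M, D, p_or_q, q_adj, call, direction, and attributes
#'   `method`, `extraction`, `conditions`, `alpha`, `q_cut`, `phi`.
#' @export
de_test <- function(x, extraction, conditions = NULL,
                    config = de_config()) {
  assert_that(inherits(x, "count_matrix"), "x must be a count_matrix")
  assert_that(inherits(config, "de_config"), "config must be a de_config")
  sub <- subset_samples(x, extraction = extraction)
  if (is.null(conditions)) conditions <- unique(sub$samples$condition)
  assert_that(length(conditions) == 2,
              "exactly two conditions are required")
  sub <- subset_samples(sub, condition = conditions)
  group <- factor(sub$samples$condition, levels = conditions)
  assert_that(all(table(group) >= 1), "both conditions need samples")

  rp <- compute_rpkm(sub)
  i1 <- which(group == conditions[1]); i2 <- which(group == conditions[2])
  mean1 <- rowMeans(rp$rpkm[, i1, drop = FALSE])
  mean2 <- rowMeans(rp$rpkm[, i2, drop = FALSE])
  k <- config$pseudo_count
  M <- log2((mean1 + k) / (mean2 + k))
  D <- abs(mean1 - mean2)

  phi <- NA_real_
  if (config$method == "nb_exact") {
    phi <- if (!is.null(config$dispersion)) config$dispersion else
      estimate_common_dispersion(sub, group,
                                 floor = config$dispersion_floor)$phi
    N <- colSums(sub$counts)
    p <- nb_exact_test_all(sub$counts[, i1, drop = FALSE],
                           sub$counts[, i2, drop = FALSE],
                           N[i1], N[i2], phi)
    q_adj <- bh_adjust(p)
    res <- data.frame(gene_id = rownames(sub$counts), mean1 = mean1,
                      mean2 = mean2, M = M, D = D, p_or_q = p,
                      q_adj = q_adj, row.names = NULL)
  } else {
    q <- noiseq_like_probability(rp$rpkm, group, pseudo_count = k)
    res <- data.frame(gene_id = rownames(sub$counts), mean1 = mean1,
                      mean2 = mean2, M = M, D = D, p_or_q = q,
                      q_adj = NA_real_, row.names = NULL)
  }
  attr(res, "conditions") <- conditions
  res <- call_de(res, config)
  attr(res, "method") <- config$method
  attr(res, "extraction") <- extraction
  attr(res, "conditions") <- conditions
  attr(res, "alpha") <- config$alpha
  attr(res, "q_cut") <- config$q_cut
  attr(res, "phi") <- phi
  class(res) <- c("de_result", "data.frame")
  res
}

# Vectorized-over-genes exact test.  The conditional split distribution only
# depends on s through its support, but each gene has its own s, so loop;
# each gene's enumeration is a single vectorized computation.
nb_exact_test_all <- function(c1, c2, lib1, lib2, phi) {
  n1 <- ncol(c1); n2 <- ncol(c2)
  common <- exp(mean(log(c(lib1, lib2))))
  a <- round(as.vector(c1 %*% (common / lib1)))
  b <- round(as.vector(c2 %*% (common / lib2)))
  s <- a + b
  p <- rep(1, length(s))
  for (i in which(s > 0)) {
    lp <- nb_conditional_logprob(s[i], n1, n2, phi)
    p[i] <- min(1, sum(exp(lp[lp <= lp[a[i] + 1] + log1p(1e-7)])))
  }
  pmax(p, .Machine$double.xmin)
}

#' Write a DE result table as TSV
#'
#' Header comments record the method, thresholds, dispersion and contrast.
#'
#' @param x A `de_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_de_result <- function(x, path) {
  assert_that(inherits(x, "de_result"), "x must be a de_result")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s extraction=%s conditions=%s alpha=%g q_cut=%g phi=%s",
                     attr(x, "method"), attr(x, "extraction"),
                     paste(attr(x, "conditions"), collapse = "_vs_"),
                     attr(x, "alpha"), attr(x, "q_cut"),
                     format(attr(x, "phi"))), con)
  suppressWarnings(write.table(as.data.frame(x), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}
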