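# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (enumeration, double loops, textbook
# definitions) and independent of the package's computational paths.

# Count matrix from a bare counts matrix: one extraction, two conditions
# split evenly over the columns.
mk_cm <- function(counts, extraction = "x", cond = c("A", "B"),
                  lengths = NULL) {
  n <- nrow(counts)
  rownames(counts) <- sprintf("g%04d", seq_len(n))
  nr <- ncol(counts) / 2
  ids <- sprintf("%s_s%d", extraction, seq_len(ncol(counts)))
  colnames(counts) <- ids
  samples <- data.frame(sample_id = ids, extraction = extraction,
                        condition = rep(cond, each = nr),
                        replicate = rep(seq_len(nr), 2))
  if (is.null(lengths)) lengths <- rep(1000, n)
  count_matrix(counts, samples,
               stats::setNames(lengths, rownames(counts)))
}

# Two-tissue model: n_shared genes with identical abundance in both tissues
# and conditions, plus one gene exclusive to tissue 1 ("gland").
excl_model <- function(w1 = 0.02, phi = 0.01, n_shared = 100,
                       excl_abundance = 250, base_seed = 42,
                       lengths = NULL) {
  n <- n_shared + 1
  lam <- array(0, dim = c(n, 2, 2),
               dimnames = list(sprintf("g%04d", seq_len(n)),
                               c("gland", "rest"), c("nurse", "forager")))
  set.seed(base_seed)
  base <- rlnorm(n_shared, log(50), 0.5)
  lam[seq_len(n_shared), 1, ] <- base
  lam[seq_len(n_shared), 2, ] <- base
  lam[n, 1, ] <- excl_abundance
  if (is.null(lengths)) lengths <- rep(1000, n)
  mixture_model(lam, lengths,
                data.frame(name = c("gland", "rest"),
                           mass_fraction = c(w1, 1 - w1), dispersion = phi))
}

# Hand-built DE result table for concordance tests.
make_de_result <- function(gene_id, call, direction, extraction = "focal",
                           method = "noiseq_like",
                           conditions = c("nurse", "forager")) {
  M <- ifelse(direction == paste0("up_in_", conditions[1]), 1,
              ifelse(direction == paste0("up_in_", conditions[2]), -1, 0))
  df <- data.frame(gene_id = gene_id, mean1 = 1, mean2 = 1, M = M, D = 1,
                   p_or_q = ifelse(call == "DE", 0.99, 0.1),
                   q_adj = NA_real_, call = call, direction = direction,
                   row.names = NULL)
  attr(df, "method") <- method
  attr(df, "extraction") <- extraction
  attr(df, "conditions") <- conditions
  attr(df, "alpha") <- 0.05
  attr(df, "q_cut") <- 0.8
  attr(df, "phi") <- NA_real_
  class(df) <- c("de_result", "data.frame")
  df
}

# -- Oracles -----------------------------------------------------------------

# Two-sided Fisher p by direct enumeration over the hypergeometric support.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]   # column-1 margin
  n <- tab[1, 2] + tab[2, 2]   # column-2 margin
  k <- tab[1, 1] + tab[1, 2]   # row-1 margin
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up from its textbook definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(n)
  out[o] <- pmin(1, q_sorted)
  out
}

# Conditional NB split distribution by normalizing products of dnbinom
# terms with a shared probability parameter (mu_i proportional to size_i):
# an independent route to the same law the package derives via lgamma.
nb_oracle_p <- function(a, b, n1, n2, phi) {
  s <- a + b
  if (s == 0) return(1)
  if (phi == 0) {
    probs <- dbinom(0:s, s, n1 / (n1 + n2))
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    probs <- dnbinom(0:s, size = r1, mu = r1) *
      dnbinom(s - (0:s), size = r2, mu = r2)
    probs <- probs / sum(probs)
  }
  min(1, sum(probs[probs <= probs[a + 1] * (1 + 1e-7)]))
}

# Minimum-likelihood two-sided binomial test by enumeration.
binom_oracle_p <- function(a, s, prob = 0.5) {
  probs <- dbinom(0:s, s, prob)
  min(1, sum(probs[probs <= probs[a + 1] * (1 + 1e-7)]))
}

# Signal-vs-noise probability by explicit double loop over genes and the
# full noise pool.
noiseq_oracle <- function(x, group, k = 0.5) {
  lev <- levels(as.factor(group))
  g1 <- which(group == lev[1]); g2 <- which(group == lev[2])
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  M <- log2((m1 + k) / (m2 + k)); D <- abs(m1 - m2)
  Ms <- numeric(0); Ds <- numeric(0)
  for (cols in list(g1, g2))
    for (i in seq_along(cols)) for (j in seq_along(cols)) if (i < j) {
      Ms <- c(Ms, log2((x[, cols[i]] + k) / (x[, cols[j]] + k)))
      Ds <- c(Ds, abs(x[, cols[i]] - x[, cols[j]]))
    }
  q <- numeric(length(M))
  for (g in seq_along(M)) {
    cnt <- 0
    for (p in seq_along(Ms))
      if (abs(Ms[p]) < abs(M[g]) && Ds[p] < D[g]) cnt <- cnt + 1
    q[g] <- cnt / length(Ms)
  }
  q
}
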