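# RPKM quantification, transcriptome membership at an RPKM threshold, and
# depth equalization by hypergeometric downsampling.

#' Compute RPKM from a count matrix
#'
#' RPKM_gs = 1e9 * c_gs / (N_s * L_g), with N_s the column sum of the count
#' matrix (the self-consistent library size at the count-matrix boundary)
#' and L_g the annotated transcript length in bp.
#'
#' @param x A `count_matrix`.
#' @return An object of class `rpkm_matrix`: list with `rpkm` (numeric matrix,
#'   same dimnames as the counts), `samples` (the metadata) and
#'   `gene_lengths`.
#' @export
compute_rpkm <- function(x) {
  assert_that(inherits(x, "count_matrix"), "x must be a count_matrix")
  N <- colSums(x$counts)
  zero <- names(N)[N == 0]
  assert_that(length(zero) == 0,
              sprintf("sample(s) with zero total counts: %s",
                      paste(zero, collapse = ", ")))
  rpkm <- 1e9 * sweep(x$counts / x$gene_lengths, 2, N, "/")
  structure(list(rpkm = rpkm, samples = x$samples,
                 gene_lengths = x$gene_lengths),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat(sprintf("rpkm_matrix: %d genes x %d samples\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

#' Write an RPKM matrix as TSV (4 decimal places)
#'
#' @param x An `rpkm_matrix`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rpkm <- function(x, path) {
  assert_that(inherits(x, "rpkm_matrix"), "x must be an rpkm_matrix")
  df <- data.frame(gene_id = rownames(x$rpkm),
                   round(x$rpkm, 4), check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcriptome membership at an RPKM threshold
#'
#' A gene belongs to the transcriptome of (extraction, condition) when its
#' replicate-mean RPKM is strictly greater than `tau` (default 10, the usual
#' expressed-gene cutoff for bulk libraries).
#'
#' @param x An `rpkm_matrix`.
#' @param extraction,condition Which samples to average over.
#' @param tau Positive RPKM threshold; membership requires mean RPKM > tau.
#' @return Object of class `transcriptome_set`: list with `extraction`,
#'   `condition`, `threshold`, `members` (character vector of gene ids) and
#'   `mean_rpkm` (named vector over all genes).
#' @export
transcriptome_membership <- function(x, extraction, condition, tau = 10) {
  assert_that(inherits(x, "rpkm_matrix"), "x must be an rpkm_matrix")
  assert_that(is.numeric(tau) && length(tau) == 1 && tau > 0,
              "tau must be a positive RPKM threshold")
  keep <- x$samples$extraction == extraction & x$samples$condition == condition
  assert_that(any(keep),
              sprintf("no samples for extraction '%s', condition '%s'",
                      extraction, condition))
  m <- rowMeans(x$rpkm[, keep, drop = FALSE])
  structure(list(extraction = extraction, condition = condition,
                 threshold = tau, members = names(m)[m > tau],
                 mean_rpkm = m),
            class = "transcriptome_set")
}

#' @export
print.transcriptome_set <- function(x, ...) {
  cat(sprintf("transcriptome_set: %s / %s, RPKM > %g: %d genes\n",
              x$extraction, x$condition, x$threshold, length(x$members)))
  invisible(x)
}

#' Write a transcriptome set as a one-column gene list
#'
#' The header comment records extraction, condition and threshold.
#'
#' @param x A `transcriptome_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_transcriptome_set <- function(x, path) {
  assert_that(inherits(x, "transcriptome_set"), "x must be a transcriptome_set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# extraction=%s condition=%s tau=%g",
                     x$extraction, x$condition, x$threshold), con)
  writeLines("gene_id", con)
  writeLines(x$members, con)
  invisible(path)
}

#' Downsample every sample to a common sequencing depth
#'
#' Thins each column without replacement to exactly `target_depth` total
#' reads (a multivariate hypergeometric draw per sample), emulating the
#' equal-depth design of comparing libraries at the same number of
#' quality-controlled reads.  Deterministic given `seed`; each sample uses
#' its own derived stream.
#'
#' @param x A `count_matrix`.
#' @param target_depth Desired total per sample; must not exceed any sample's
#'   current total.
#' @param seed Integer seed.
#' @return A `count_matrix` whose columns each sum exactly to `target_depth`.
#'   Columns already at the target are returned unchanged.
#' @export
downsample_counts <- function(x, target_depth, seed = 1L) {
  assert_that(inherits(x, "count_matrix"), "x must be a count_matrix")
  assert_that(is_count(target_depth), "target_depth must be a positive integer")
  N <- colSums(x$counts)
  low <- names(N)[N < target_depth]
  assert_that(length(low) == 0,
              sprintf("target_depth %d exceeds total counts of sample(s): %s",
                      as.integer(target_depth), paste(low, collapse = ", ")))
  counts <- x$counts
  for (s in seq_len(ncol(counts))) {
    if (N[s] == target_depth) next
    with_seed(derive_seed(seed, "downsample", colnames(counts)[s]), {
      counts[, s] <- rmvhyper(counts[, s], target_depth)
    })
  }
  out <- count_matrix(counts, x$samples, x$gene_lengths)
  attr(out, "truth") <- attr(x, "truth")
  out
}

# One multivariate hypergeometric draw: sample k reads without replacement
# from an urn with x[i] reads of gene i, via sequential univariate draws.
rmvhyper <- function(x, k) {
  out <- integer(length(x))
  rem <- sum(x)
  for (i in seq_along(x)) {
    if (k == 0) break
    d <- rhyper(1, x[i], rem - x[i], k)
    out[i] <- d
    k <- k - d
    rem <- rem - x[i]
  }
  out
}
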