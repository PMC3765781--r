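# The pipeline's universal currency: an integer genes x samples count matrix
# with per-sample metadata (extraction, condition, replicate) and per-gene
# transcript lengths, mirroring the output of a read-counting stage.

#' Construct a count matrix with sample metadata and gene lengths
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).  All entries non-negative whole
#'   numbers.
#' @param samples Data frame with columns `sample_id`, `extraction`,
#'   `condition`, `replicate`; one row per column of `counts`.
#' @param gene_lengths Named numeric vector of transcript lengths in bp
#'   (>= 1), covering every gene in `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, gene_lengths) {
  assert_that(is.matrix(counts) && is.numeric(counts),
              "counts must be a numeric matrix")
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts must have unique gene-id rownames")
  assert_that(!is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
              "counts must have unique sample-id colnames")
  assert_that(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == floor(counts)),
              "counts must be non-negative integers")
  assert_that(is.data.frame(samples) &&
                all(c("sample_id", "extraction", "condition", "replicate")
                    %in% names(samples)),
              "samples must have sample_id, extraction, condition, replicate")
  assert_that(setequal(samples$sample_id, colnames(counts)) &&
                nrow(samples) == ncol(counts),
              "every sample must have exactly one metadata row")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  assert_that(length(missing_len) == 0,
              sprintf("missing gene length for: %s",
                      paste(utils::head(missing_len, 3), collapse = ", ")))
  gene_lengths <- gene_lengths[rownames(counts)]
  assert_that(all(is.finite(gene_lengths)) && all(gene_lengths >= 1),
              "gene lengths must be finite and >= 1")
  structure(list(counts = counts, samples = samples,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$extraction, x$samples$condition)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Combine count matrices sharing a gene universe
#'
#' Column-binds several `count_matrix` objects (e.g. separate extractions of
#' one simulated experiment) after checking that gene ids and lengths agree.
#'
#' @param ... `count_matrix` objects, or a single list of them.
#' @return A single `count_matrix`.
#' @export
combine_count_matrices <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "count_matrix")) xs <- xs[[1]]
  assert_that(length(xs) >= 1 && all(vapply(xs, inherits, logical(1),
                                            "count_matrix")),
              "all inputs must be count_matrix objects")
  ref <- xs[[1]]
  for (x in xs[-1]) {
    assert_that(identical(rownames(x$counts), rownames(ref$counts)),
                "gene ids differ between count matrices")
    assert_that(identical(x$gene_lengths, ref$gene_lengths),
                "gene lengths differ between count matrices")
  }
  counts <- do.call(cbind, lapply(xs, `[[`, "counts"))
  samples <- do.call(rbind, lapply(xs, `[[`, "samples"))
  count_matrix(counts, samples, ref$gene_lengths)
}

#' Write a simulated or real experiment to tab-separated files
#'
#' Writes `counts.tsv` (first column `gene_id`, one column per sample),
#' `samples.tsv` (sample_id, extraction, condition, replicate),
#' `gene_lengths.tsv` (gene_id, length_bp), and, when truth labels are
#' supplied, `truth.tsv` (gene_id, tissue, label, log2fc).
#'
#' @param x A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth data frame as produced by
#'   [mixture_model()] (`model$truth`).
#' @return Invisibly, the vector of paths written.
#' @export
write_experiment <- function(x, dir, truth = NULL) {
  assert_that(inherits(x, "count_matrix"), "x must be a count_matrix")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, row.names = NULL)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "samples.tsv")
  write.table(x$samples, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "gene_lengths.tsv")
  write.table(data.frame(gene_id = names(x$gene_lengths),
                         length_bp = as.numeric(x$gene_lengths)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(truth)) {
    p <- file.path(dir, "truth.tsv")
    write.table(truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir Directory containing `counts.tsv`, `samples.tsv` and
#'   `gene_lengths.tsv` (and optionally `truth.tsv`).
#' @return A list with elements `counts` (a `count_matrix`) and `truth`
#'   (data frame or `NULL`).
#' @export
read_experiment <- function(dir) {
  for (f in c("counts.tsv", "samples.tsv", "gene_lengths.tsv"))
    assert_that(file.exists(file.path(dir, f)),
                sprintf("missing %s in %s", f, dir))
  cdf <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  samples <- read.delim(file.path(dir, "samples.tsv"),
                        colClasses = "character")
  samples$replicate <- as.integer(samples$replicate)
  len <- read.delim(file.path(dir, "gene_lengths.tsv"))
  gl <- stats::setNames(as.numeric(len$length_bp), len$gene_id)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read.delim(truth_path) else NULL
  list(counts = count_matrix(counts, samples, gl), truth = truth)
}

# Subset samples by extraction (and optionally condition); errors when empty.
subset_samples <- function(x, extraction = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(extraction)) keep <- keep & x$samples$extraction %in% extraction
  if (!is.null(condition)) keep <- keep & x$samples$condition %in% condition
  assert_that(any(keep), sprintf("no samples match extraction=%s condition=%s",
                                 paste(extraction, collapse = "/"),
                                 paste(condition, collapse = "/")))
  count_matrix(x$counts[, keep, drop = FALSE],
               x$samples[keep, , drop = FALSE], x$gene_lengths)
}
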