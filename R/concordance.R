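# Cross-extraction comparisons: do genes called DE in a focal tissue remain
# significant -- and directionally consistent -- when the tissue is assayed
# only as part of the composite structure containing it?

# Replicate-mean RPKM for one extraction/condition.
replicate_mean_rpkm <- function(x, extraction, condition) {
  assert_that(inherits(x, "rpkm_matrix"), "x must be an rpkm_matrix")
  keep <- x$samples$extraction == extraction &
    x$samples$condition == condition
  assert_that(any(keep),
              sprintf("no samples for extraction '%s', condition '%s'",
                      extraction, condition))
  rowMeans(x$rpkm[, keep, drop = FALSE])
}

#' Concordance table constructor
#'
#' Counts of focal-tissue DE genes that are not significant, significant in
#' the same direction, or significant in the opposite direction in the
#' composite extraction.  Usually produced by [classify_cross_extraction()];
#' callable directly to analyse published or external counts.
#'
#' @param not_sig,same_direction,opposite_direction Non-negative integer
#'   counts.
#' @param focal,composite Extraction names (annotation only).
#' @param categories Optional per-gene data frame (`gene_id`, `category`).
#' @return Object of class `concordance_table` with fields `n_focal_de`,
#'   `n_not_sig`, `n_same_direction`, `n_opposite_direction`, `categories`.
#' @export
concordance_table <- function(not_sig, same_direction, opposite_direction,
                              focal = NA_character_,
                              composite = NA_character_,
                              categories = NULL) {
  for (v in c(not_sig, same_direction, opposite_direction))
    assert_that(length(v) == 1 && is.numeric(v) && v >= 0 && v == floor(v),
                "category counts must be non-negative integers")
  n_focal_de <- not_sig + same_direction + opposite_direction
  if (!is.null(categories)) {
    tab <- table(factor(categories$category,
                        levels = c("not_sig", "same_direction",
                                   "opposite_direction")))
    assert_that(tab[["not_sig"]] == not_sig &&
                  tab[["same_direction"]] == same_direction &&
                  tab[["opposite_direction"]] == opposite_direction,
                "per-gene categories do not reconcile with the counts")
  }
  structure(list(focal = focal, composite = composite,
                 n_focal_de = n_focal_de, n_not_sig = not_sig,
                 n_same_direction = same_direction,
                 n_opposite_direction = opposite_direction,
                 categories = categories),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("concordance_table: %s vs %s\n", x$focal, x$composite))
  cat(sprintf("  focal DE genes:        %d\n", x$n_focal_de))
  cat(sprintf("  not significant:       %d (%.1f%%)\n",
              x$n_not_sig, s$pct_not_sig))
  cat(sprintf("  same direction:        %d (%.1f%%)\n",
              x$n_same_direction, s$pct_same_direction))
  cat(sprintf("  opposite direction:    %d (%.1f%%)\n",
              x$n_opposite_direction, s$pct_opposite_direction))
  invisible(x)
}

#' Proportion summary of a concordance table
#'
#' @param object A `concordance_table`.
#' @param ... Unused.
#' @return List with the three category percentages (of focal DE genes).
#' @export
summary.concordance_table <- function(object, ...) {
  n <- object$n_focal_de
  pct <- function(k) if (n > 0) 100 * k / n else NA_real_
  list(n_focal_de = n,
       pct_not_sig = pct(object$n_not_sig),
       pct_same_direction = pct(object$n_same_direction),
       pct_opposite_direction = pct(object$n_opposite_direction))
}

#' Classify focal-tissue DE genes by their composite-extraction behaviour
#'
#' Iterates over the genes called DE in the focal extraction.  A gene is
#' `not_sig` when the composite result calls it not DE or omits it entirely
#' (a filtered or zero-count gene is a false-negative candidate, not a
#' contradiction); otherwise it is `same_direction` or `opposite_direction`
#' by comparing direction fields.
#'
#' @param focal_results,composite_results `de_result` objects from the same
#'   method, thresholds and condition contrast.
#' @return A [concordance_table()] with the per-gene category mapping.
#' @export
classify_cross_extraction <- function(focal_results, composite_results) {
  assert_that(inherits(focal_results, "de_result") &&
                inherits(composite_results, "de_result"),
              "inputs must be de_result objects")
  for (a in c("method", "conditions", "alpha", "q_cut"))
    assert_that(identical(attr(focal_results, a), attr(composite_results, a)),
                sprintf("focal and composite results differ in %s; compare like with like", a))
  assert_that(nrow(focal_results) == 0 ||
                length(intersect(focal_results$gene_id,
                                 composite_results$gene_id)) > 0,
              "gene universes do not overlap")
  de <- focal_results[focal_results$call == "DE", , drop = FALSE]
  idx <- match(de$gene_id, composite_results$gene_id)
  comp_call <- ifelse(is.na(idx), "not_DE", composite_results$call[idx])
  comp_dir <- ifelse(is.na(idx), "none", composite_results$direction[idx])
  category <- ifelse(comp_call != "DE", "not_sig",
                     ifelse(comp_dir == de$direction, "same_direction",
                            "opposite_direction"))
  categories <- data.frame(gene_id = de$gene_id, category = category,
                           row.names = NULL)
  concordance_table(sum(category == "not_sig"),
                    sum(category == "same_direction"),
                    sum(category == "opposite_direction"),
                    focal = attr(focal_results, "extraction"),
                    composite = attr(composite_results, "extraction"),
                    categories = categories)
}

#' Concordance analysis restricted to a gene list
#'
#' Same classification as [classify_cross_extraction()] but only for genes
#' in `gene_list` (e.g. a curated transcription-factor list).  Ids absent
#' from both result sets are reported via a warning, not an error.
#'
#' @inheritParams classify_cross_extraction
#' @param gene_list Non-empty character vector of gene ids.
#' @return A [concordance_table()].
#' @export
subset_analysis <- function(focal_results, composite_results, gene_list) {
  assert_that(is.character(gene_list) && length(gene_list) > 0,
              "gene_list must be a non-empty character vector")
  universe <- union(focal_results$gene_id, composite_results$gene_id)
  unresolved <- setdiff(gene_list, universe)
  if (length(unresolved))
    warning(sprintf("%d gene id(s) not found in the result sets: %s",
                    length(unresolved),
                    paste(utils::head(unresolved, 5), collapse = ", ")))
  keep <- focal_results$gene_id %in% gene_list
  sub <- focal_results[keep, , drop = FALSE]
  for (a in c("method", "extraction", "conditions", "alpha", "q_cut", "phi"))
    attr(sub, a) <- attr(focal_results, a)
  class(sub) <- class(focal_results)
  classify_cross_extraction(sub, composite_results)
}

#' Presence/absence of genes between focal and composite transcriptomes
#'
#' Applies [transcriptome_membership()] at threshold `tau` to both
#' extractions in one condition and reports the genes present in exactly one
#' of the two, binned by expression level in the extraction where the gene
#' is present (default bins (tau,30], (30,100], (100,300], (300,Inf) RPKM).
#'
#' @param x An `rpkm_matrix` containing both extractions.
#' @param focal,composite Extraction names.
#' @param condition Condition to analyse.
#' @param tau Positive RPKM membership threshold.
#' @param bin_edges Increasing interior bin edges above `tau`.
#' @return Object of class `presence_absence_table`: list with `focal_only`
#'   and `composite_only` data frames (gene_id, rpkm, bin), bin count
#'   tables, and the parameters used.
#' @export
presence_absence_table <- function(x, focal, composite, condition,
                                   tau = 10, bin_edges = c(30, 100, 300)) {
  assert_that(is.numeric(tau) && length(tau) == 1 && tau > 0,
              "tau must be positive")
  assert_that(all(diff(c(tau, bin_edges)) > 0),
              "bin_edges must be increasing and above tau")
  mf <- transcriptome_membership(x, focal, condition, tau)
  mc <- transcriptome_membership(x, composite, condition, tau)
  breaks <- c(tau, bin_edges, Inf)
  bin_of <- function(v) cut(v, breaks = breaks, include.lowest = FALSE)
  focal_only_ids <- setdiff(mf$members, mc$members)
  comp_only_ids <- setdiff(mc$members, mf$members)
  focal_only <- data.frame(gene_id = focal_only_ids,
                           rpkm = mf$mean_rpkm[focal_only_ids],
                           bin = bin_of(mf$mean_rpkm[focal_only_ids]),
                           row.names = NULL)
  composite_only <- data.frame(gene_id = comp_only_ids,
                               rpkm = mc$mean_rpkm[comp_only_ids],
                               bin = bin_of(mc$mean_rpkm[comp_only_ids]),
                               row.names = NULL)
  structure(list(focal = focal, composite = composite, condition = condition,
                 threshold = tau,
                 focal_only = focal_only, composite_only = composite_only,
                 focal_only_bins = table(focal_only$bin),
                 composite_only_bins = table(composite_only$bin)),
            class = "presence_absence_table")
}

#' @export
print.presence_absence_table <- function(x, ...) {
  cat(sprintf("presence_absence_table (%s, RPKM > %g):\n",
              x$condition, x$threshold))
  cat(sprintf("  +%s / -%s: %d genes\n", x$focal, x$composite,
              nrow(x$focal_only)))
  print(x$focal_only_bins)
  cat(sprintf("  -%s / +%s: %d genes\n", x$focal, x$composite,
              nrow(x$composite_only)))
  print(x$composite_only_bins)
  invisible(x)
}

#' Dilution-ratio set constructor
#'
#' @param n_above_1,n_at_or_below_1,n_undefined Non-negative integer counts.
#' @param ratios Optional named vector of the per-gene ratios (defined ones).
#' @param focal,composite Extraction names (annotation only).
#' @return Object of class `dilution_ratio_set`.
#' @export
dilution_ratio_set <- function(n_above_1, n_at_or_below_1, n_undefined = 0,
                               ratios = NULL, focal = NA_character_,
                               composite = NA_character_) {
  for (v in c(n_above_1, n_at_or_below_1, n_undefined))
    assert_that(length(v) == 1 && is.numeric(v) && v >= 0 && v == floor(v),
                "counts must be non-negative integers")
  structure(list(focal = focal, composite = composite,
                 n_above_1 = n_above_1, n_at_or_below_1 = n_at_or_below_1,
                 n_undefined = n_undefined, ratios = ratios),
            class = "dilution_ratio_set")
}

#' @export
print.dilution_ratio_set <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("dilution_ratio_set: %s / %s\n", x$focal, x$composite))
  cat(sprintf("  ratio > 1:  %d (%.1f%%)\n", x$n_above_1, s$pct_above_1))
  cat(sprintf("  ratio <= 1: %d\n", x$n_at_or_below_1))
  cat(sprintf("  undefined (composite RPKM 0): %d\n", x$n_undefined))
  invisible(x)
}

#' Proportion summary of a dilution-ratio set
#'
#' The percentage above 1 is taken over the defined ratios (undefined genes
#' -- composite RPKM zero -- are tracked separately).
#'
#' @param object A `dilution_ratio_set`.
#' @param ... Unused.
#' @return List with `n_defined`, `pct_above_1` and `n_undefined`.
#' @export
summary.dilution_ratio_set <- function(object, ...) {
  n <- object$n_above_1 + object$n_at_or_below_1
  list(n_defined = n,
       pct_above_1 = if (n > 0) 100 * object$n_above_1 / n else NA_real_,
       n_undefined = object$n_undefined)
}

#' Focal-to-composite RPKM dilution ratios
#'
#' r_g = (replicate-mean focal RPKM) / (replicate-mean composite RPKM) for
#' each gene in `gene_set` (typically the focal tissue's DE genes).  Ratios
#' strictly greater than 1 indicate dilution of the focal signal in the
#' composite extraction; under the mass-weighted mixture model a gene
#' expressed only in the focal tissue has expected ratio 1/w, the inverse
#' of the tissue's mass fraction.  Genes with composite RPKM 0 are counted
#' as undefined and excluded from the above/below tally; a gene with focal
#' RPKM 0 (possible only if it was force-listed) contributes r = 0.
#'
#' @param x An `rpkm_matrix` containing both extractions.
#' @param focal,composite Extraction names.
#' @param condition Condition whose replicate means are compared.
#' @param gene_set Non-empty character vector of gene ids.
#' @return A [dilution_ratio_set()] with per-gene ratios attached.
#' @export
dilution_ratios <- function(x, focal, composite, condition, gene_set) {
  assert_that(is.character(gene_set) && length(gene_set) > 0,
              "gene_set must be a non-empty character vector")
  mf <- replicate_mean_rpkm(x, focal, condition)
  mc <- replicate_mean_rpkm(x, composite, condition)
  assert_that(all(gene_set %in% names(mf)),
              "gene_set contains ids absent from the RPKM matrix")
  f <- mf[gene_set]; cpos <- mc[gene_set]
  defined <- cpos > 0
  r <- f[defined] / cpos[defined]
  dilution_ratio_set(n_above_1 = sum(r > 1),
                     n_at_or_below_1 = sum(r <= 1),
                     n_undefined = sum(!defined),
                     ratios = r, focal = focal, composite = composite)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule over the hypergeometric
#' support with fixed margins (tied tables included within relative
#' tolerance 1e-7), and the sample odds ratio ad/bc (Inf when bc = 0 with
#' ad > 0).
#'
#' @param tab 2x2 matrix of non-negative integer counts with at least one
#'   positive margin.
#' @return Object of class `fisher_result`: list with `table`, `odds_ratio`,
#'   `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == c(2, 2)), "table must be 2x2")
  assert_that(all(is.finite(tab)) && all(tab >= 0) &&
                all(tab == floor(tab)),
              "cells must be non-negative integers")
  assert_that(sum(tab) > 0, "table must have at least one nonzero margin")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NaN
  p <- fisher.test(tab)$p.value
  structure(list(table = tab, odds_ratio = or, p_value = min(1, p)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (two-sided)\n")
  print(x$table)
  cat(sprintf("  odds ratio (ad/bc) = %.4g, p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Compare a property between two focal tissues by Fisher's exact test
#'
#' Builds the 2x2 table property-present/absent x tissue-A/tissue-B and
#' delegates to [fisher_exact_2x2()].  For `concordance_table` inputs the
#' property is "not significant in the composite"; for `dilution_ratio_set`
#' inputs it is "dilution ratio > 1" (undefined-ratio genes are excluded
#' before the table is built).
#'
#' @param table_a,table_b Two objects of the same class, either both
#'   `concordance_table` or both `dilution_ratio_set`.
#' @return A `fisher_result`; the 2x2 table used is in `$table` with the
#'   tissues as rows.
#' @export
compare_focal_tissues <- function(table_a, table_b) {
  if (inherits(table_a, "concordance_table")) {
    assert_that(inherits(table_b, "concordance_table"),
                "both inputs must be the same type")
    tab <- rbind(c(table_a$n_not_sig, table_a$n_focal_de - table_a$n_not_sig),
                 c(table_b$n_not_sig, table_b$n_focal_de - table_b$n_not_sig))
    dimnames(tab) <- list(c(table_a$focal, table_b$focal),
                          c("not_sig_in_composite", "sig_in_composite"))
  } else if (inherits(table_a, "dilution_ratio_set")) {
    assert_that(inherits(table_b, "dilution_ratio_set"),
                "both inputs must be the same type")
    tab <- rbind(c(table_a$n_above_1, table_a$n_at_or_below_1),
                 c(table_b$n_above_1, table_b$n_at_or_below_1))
    dimnames(tab) <- list(c(table_a$focal, table_b$focal),
                          c("ratio_above_1", "ratio_at_or_below_1"))
  } else {
    abort_validation("inputs must be concordance_table or dilution_ratio_set")
  }
  fisher_exact_2x2(tab)
}
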