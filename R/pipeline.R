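# End-to-end orchestration: simulate an experiment to TSV files, or run the
# full analysis chain (depth equalization -> RPKM -> membership -> DE per
# method -> concordance / presence-absence / dilution / Fisher comparisons)
# and emit per-analysis TSVs plus one summary JSON.

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config accepted by [run_simulate()] and
#' [run_full_analysis()].  Top-level keys: `seed`; `simulation` (effects,
#' tissues, extractions, n_replicates, depth, grains); `paths` (counts dir,
#' used instead of `simulation` when analysing existing files); `analysis`
#' (composite, condition, tau, bin_edges, methods, alpha, q_cut,
#' pseudo_count, target_depth).
#'
#' @return The default configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulation = list(
      n_genes = 5000,
      de_fraction = 0.1,
      log2fc_location = 2,
      log2fc_scale = 0.5,
      exclusive_fraction = 0.2,
      opposite_fraction = 0.05,
      baseline_meanlog = log(50),
      baseline_sdlog = 1.5,
      conditions = c("nurse", "forager"),
      tissues = data.frame(
        name = c("gland", "gut", "remainder"),
        mass_fraction = c(0.02, 0.30, 0.68),
        dispersion = c(0.05, 0.05, 0.05)),
      extractions = NULL,   # default: all tissues + composite
      n_replicates = 2,
      depth = 2e6,
      grains = Inf),
    paths = NULL,
    analysis = list(
      composite = "composite",
      focal = NULL,         # default: every non-composite extraction
      condition = NULL,     # default: first condition present
      tau = 10,
      bin_edges = c(30, 100, 300),
      methods = c("nb_exact", "noiseq_like"),
      alpha = 0.05,
      q_cut = 0.8,
      pseudo_count = 0.5,
      target_depth = NULL)) # default: equalize to the smallest sample
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of
#' [default_pipeline_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]]) &&
          !is.data.frame(base[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  cfg <- merge_cfg(cfg, user)
  if (!is.data.frame(cfg$simulation$tissues) &&
      !is.null(cfg$simulation$tissues)) {
    cfg$simulation$tissues <- do.call(
      rbind, lapply(cfg$simulation$tissues, function(t)
        data.frame(name = t$name, mass_fraction = t$mass_fraction,
                   dispersion = t$dispersion)))
  }
  cfg
}

#' Simulate an experiment and write it to disk
#'
#' Builds the mixture model from `config$simulation`, simulates counts for
#' every requested extraction and condition, and writes the count, sample,
#' gene-length and truth TSVs plus a `manifest.json` recording every
#' parameter and the seed (so the run can be reproduced from the manifest
#' alone).
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the simulated `count_matrix`.
#' @export
run_simulate <- function(config = default_pipeline_config(), out_dir) {
  sim <- config$simulation
  assert_that(!is.null(sim), "config$simulation is required")
  eff <- effect_config(
    n_genes = sim$n_genes, de_fraction = sim$de_fraction,
    log2fc_location = sim$log2fc_location, log2fc_scale = sim$log2fc_scale,
    exclusive_fraction = sim$exclusive_fraction,
    opposite_fraction = sim$opposite_fraction,
    baseline_meanlog = sim$baseline_meanlog,
    baseline_sdlog = sim$baseline_sdlog,
    conditions = as.character(sim$conditions),
    seed = config$seed)
  model <- build_mixture_model(eff, sim$tissues)
  grains <- sim$grains
  # JSON manifests and YAML configs may carry infinity as a string
  if (is.character(grains))
    grains <- if (grains %in% c("Inf", "infinite")) Inf else as.numeric(grains)
  extractions <- sim$extractions
  if (is.null(extractions))
    extractions <- c(model$tissues$name, "composite")
  cm <- simulate_experiment(
    model, extractions = extractions, n_replicates = sim$n_replicates,
    depth = sim$depth,
    homogenization = homogenization_spec(grains = grains),
    seed = config$seed)
  write_experiment(cm, out_dir, truth = model$truth)
  manifest <- list(stage = "simulate", seed = config$seed,
                   simulation = sim, package_version =
                     as.character(utils::packageVersion("compexr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(cm)
}

#' Run the full composite-extraction analysis
#'
#' Executes the complete chain on either freshly simulated data
#' (`config$simulation`) or files on disk (`config$paths$dir`, the layout
#' written by [run_simulate()]): depth equalization, RPKM, transcriptome
#' membership, per-extraction DE testing with every configured method,
#' cross-extraction concordance for each focal tissue, presence/absence and
#' dilution-ratio analyses, and Fisher comparisons between the first two
#' focal tissues.  Per-analysis TSVs and a `summary.json` are written to
#' `out_dir`.
#'
#' When a concordance table has zero focal-DE genes the Fisher comparison is
#' skipped and the reason logged.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary list.
#' @export
run_full_analysis <- function(config = default_pipeline_config(), out_dir,
                              quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$paths) && !is.null(config$paths$dir)) {
    log_msg("loading experiment from %s", config$paths$dir)
    exp_data <- read_experiment(config$paths$dir)
    cm <- exp_data$counts
  } else {
    log_msg("simulating experiment")
    sim_dir <- file.path(out_dir, "simdata")
    cm <- run_simulate(config, sim_dir)
  }

  an <- config$analysis
  composite <- an$composite
  extractions <- unique(cm$samples$extraction)
  assert_that(composite %in% extractions,
              sprintf("composite extraction '%s' not present (have: %s)",
                      composite, paste(extractions, collapse = ", ")))
  focal <- an$focal
  if (is.null(focal)) focal <- setdiff(extractions, composite)
  assert_that(length(focal) >= 1, "at least one focal extraction is required")
  conditions <- unique(cm$samples$condition)
  assert_that(length(conditions) == 2, "exactly two conditions are required")
  cond1 <- if (is.null(an$condition)) conditions[1] else an$condition

  target <- an$target_depth
  if (is.null(target)) target <- min(colSums(cm$counts))
  log_msg("equalizing depth to %d reads/sample", as.integer(target))
  cm <- downsample_counts(cm, target, seed = config$seed)

  rp <- compute_rpkm(cm)
  membership <- list()
  for (ex in extractions) for (cc in conditions) {
    ts <- transcriptome_membership(rp, ex, cc, tau = an$tau)
    membership[[paste(ex, cc, sep = "_")]] <- length(ts$members)
    write_transcriptome_set(ts, file.path(
      out_dir, sprintf("transcriptome_%s_%s.tsv", ex, cc)))
  }

  summary_out <- list(
    parameters = list(seed = config$seed, tau = an$tau, alpha = an$alpha,
                      q_cut = an$q_cut, pseudo_count = an$pseudo_count,
                      target_depth = target, composite = composite,
                      focal = focal, conditions = conditions),
    transcriptome_sizes = membership,
    methods = list())

  for (method in an$methods) {
    log_msg("DE testing (%s)", method)
    cfg <- de_config(method = method, alpha = an$alpha, q_cut = an$q_cut,
                     pseudo_count = an$pseudo_count)
    de_res <- list()
    for (ex in c(focal, composite)) {
      de_res[[ex]] <- de_test(cm, ex, conditions = conditions, config = cfg)
      write_de_result(de_res[[ex]], file.path(
        out_dir, sprintf("de_%s_%s.tsv", method, ex)))
    }

    m_out <- list(n_de = lapply(de_res, function(r) sum(r$call == "DE")))
    conc <- list()
    dil <- list()
    for (ex in focal) {
      ct <- classify_cross_extraction(de_res[[ex]], de_res[[composite]])
      conc[[ex]] <- ct
      write.table(ct$categories, file.path(
        out_dir, sprintf("concordance_%s_%s.tsv", method, ex)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      m_out$concordance[[ex]] <- c(
        list(n_focal_de = ct$n_focal_de, n_not_sig = ct$n_not_sig,
             n_same_direction = ct$n_same_direction,
             n_opposite_direction = ct$n_opposite_direction),
        summary(ct)[-1])
      de_genes <- ct$categories$gene_id
      if (length(de_genes) > 0) {
        dr <- dilution_ratios(rp, ex, composite, cond1, de_genes)
        dil[[ex]] <- dr
        m_out$dilution[[ex]] <- c(
          list(n_above_1 = dr$n_above_1,
               n_at_or_below_1 = dr$n_at_or_below_1,
               n_undefined = dr$n_undefined),
          summary(dr)["pct_above_1"])
      } else {
        log_msg("no focal-DE genes in %s (%s); dilution analysis skipped",
                ex, method)
      }
      pa <- presence_absence_table(rp, ex, composite, cond1,
                                   tau = an$tau, bin_edges = an$bin_edges)
      m_out$presence_absence[[ex]] <- list(
        n_focal_only = nrow(pa$focal_only),
        n_composite_only = nrow(pa$composite_only),
        focal_only_bins = as.list(pa$focal_only_bins),
        composite_only_bins = as.list(pa$composite_only_bins))
    }

    if (length(focal) >= 2) {
      a <- focal[1]; b <- focal[2]
      if (conc[[a]]$n_focal_de > 0 && conc[[b]]$n_focal_de > 0) {
        fr <- compare_focal_tissues(conc[[a]], conc[[b]])
        m_out$fisher_concordance <- list(p_value = fr$p_value,
                                         odds_ratio = fr$odds_ratio)
      } else {
        log_msg("Fisher concordance comparison skipped: a focal tissue has no DE genes")
      }
      if (!is.null(dil[[a]]) && !is.null(dil[[b]]) &&
          (dil[[a]]$n_above_1 + dil[[a]]$n_at_or_below_1) > 0 &&
          (dil[[b]]$n_above_1 + dil[[b]]$n_at_or_below_1) > 0) {
        fr <- compare_focal_tissues(dil[[a]], dil[[b]])
        m_out$fisher_dilution <- list(p_value = fr$p_value,
                                      odds_ratio = fr$odds_ratio)
      } else {
        log_msg("Fisher dilution comparison skipped: no defined ratios")
      }
    }
    summary_out$methods[[method]] <- m_out
  }

  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  log_msg("summary written to %s", file.path(out_dir, "summary.json"))
  invisible(summary_out)
}
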