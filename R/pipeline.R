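## Pipeline configuration and the end-to-end runner: cluster -> matrices ->
## annotation -> enrichment -> trees -> group stats -> quantification.
## One log line per stage with a parameter fingerprint and output sizes;
## the configuration is echoed into the output directory for provenance.

#' Pipeline configuration
#'
#' @param identity_threshold Ortholog clustering identity (default 0.85).
#' @param panel_identity_threshold Reference-panel acceptance identity
#'   (default 0.90).
#' @param evalue_threshold Operational "E-value = 0" (default 1e-180; a
#'   literal floating-point zero from the re-implemented Karlin-Altschul
#'   formula would be representation-dependent).
#' @param bootstrap_replicates Bootstrap replicates for trees (default
#'   1000).
#' @param alpha Significance level (default 0.05).
#' @param genome_size_for_quant Genome size for copy conversion, Mbp
#'   (default 2.21).
#' @param bp_molar_mass Mean bp molar mass, g/mol/bp (default 655).
#' @param linkage Dendrogram linkage (default "average").
#' @param prefilter Use clustering prefilter (default TRUE).
#' @param seed Master seed for all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(identity_threshold = 0.85,
                            panel_identity_threshold = 0.90,
                            evalue_threshold = 1e-180,
                            bootstrap_replicates = 1000L,
                            alpha = 0.05,
                            genome_size_for_quant = 2.21,
                            bp_molar_mass = 655,
                            linkage = "average",
                            prefilter = TRUE,
                            seed = 1L) {
  for (thr in c(identity_threshold, panel_identity_threshold))
    if (thr <= 0 || thr > 1)
      stop("identity thresholds must lie in (0, 1]", call. = FALSE)
  if (bootstrap_replicates < 1L)
    stop("bootstrap_replicates must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(identity_threshold = identity_threshold,
                 panel_identity_threshold = panel_identity_threshold,
                 evalue_threshold = evalue_threshold,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 alpha = alpha,
                 genome_size_for_quant = genome_size_for_quant,
                 bp_molar_mass = bp_molar_mass,
                 linkage = linkage, prefilter = prefilter,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @noRd
.log_stage <- function(stage, t0, note) {
  message(sprintf("[%s] %.2fs | %s", stage,
                  as.numeric(Sys.time()) - t0, note))
}

#' @noRd
.echo_config <- function(config, out_dir) {
  df <- data.frame(parameter = names(config),
                   value = vapply(config, function(v)
                     paste(format(v), collapse = ","), character(1)))
  write_tsv(df, file.path(out_dir, "config.tsv"))
}

#' Run the full comparative pan-genomics pipeline
#'
#' Executes, in order: pseudogene filtering + ortholog clustering, pan
#' matrices and summary, reference-panel annotation, subsystem enrichment,
#' presence/absence and MLST trees with bootstrap, genome-feature group
#' statistics, and measurement quantification — each stage only when its
#' inputs are given. Any stage error aborts with a stage-labelled message;
#' outputs of completed stages are already written when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @param strains List of [strain_cds_set()] objects.
#' @param panel Optional [reference_gene_panel()].
#' @param subsystems Optional subsystem table (`cds_id`, `strain_id`,
#'   `subsystem`).
#' @param mlst Optional named list of MLST locus alignments.
#' @param measurements Optional measurement table (`strain_id`, `group`,
#'   `timepoint_h`, `value`); summarised, and compared as 24 h vs 48 h
#'   fold changes when both time points are present.
#' @param standards Optional qPCR standard table (`copies`, `cq`).
#' @param out_dir Optional output directory; created if missing. All
#'   tabular outputs, consensus FASTA and Newick trees are written there
#'   and the configuration is echoed to `config.tsv`.
#' @return An object of class `pipeline_result` (a list of all stage
#'   outputs).
#' @export
run_pipeline <- function(config, strains, panel = NULL, subsystems = NULL,
                         mlst = NULL, measurements = NULL, standards = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(strains) < 2L)
    stop_stage("run_pipeline", ">= 2 strains required")
  groups <- vapply(strains, function(s) s$group, character(1))
  names(groups) <- vapply(strains, function(s) s$strain_id, character(1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .echo_config(config, out_dir)
  }
  emit <- function(name, df) {
    if (!is.null(out_dir)) write_tsv(df, file.path(out_dir, name))
  }
  res <- list(config = config, groups = groups)

  ## stage: cluster
  t0 <- as.numeric(Sys.time())
  pool <- pool_cds(strains, drop_pseudogenes = TRUE)
  clusters <- cluster_orthologs(pool, threshold = config$identity_threshold,
                                prefilter = config$prefilter)
  res$clusters <- clusters
  emit("clusters.tsv", do.call(rbind, lapply(clusters, function(cl)
    data.frame(ortholog_id = cl$ortholog_id, cl$members))))
  if (!is.null(out_dir)) {
    cons <- Biostrings::DNAStringSet(setNames(
      vapply(clusters, `[[`, "", "consensus"),
      vapply(clusters, `[[`, "", "ortholog_id")))
    Biostrings::writeXStringSet(cons, file.path(out_dir, "consensus.fasta"),
                                width = 70L)
  }
  .log_stage("cluster", t0, sprintf(
    "threshold=%.2f prefilter=%s | %d CDSs -> %d orthologs",
    config$identity_threshold, config$prefilter, nrow(pool),
    length(clusters)))

  ## stage: matrices
  t0 <- as.numeric(Sys.time())
  pm <- build_pan_matrix(clusters, strains)
  summ <- pan_genome_summary(pm, groups)
  res$pan_matrix <- pm
  res$summary <- summ
  emit("pan_matrix.tsv", data.frame(strain = rownames(pm$copy_number),
                                    pm$copy_number, check.names = FALSE))
  emit("summary.tsv", data.frame(
    metric = c("total", "core", "strain_specific",
               paste0("exclusive_", names(summ$group_exclusive))),
    value = c(summ$total, summ$core, summ$strain_specific,
              unname(summ$group_exclusive))))
  emit("sharing_histogram.tsv", data.frame(
    n_strains = as.integer(names(summ$histogram)),
    n_orthologs = unname(summ$histogram)))
  .log_stage("matrices", t0, sprintf(
    "total=%d core=%d strain_specific=%d", summ$total, summ$core,
    summ$strain_specific))

  ## stage: annotation
  if (!is.null(panel)) {
    t0 <- as.numeric(Sys.time())
    hits <- screen_panel(clusters, panel,
                         identity_threshold = config$panel_identity_threshold,
                         evalue_threshold = config$evalue_threshold)
    res$hits <- hits
    res$panel_presence <- presence_matrix_by_category(hits, pm, panel)
    res$copy_number_comparison <-
      tryCatch(compare_copy_numbers(pm, hits, groups, config$alpha),
               error = function(e) NULL)
    emit("panel_hits.tsv", as.data.frame(hits))
    emit("panel_presence.tsv",
         data.frame(strain = rownames(res$panel_presence),
                    res$panel_presence, check.names = FALSE))
    if (!is.null(res$copy_number_comparison))
      emit("copy_number_comparison.tsv", res$copy_number_comparison)
    .log_stage("annotation", t0, sprintf(
      "panel=%d genes | %d hits, %d accepted", nrow(panel), nrow(hits),
      sum(hits$accepted)))
  }

  ## stage: enrichment
  if (!is.null(subsystems)) {
    t0 <- as.numeric(Sys.time())
    enr <- subsystem_enrichment(subsystems, groups, alpha = config$alpha)
    res$enrichment <- enr
    emit("enrichment.tsv", enr)
    .log_stage("enrichment", t0, sprintf(
      "categories=%d significant=%d", nrow(enr), sum(enr$significant)))
  }

  ## stage: trees
  t0 <- as.numeric(Sys.time())
  bs <- bootstrap_presence_support(pm,
                                   replicates = config$bootstrap_replicates,
                                   seed = child_seed(config$seed, 8L),
                                   linkage = config$linkage)
  res$presence_tree <- bs$tree
  res$presence_support <- bs$support
  if (!is.null(out_dir))
    write_newick(bs$tree, file.path(out_dir, "presence_tree.nwk"))
  if (!is.null(mlst)) {
    conc <- concat_mlst(mlst)
    res$mlst_tree <- bootstrap_consensus(
      conc, replicates = config$bootstrap_replicates,
      seed = child_seed(config$seed, 9L))
    if (!is.null(out_dir))
      write_newick(res$mlst_tree, file.path(out_dir, "mlst_tree.nwk"))
  }
  .log_stage("trees", t0, sprintf("replicates=%d mlst=%s",
                                  config$bootstrap_replicates,
                                  !is.null(mlst)))

  ## stage: group stats
  t0 <- as.numeric(Sys.time())
  res$feature_summary <- summarize_features(strain_features(strains))
  emit("feature_groups.tsv", res$feature_summary$groups)
  emit("feature_tests.tsv", res$feature_summary$tests)
  .log_stage("group_stats", t0, sprintf(
    "features=3 groups=%d", length(unique(groups))))

  ## stage: quantification
  if (!is.null(measurements) || !is.null(standards)) {
    t0 <- as.numeric(Sys.time())
    qm <- quant_model(config$genome_size_for_quant, config$bp_molar_mass)
    if (!is.null(standards)) {
      qm <- fit_standard_curve(standards, qm)
      res$quant_model <- qm
    }
    if (!is.null(measurements)) {
      res$measurement_summary <- summarize_measurements(measurements)
      emit("measurement_summary.tsv", res$measurement_summary)
      tps <- unique(measurements$timepoint_h)
      if (all(c(24, 48) %in% tps)) {
        res$fold_change <- competition_fold_change(measurements)
        emit("fold_changes.tsv", res$fold_change$fold_changes)
      }
    }
    .log_stage("quantification", t0, sprintf(
      "standards=%s measurements=%s", !is.null(standards),
      !is.null(measurements)))
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:",
      paste(setdiff(names(x), c("config", "groups")), collapse = ", "),
      "\n")
  invisible(x)
}
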