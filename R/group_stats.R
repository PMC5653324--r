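## Group statistics: genome-feature summaries with Welch t-tests,
## two-sided Fisher's exact tests, and subsystem (functional category)
## enrichment between two strain groups.

#' Genome-feature table from strain CDS sets
#'
#' @param strains List of [strain_cds_set()] objects.
#' @return data.frame with columns `strain`, `group`, `genome_size`,
#'   `n_cds`, `gc_percent`.
#' @export
strain_features <- function(strains) {
  do.call(rbind, lapply(strains, function(s)
    data.frame(strain = s$strain_id, group = s$group,
               genome_size = s$genome_size, n_cds = length(s$cds),
               gc_percent = s$gc_percent, stringsAsFactors = FALSE)))
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch statistic with Welch-Satterthwaite degrees of freedom.
#' Conventions: samples with zero variance in both groups and equal means
#' give t = 0, p = 1; zero variance in both groups with different means
#' gives p = 0 (infinite t). Swapping the samples negates t and preserves
#' p. A pooled-variance (classical Student) variant is available via
#' `pooled = TRUE`.
#'
#' @param x,y Numeric samples with at least two values each.
#' @param pooled Use the pooled-variance statistic instead of Welch.
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop_stage("welch_t_test",
               "insufficient replication: both samples need >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  tt <- t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Group means, sample SDs and Welch tests of genomic features
#'
#' For each feature (genome size in Mbp, CDS count, GC%), reports the
#' per-group mean and sample standard deviation (n - 1 denominator) and a
#' two-sided Welch t-test between the two groups.
#'
#' @param features data.frame with columns `strain`, `group`,
#'   `genome_size`, `n_cds`, `gc_percent` (see [strain_features()]), or a
#'   list of [strain_cds_set()] objects.
#' @param pooled Passed to [welch_t_test()].
#' @return An object of class `feature_summary`: list with `groups`
#'   (data.frame of per-group mean/sd per feature) and `tests` (data.frame
#'   of `feature`, `t`, `df`, `p_value`).
#' @export
summarize_features <- function(features, pooled = FALSE) {
  if (is.list(features) && !is.data.frame(features))
    features <- strain_features(features)
  need <- c("group", "genome_size", "n_cds", "gc_percent")
  if (!all(need %in% names(features)))
    stop_stage("summarize_features", "features need columns: ",
               paste(need, collapse = ", "))
  gl <- unique(features$group)
  if (length(gl) != 2L)
    stop_stage("summarize_features", "exactly two groups required, got ",
               length(gl))
  if (any(table(features$group) < 2L))
    stop_stage("summarize_features",
               "feature summary needs >= 2 strains per group")
  feats <- c("genome_size", "n_cds", "gc_percent")
  groups <- do.call(rbind, lapply(gl, function(g) {
    sub <- features[features$group == g, ]
    row <- data.frame(group = g, n = nrow(sub))
    for (f in feats) {
      row[[paste0(f, "_mean")]] <- mean(sub[[f]])
      row[[paste0(f, "_sd")]] <- sd(sub[[f]])
    }
    row
  }))
  tests <- do.call(rbind, lapply(feats, function(f) {
    tt <- welch_t_test(features[[f]][features$group == gl[1]],
                       features[[f]][features$group == gl[2]],
                       pooled = pooled)
    data.frame(feature = f, t = tt$t, df = tt$df, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, tests = tests),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, digits = 2, ...) {
  cat("Genomic feature summary (mean ± SD):\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s (n=%d): %.2f ± %.2f Mbp, %.2f ± %.2f CDSs, %.2f ± %.2f GC%%\n",
                g$group, g$n, g$genome_size_mean, g$genome_size_sd,
                g$n_cds_mean, g$n_cds_sd, g$gc_percent_mean,
                g$gc_percent_sd))
  }
  cat("Welch two-sided p-values:",
      paste(sprintf("%s %.4g", x$tests$feature, x$tests$p_value),
            collapse = ", "), "\n")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p by the minimum-likelihood method: the sum of
#' hypergeometric probabilities, with margins fixed, of all tables whose
#' probability does not exceed that of the observed table. No continuity
#' correction. A zero row or column margin gives p = 1 by convention. The
#' odds ratio reported is the sample cross-product ratio `ad/bc` (infinite
#' or undefined with zero off-diagonal cells).
#'
#' @param table 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts with a positive grand total.
#' @return List with `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2L, 2L)
  if (any(m < 0) || any(m != floor(m)))
    stop_stage("fisher_exact_2x2", "counts must be non-negative integers")
  if (sum(m) == 0)
    stop_stage("fisher_exact_2x2", "grand total must be positive")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1))
  ft <- fisher.test(m, conf.int = FALSE)
  list(odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       p_value = ft$p.value)
}

#' Subsystem enrichment between two groups by Fisher's exact test
#'
#' For each functional category, gene counts are summed over the strains of
#' each group and laid out against the complement ("all other categorised
#' genes" of the same group) in a 2x2 table:
#' \preformatted{          in category   other genes
#'   group 1       a             b
#'   group 2       c             d }
#' Each table gets a two-sided [fisher_exact_2x2()]; rows are sorted by
#' p-value and flagged significant at `alpha` (raw p, no multiple-testing
#' correction by default, matching the P < 0.05 screening convention; set
#' `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param subsystems data.frame with columns `cds_id`, `strain_id`,
#'   `subsystem` (see [generate_subsystem_table()]).
#' @param groups Named character vector mapping strain id to group.
#' @param alpha Significance level (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return data.frame with columns `subsystem`, `n_1`, `other_1`, `n_2`,
#'   `other_2` (the 2x2 cells, suffixed by group names), `odds_ratio`,
#'   `p_value`, `significant`.
#' @export
subsystem_enrichment <- function(subsystems, groups, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("cds_id", "strain_id", "subsystem")
  if (!all(need %in% names(subsystems)))
    stop_stage("subsystem_enrichment", "subsystems need columns: ",
               paste(need, collapse = ", "))
  if (nrow(subsystems) == 0L) return(data.frame())
  grp <- groups[subsystems$strain_id]
  if (any(is.na(grp)))
    stop_stage("subsystem_enrichment", "strain without group label: ",
               subsystems$strain_id[which(is.na(grp))[1L]])
  gl <- unique(grp)
  if (length(gl) != 2L)
    stop_stage("subsystem_enrichment", "exactly two groups required")
  tot <- table(factor(grp, levels = gl))
  cats <- sort(unique(subsystems$subsystem))
  rows <- lapply(cats, function(cc) {
    a <- sum(subsystems$subsystem == cc & grp == gl[1])
    c_ <- sum(subsystems$subsystem == cc & grp == gl[2])
    tab <- matrix(c(a, c_, tot[[1]] - a, tot[[2]] - c_), 2L, 2L)
    ft <- fisher_exact_2x2(tab)
    data.frame(subsystem = cc, n_1 = a, other_1 = tot[[1]] - a,
               n_2 = c_, other_2 = tot[[2]] - c_,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0(c("n_", "other_"), gl[1]),
                       paste0(c("n_", "other_"), gl[2]))
  p_used <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_used < alpha
  out <- out[order(out$p_value, out$subsystem), ]
  rownames(out) <- NULL
  out
}
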