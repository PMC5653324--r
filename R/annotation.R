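## Screening pan-genome ortholog consensi against labelled reference gene
## panels (antibiotic-resistance, EPS, extracellular-protein families)
## under the joint identity / E-value acceptance rule, and the derived
## per-strain presence and copy-number comparisons.

#' Karlin-Altschul E-value for an ungapped nucleotide scoring scheme
#'
#' `E = K * m * n * exp(-lambda * S)` with the fixed ungapped nucleotide
#' constants `lambda = 1.33`, `K = 0.621` (match +1 / mismatch -1). The
#' E-value is monotone decreasing in the score; negative scores are capped
#' at `K * m * n`.
#'
#' @param score Alignment raw score (vectorised).
#' @param query_len,db_len Query and database lengths in bp (> 0).
#' @param lambda,K Karlin-Altschul constants.
#' @return E-value(s).
#' @export
karlin_altschul_evalue <- function(score, query_len, db_len,
                                   lambda = 1.33, K = 0.621) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("query_len and db_len must be positive", call. = FALSE)
  K * query_len * db_len * exp(-lambda * pmax(score, 0))
}

#' Screen ortholog consensus sequences against a reference gene panel
#'
#' Each (ortholog consensus, panel gene) pair is aligned locally (panel
#' gene as query) under the package scoring scheme; identity and E-value
#' come from that same alignment. A pair is `accepted` iff
#' `evalue <= evalue_threshold` and `identity >= identity_threshold` —
#' the operational form of the "E-value = 0 and identity >= 90%" rule.
#' Rows are reported down to an identity floor of 0.5 to keep near-misses
#' auditable; the best hit per ortholog (highest identity, then score) is
#' marked.
#'
#' A shared-k-mer screen (same calibration as [cluster_orthologs()]) skips
#' unrelated pairs, which cannot reach the reporting floor over a
#' biologically meaningful alignment.
#'
#' @param clusters An `ortholog_clusters` object, or a named character
#'   vector of consensus sequences.
#' @param panel A [reference_gene_panel()].
#' @param identity_threshold Acceptance identity (default 0.90).
#' @param evalue_threshold Acceptance E-value (default 1e-180, the
#'   operational "E-value = 0").
#' @param report_floor Minimum identity for a row to be reported.
#' @param prefilter Use the shared-k-mer screen (default TRUE).
#' @return data.frame of class `panel_hit_table`: `ortholog_id`, `gene_id`,
#'   `category`, `family`, `identity`, `score`, `evalue`, `accepted`,
#'   `best`.
#' @export
screen_panel <- function(clusters, panel, identity_threshold = 0.90,
                         evalue_threshold = 1e-180, report_floor = 0.5,
                         prefilter = TRUE) {
  cons <- if (inherits(clusters, "ortholog_clusters"))
    setNames(vapply(clusters, `[[`, "", "consensus"),
             vapply(clusters, `[[`, "", "ortholog_id"))
  else clusters
  if (length(cons) == 0L || nrow(panel) == 0L)
    stop_stage("screen_panel", "empty consensus set or panel")
  check_dna(cons, "consensus")

  pairs <- if (prefilter) {
    all_seqs <- c(cons, setNames(panel$sequence, panel$gene_id))
    cand <- .kmer_candidates(all_seqs, 10L, 5L)
    nc <- length(cons)
    sel <- (cand$id <= nc) != (cand$i.id <= nc)  # ortholog x panel only
    data.frame(og = pmin(cand$id[sel], cand$i.id[sel]),
               pg = pmax(cand$id[sel], cand$i.id[sel]) - nc)
  } else expand.grid(og = seq_along(cons), pg = seq_len(nrow(panel)))

  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    og <- pairs$og[r]; pg <- pairs$pg[r]
    hit <- local_alignment(panel$sequence[pg], cons[og])
    if (hit$identity < report_floor) return(NULL)
    data.frame(ortholog_id = names(cons)[og],
               gene_id = panel$gene_id[pg],
               category = panel$category[pg],
               family = panel$family[pg],
               identity = hit$identity,
               score = hit$score,
               evalue = karlin_altschul_evalue(
                 hit$score, nchar(panel$sequence[pg]), nchar(cons[og])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ortholog_id = character(0), gene_id = character(0),
                      category = character(0), family = character(0),
                      identity = numeric(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  out$accepted <- out$evalue <= evalue_threshold &
    out$identity >= identity_threshold
  out$best <- FALSE
  if (nrow(out)) {
    ord <- order(out$ortholog_id, -out$identity, -out$score)
    out <- out[ord, , drop = FALSE]
    out$best[!duplicated(out$ortholog_id)] <- TRUE
    rownames(out) <- NULL
  }
  class(out) <- c("panel_hit_table", "data.frame")
  out
}

#' Per-strain presence matrix of panel genes
#'
#' A strain carries a panel gene iff it is present (pan-matrix presence) in
#' at least one ortholog accepted for that gene.
#'
#' @param hits A [screen_panel()] result.
#' @param matrix A [build_pan_matrix()] result built on the same clusters.
#' @param panel Optional [reference_gene_panel()]; when given, the output
#'   has one column per panel gene (all-zero when unaccepted), optionally
#'   restricted by `category`.
#' @param category Optional category filter (requires `panel`).
#' @return strains x panel-genes binary integer matrix.
#' @export
presence_matrix_by_category <- function(hits, matrix, panel = NULL,
                                        category = NULL) {
  stopifnot(inherits(matrix, "pan_matrix"))
  genes <- if (!is.null(panel)) {
    g <- panel$gene_id
    if (!is.null(category)) g <- g[panel$category %in% category]
    g
  } else sort(unique(hits$gene_id[hits$accepted]))
  out <- matrix(0L, nrow(matrix$presence), length(genes),
                dimnames = list(rownames(matrix$presence), genes))
  acc <- hits[hits$accepted & hits$gene_id %in% genes, , drop = FALSE]
  for (r in seq_len(nrow(acc))) {
    og <- acc$ortholog_id[r]
    if (!og %in% colnames(matrix$presence))
      stop_stage("presence_matrix_by_category",
                 "hit ortholog not in pan matrix: ", og)
    out[, acc$gene_id[r]] <-
      pmax(out[, acc$gene_id[r]], matrix$presence[, og])
  }
  out
}

#' Group copy-number comparison of accepted panel genes
#'
#' Per accepted panel gene, the per-strain copy number is summed over its
#' accepted orthologs; group means and a two-sided Welch t-test p-value are
#' reported. Genes absent from every strain are excluded. Identical copy
#' numbers in both groups give p = 1 by convention.
#'
#' @param matrix A [build_pan_matrix()] result.
#' @param hits A [screen_panel()] result.
#' @param groups Named character vector mapping strain id to group; both
#'   groups need at least two strains.
#' @param alpha Significance level for the flag (default 0.05).
#' @return data.frame with per-gene group means, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_copy_numbers <- function(matrix, hits, groups, alpha = 0.05) {
  stopifnot(inherits(matrix, "pan_matrix"))
  strains <- rownames(matrix$copy_number)
  gl <- unique(groups[strains])
  if (length(gl) != 2L)
    stop_stage("compare_copy_numbers", "exactly two groups required")
  if (any(table(groups[strains]) < 2L))
    stop_stage("compare_copy_numbers", "both groups need >= 2 strains")
  acc <- hits[hits$accepted, , drop = FALSE]
  rows <- lapply(sort(unique(acc$gene_id)), function(g) {
    ogs <- intersect(acc$ortholog_id[acc$gene_id == g],
                     colnames(matrix$copy_number))
    cn <- rowSums(matrix$copy_number[, ogs, drop = FALSE])
    if (all(cn == 0L)) return(NULL)  # absent everywhere
    x <- cn[groups[strains] == gl[1]]
    y <- cn[groups[strains] == gl[2]]
    tt <- welch_t_test(x, y)
    df <- data.frame(gene_id = g,
                     category = acc$category[acc$gene_id == g][1L],
                     mean_1 = mean(x), mean_2 = mean(y),
                     t = tt$t, df = tt$df, p_value = tt$p_value,
                     significant = tt$p_value < alpha,
                     stringsAsFactors = FALSE)
    names(df)[names(df) == "mean_1"] <- paste0("mean_", gl[1])
    names(df)[names(df) == "mean_2"] <- paste0("mean_", gl[2])
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
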