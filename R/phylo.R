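## Phylogenetics layer: presence/absence hierarchical clustering with
## ordinary bootstrap support, TN93 nucleotide distances, an in-package
## neighbor-joining implementation, majority-rule bootstrap consensus
## trees, and MLST concatenation.

#' Euclidean distance between presence/absence rows of a pan matrix
#'
#' Presence (not copy number) rows are used, matching clustering on the
#' presence or absence of each orthologous CDS.
#'
#' @param matrix A [build_pan_matrix()] result, or a binary matrix with
#'   strain rownames.
#' @return A `dist` object.
#' @export
presence_distance <- function(matrix) {
  p <- if (inherits(matrix, "pan_matrix")) matrix$presence else matrix
  if (nrow(p) < 2L)
    stop_stage("presence_distance", ">= 2 strains required")
  dist(p, method = "euclidean")
}

#' Agglomerative hierarchical clustering of strains
#'
#' Average linkage by default (complete/single/ward.D2 available). Labels
#' are sorted before clustering, so the result is invariant to input
#' order; merge heights are non-decreasing for the default linkages.
#'
#' @param d A `dist` object with labels.
#' @param linkage hclust method (default "average").
#' @return A rooted `phylo` dendrogram; the underlying `hclust` object is
#'   attached as attribute `"hclust"`.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  m <- as.matrix(d)
  if (nrow(m) == 1L) {
    tr <- structure(list(edge = matrix(nrow = 0, ncol = 2),
                         tip.label = rownames(m), Nnode = 0L),
                    class = "phylo")
    return(tr)
  }
  ord <- order(rownames(m))
  hc <- hclust(as.dist(m[ord, ord]), method = linkage)
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Bootstrap support for a presence/absence dendrogram
#'
#' Resamples ortholog columns with replacement, re-clusters each
#' replicate, and reports for every internal node of the original
#' dendrogram the percentage of replicates in which that node's leaf set
#' reappears as a cluster. Ordinary (single-scale) bootstrap proportions,
#' labelled BP; deterministic given `seed`.
#'
#' @param matrix A [build_pan_matrix()] result.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param linkage Passed to [hierarchical_cluster()].
#' @return List with `tree` (the original dendrogram, node labels set to
#'   integer support percentages) and `support` (numeric vector over
#'   internal nodes).
#' @export
bootstrap_presence_support <- function(matrix, replicates = 1000L,
                                       seed = 1L, linkage = "average") {
  stopifnot(inherits(matrix, "pan_matrix"), replicates >= 1L)
  p <- matrix$presence
  base <- hierarchical_cluster(presence_distance(matrix), linkage)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample(ncol(p), ncol(p), replace = TRUE)
    reps[[r]] <- hierarchical_cluster(
      dist(p[, cols, drop = FALSE], method = "euclidean"), linkage)
  }
  counts <- ape::prop.clades(base, reps, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / replicates
  base$node.label <- as.character(round(support))
  list(tree = base, support = support)
}

#' Matrix of pairwise TN93 distances over an alignment
#'
#' Tamura-Nei (TN93) distances with empirical base frequencies and
#' pairwise deletion of gap/ambiguous sites. Saturated pairs (logarithm
#' argument non-positive) are set to `ceiling` and recorded in the
#' `"saturated"` attribute.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param ceiling Distance assigned to saturated pairs (default 3).
#' @return A `dist` object; attribute `"saturated"` is a logical matrix.
#' @export
tn93_distance_matrix <- function(alignment, ceiling = 3) {
  m <- seq_matrix(alignment)
  bin <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  sat <- !is.finite(dm)
  dm[sat] <- ceiling
  out <- as.dist(dm)
  attr(out, "saturated") <- sat
  out
}

#' TN93 nucleotide distance between two aligned sequences
#'
#' The pairwise closed form of the Tamura-Nei model with base frequencies
#' estimated from the pair; columns containing a gap or N in either
#' sequence are removed first. Identical sequences give 0; saturation
#' (non-positive logarithm argument) is flagged and the distance set to
#' `ceiling`.
#'
#' @param a,b Aligned sequences of equal length.
#' @param ceiling Distance used for saturated pairs.
#' @return List with `distance` and `saturated`.
#' @export
nucleotide_distance <- function(a, b, ceiling = 3) {
  if (nchar(a) != nchar(b))
    stop_stage("nucleotide_distance", "sequences must be aligned (equal length)")
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  keep <- va %in% .DNA_BASES & vb %in% .DNA_BASES
  if (!any(keep))
    return(list(distance = NA_real_, saturated = TRUE))
  al <- setNames(c(paste(va[keep], collapse = ""),
                   paste(vb[keep], collapse = "")), c("a", "b"))
  d <- tn93_distance_matrix(al, ceiling = ceiling)
  list(distance = as.numeric(d)[1],
       saturated = any(attr(d, "saturated")))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with the Q-criterion. Taxa are
#' sorted by label first, so the unrooted topology is invariant to input
#' order; Q ties resolve to the first pair in that fixed order. Negative
#' branch lengths are clamped to zero with the length moved to the sister
#' edge (their sum is preserved). On additive distance matrices the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param d A `dist` object or symmetric matrix with at least 3 labelled
#'   taxa (2 taxa give a trivial cherry).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  D <- as.matrix(d)
  if (is.null(rownames(D)))
    stop_stage("neighbor_joining", "taxa must be labelled")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  n <- nrow(D)
  if (n < 2L) stop_stage("neighbor_joining", ">= 2 taxa required")
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", rownames(D)[1], fmt(D[1, 2] / 2),
                   rownames(D)[2], fmt(D[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  frag <- rownames(D)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ix <- which(Q == min(Q), arr.ind = TRUE)
    ix <- ix[ix[, 1] < ix[, 2], , drop = FALSE]
    f <- ix[1, 1]; g <- ix[1, 2]
    lf <- D[f, g] / 2 + (r[f] - r[g]) / (2 * (m - 2))
    lg <- D[f, g] - lf
    if (lf < 0) { lg <- D[f, g]; lf <- 0 }
    if (lg < 0) { lf <- D[f, g]; lg <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[f], fmt(lf), frag[g], fmt(lg))
    du <- (D[f, ] + D[g, ] - D[f, g]) / 2
    keep <- setdiff(seq_len(m), c(f, g))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    lab <- c(rownames(D)[keep], sprintf("@u%d@", m))
    dimnames(D2) <- list(lab, lab)
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  cc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(a), frag[2], fmt(b), frag[3], fmt(cc))
  ape::read.tree(text = txt)
}

#' Majority-rule bootstrap consensus tree from an alignment
#'
#' Resamples alignment columns with replacement; each replicate yields a
#' TN93 distance matrix and a [neighbor_joining()] tree; the strict
#' majority-rule (> 50%) consensus topology is returned with per-split
#' support as the percentage of replicates containing the split.
#' Deterministic given `seed`. An all-identical alignment carries no
#' signal: a star tree is returned with attribute
#' `"undefined_support" = TRUE`.
#'
#' @param alignment Named character vector of equal-length sequences,
#'   >= 3 taxa.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return An unrooted consensus `phylo`; `node.label` holds integer
#'   support percentages (empty for the root-adjacent basal node).
#' @export
bootstrap_consensus <- function(alignment, replicates = 1000L, seed = 1L) {
  if (length(alignment) < 3L)
    stop_stage("bootstrap_consensus", ">= 3 taxa required")
  m <- seq_matrix(alignment)
  taxa <- sort(rownames(m))
  if (all(apply(m, 2L, function(col) length(unique(col)) == 1L))) {
    star <- ape::read.tree(text = paste0(
      "(", paste(taxa, collapse = ","), ");"))
    attr(star, "undefined_support") <- TRUE
    return(star)
  }
  set.seed(seed)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample(ncol(m), ncol(m), replace = TRUE)
    al <- matrix_seq(m[, cols, drop = FALSE])
    reps[[r]] <- neighbor_joining(tn93_distance_matrix(al))
  }
  class(reps) <- "multiPhylo"
  cons <- ape::consensus(reps, p = 0.5, rooted = FALSE)
  counts <- ape::prop.clades(cons, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  cons$node.label <- as.character(round(100 * counts / replicates))
  attr(cons, "undefined_support") <- FALSE
  cons
}

#' Concatenate MLST locus alignments in the canonical order
#'
#' Loci named after the seven housekeeping genes (pstB, rpsB, pheS, ftsQ,
#' nrdB, rpoA, parB) are concatenated in that fixed order; other names
#' keep their input order. All loci must cover the same taxon set.
#'
#' @param gene_alignments Named list of alignments (named character
#'   vectors of equal-length sequences).
#' @return Named character vector of concatenated sequences; attribute
#'   `"partitions"` records per-locus start/end columns.
#' @export
concat_mlst <- function(gene_alignments) {
  if (length(gene_alignments) == 0L)
    stop_stage("concat_mlst", "no alignments given")
  nm <- names(gene_alignments)
  if (!is.null(nm) && all(nm %in% MLST_LOCI))
    gene_alignments <- gene_alignments[intersect(MLST_LOCI, nm)]
  taxa <- sort(names(gene_alignments[[1]]))
  for (i in seq_along(gene_alignments)) {
    ti <- sort(names(gene_alignments[[i]]))
    if (!identical(ti, taxa)) {
      miss <- c(setdiff(taxa, ti), setdiff(ti, taxa))
      stop_stage("concat_mlst", "taxon set mismatch at locus ",
                 names(gene_alignments)[i] %||% i, ": ",
                 paste(miss, collapse = ", "))
    }
  }
  lens <- vapply(gene_alignments, function(a) nchar(a[[1]]), numeric(1))
  ends <- cumsum(lens)
  out <- vapply(taxa, function(s)
    paste(vapply(gene_alignments, function(a) a[[s]], character(1)),
          collapse = ""), character(1))
  attr(out, "partitions") <- data.frame(
    locus = names(gene_alignments) %||% seq_along(gene_alignments),
    start = c(1, head(ends, -1) + 1), end = ends, row.names = NULL)
  out
}

#' Translate a CDS to amino acids (standard bacterial code)
#'
#' @param seq Nucleotide CDS, length a multiple of 3.
#' @return Amino-acid string (stops as `*`).
#' @export
translate_cds <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

#' p-distance matrix over an amino-acid (or nucleotide) alignment
#'
#' Fraction of differing sites among ungapped columns per pair; the simple
#' distance used for sequence-level clustering of gene-family protein
#' sets, fed to [hierarchical_cluster()] like any other distance.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return A `dist` object.
#' @export
p_distance_matrix <- function(alignment) {
  m <- seq_matrix(alignment)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- m[i, ] != "-" & m[j, ] != "-"
    out[i, j] <- out[j, i] <-
      if (any(keep)) mean(m[i, keep] != m[j, keep]) else NA_real_
  }
  as.dist(out)
}
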