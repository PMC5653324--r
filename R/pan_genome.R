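## Pan-genome construction: pseudogene filtering, identity-threshold
## single-linkage ortholog clustering, majority-vote consensus sequences,
## presence/copy-number matrices, summaries, and fragment-based ANI.

#' Does a CDS carry an in-frame premature stop codon?
#' @noRd
.has_premature_stop <- function(seq) {
  nc <- nchar(seq) %/% 3L
  if (nc < 2L) return(FALSE)
  starts <- seq(1L, by = 3L, length.out = nc - 1L)  # all but final codon
  codons <- substring(seq, starts, starts + 2L)
  any(codons %in% .STOP_CODONS)
}

#' Remove pseudogenes (premature in-frame stop codons) from a CDS set
#'
#' A CDS is removed iff any codon before the final codon is TAA/TAG/TGA in
#' frame 0. Sequences whose length is not a multiple of 3 cannot be read in
#' frame and are removed with reason "frame". The kept set preserves input
#' order.
#'
#' @param cds_set A [strain_cds_set()].
#' @return List with `kept` (a [strain_cds_set()], possibly empty) and
#'   `removed` (data.frame `cds_id`, `reason`).
#' @export
filter_pseudogenes <- function(cds_set) {
  stopifnot(inherits(cds_set, "strain_cds_set"))
  seqs <- cds_set$cds
  if (length(seqs) == 0L)
    return(list(kept = cds_set,
                removed = data.frame(cds_id = character(0),
                                     reason = character(0))))
  frame_bad <- nchar(seqs) %% 3L != 0L
  stop_bad <- !frame_bad &
    vapply(seqs, .has_premature_stop, logical(1), USE.NAMES = FALSE)
  drop <- frame_bad | stop_bad
  removed <- data.frame(
    cds_id = names(seqs)[drop],
    reason = ifelse(frame_bad[drop], "frame", "premature_stop"),
    stringsAsFactors = FALSE)
  kept <- strain_cds_set(cds_set$strain_id, cds_set$group, seqs[!drop],
                         genome_size = cds_set$genome_size,
                         gc = if (any(drop)) NULL else cds_set$gc_percent)
  list(kept = kept, removed = removed)
}

#' Pool CDSs of several strains into one table
#'
#' @param strains List of [strain_cds_set()] objects.
#' @param drop_pseudogenes Apply [filter_pseudogenes()] to each strain
#'   first (default TRUE, matching the pipeline order).
#' @return data.frame with columns `strain_id`, `cds_id`, `sequence`.
#' @export
pool_cds <- function(strains, drop_pseudogenes = TRUE) {
  rows <- lapply(strains, function(s) {
    if (drop_pseudogenes) s <- filter_pseudogenes(s)$kept
    if (length(s$cds) == 0L) return(NULL)
    data.frame(strain_id = s$strain_id, cds_id = names(s$cds),
               sequence = unname(s$cds), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop_stage("pool_cds", "no CDSs left after pseudogene filtering")
  rownames(out) <- NULL
  out
}

#' Candidate pairs sharing at least `min_shared` k-mers
#' @noRd
.kmer_candidates <- function(seqs, k, min_shared) {
  kl <- lapply(seqs, .kmer_codes, k = k)
  dt <- data.table::data.table(kmer = unlist(kl),
                               id = rep(seq_along(seqs), lengths(kl)))
  j <- dt[dt, on = "kmer", allow.cartesian = TRUE]
  j <- j[j$id < j$i.id, ]
  cnt <- j[, list(N = .N), by = c("id", "i.id")]
  cnt <- cnt[cnt$N >= min_shared, ]
  cnt[order(-cnt$N), ]
}

#' Cluster a CDS pool into orthologs by single-linkage identity
#'
#' Two CDSs are linked when their global [pairwise_identity()] is at least
#' `threshold`; ortholog clusters are the connected components of the
#' resulting graph (single linkage via union-find), so members are chained:
#' every member pair is connected through pairwise identities at or above
#' the threshold, though not necessarily directly.
#'
#' With `prefilter = TRUE` (default) two screens avoid most alignments: a
#' provable length bound (identity cannot exceed `min(m,n)/max(m,n)`) and a
#' shared k-mer count (pairs sharing fewer than `min_shared_kmers` k-mers of
#' size `kmer_size` are skipped). The k-mer screen is calibrated so that for
#' i.i.d. substitution processes at up to `1 - threshold` divergence the
#' probability of skipping a true pair is negligible; pathological
#' (periodic) substitution patterns could evade it, so `prefilter = FALSE`
#' provides the exact brute-force route, and pairs already connected through
#' earlier links are skipped in either mode (provably without effect on the
#' components).
#'
#' @param pool data.frame from [pool_cds()] (`strain_id`, `cds_id`,
#'   `sequence`); `cds_id` must be globally unique.
#' @param threshold Identity threshold in (0, 1], default 0.85.
#' @param prefilter Use the k-mer/length screens (default TRUE).
#' @param kmer_size,min_shared_kmers Prefilter parameters.
#' @return An object of class `ortholog_clusters`: a list of clusters, each
#'   with `ortholog_id`, `members` (data.frame `strain_id`, `cds_id`) and
#'   `consensus`. Ordered by descending member count, ties by the
#'   lexicographically smallest member `cds_id`.
#' @export
cluster_orthologs <- function(pool, threshold = 0.85, prefilter = TRUE,
                              kmer_size = 10L, min_shared_kmers = 20L) {
  if (!is.data.frame(pool) || nrow(pool) == 0L)
    stop_stage("cluster_orthologs", "pool must be a non-empty data.frame")
  if (threshold <= 0 || threshold > 1)
    stop_stage("cluster_orthologs", "threshold must lie in (0, 1]")
  if (anyDuplicated(pool$cds_id))
    stop_stage("cluster_orthologs", "cds_ids must be globally unique")
  seqs <- pool$sequence
  check_dna(seqs, "pool sequence")
  n <- length(seqs)
  lens <- nchar(seqs)

  if (n > 1L) {
    if (prefilter) {
      cand <- .kmer_candidates(seqs, kmer_size, min_shared_kmers)
      ii <- cand$id
      jj <- cand$i.id
      keep <- pmin(lens[ii], lens[jj]) / pmax(lens[ii], lens[jj]) >= threshold
      ii <- ii[keep]; jj <- jj[keep]
    } else {
      cp <- combn(n, 2L)
      ii <- cp[1L, ]; jj <- cp[2L, ]
    }
    parent <- seq_len(n)
    uf_find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]  # path halving
        i <- parent[i]
      }
      i
    }
    ## Resolve candidate edges around pivot vertices so each pivot costs a
    ## single vectorised alignment call. Edges whose endpoints are already
    ## in one component are dropped (provably without effect on the
    ## connected components); every other candidate edge is evaluated.
    while (length(ii)) {
      ca <- vapply(ii, uf_find, integer(1))
      cb <- vapply(jj, uf_find, integer(1))
      live <- ca != cb
      ii <- ii[live]; jj <- jj[live]
      if (!length(ii)) break
      deg <- tabulate(c(ii, jj), nbins = n)
      pivot <- which.max(deg)
      at <- ii == pivot | jj == pivot
      partners <- ifelse(ii[at] == pivot, jj[at], ii[at])
      ids <- .identity_one_vs_many(seqs[pivot], seqs[partners])
      for (p in partners[ids >= threshold]) {
        a <- uf_find(pivot); b <- uf_find(p)
        if (a != b) parent[b] <- a
      }
      ii <- ii[!at]; jj <- jj[!at]
    }
    comp <- vapply(seq_len(n), uf_find, integer(1))
  } else comp <- 1L

  groups <- split(seq_len(n), comp)
  sizes <- lengths(groups)
  smallest <- vapply(groups, function(ix) min(pool$cds_id[ix]), character(1))
  ord <- order(-sizes, smallest)
  clusters <- lapply(seq_along(ord), function(r) {
    ix <- groups[[ord[r]]]
    ix <- ix[order(pool$cds_id[ix])]
    list(ortholog_id = sprintf("OG%04d", r),
         members = data.frame(strain_id = pool$strain_id[ix],
                              cds_id = pool$cds_id[ix],
                              stringsAsFactors = FALSE),
         consensus = consensus_sequence(seqs[ix]))
  })
  structure(clusters, class = "ortholog_clusters", threshold = threshold)
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat(sprintf("ortholog_clusters: %d clusters, %d CDSs, threshold %.2f\n",
              length(x), sum(vapply(x, function(cl) nrow(cl$members),
                                    integer(1))),
              attr(x, "threshold")))
  invisible(x)
}

#' Majority-vote consensus of a cluster's member sequences
#'
#' Members of equal length are stacked directly; otherwise members are
#' star-aligned to the longest member (global alignment, insertions
#' relative to the reference dropped, deletions padded with gaps). Per
#' aligned column the plurality base is taken, ties broken by the fixed
#' order A < C < G < T; columns where gaps are in strict majority are
#' dropped.
#'
#' @param members Character vector of member sequences (or an element of an
#'   `ortholog_clusters` object's member sequences).
#' @return Consensus nucleotide sequence.
#' @export
consensus_sequence <- function(members) {
  members <- unname(members)
  if (length(members) == 0L)
    stop("cluster must have at least one member", call. = FALSE)
  if (length(members) == 1L) return(members)
  if (length(unique(nchar(members))) == 1L) {
    m <- do.call(rbind, strsplit(members, ""))
  } else {
    ref_i <- which.max(nchar(members))
    ref <- members[ref_i]
    rows <- lapply(members[-ref_i], function(s) {
      aln <- Biostrings::pairwiseAlignment(
        s, ref, type = "global", substitutionMatrix = .sub_matrix(),
        gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
      p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      r <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      p[r != "-"]  # project member onto reference columns
    })
    m <- do.call(rbind, c(list(strsplit(ref, "")[[1]]), rows))
  }
  cons <- apply(m, 2L, function(col) {
    if (sum(col == "-") * 2L > length(col)) return(NA_character_)
    counts <- tabulate(match(col, .DNA_BASES), nbins = 4L)
    if (sum(counts) == 0L) return("N")
    .DNA_BASES[which.max(counts)]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Pan-genome presence and copy-number matrices
#'
#' @param clusters An `ortholog_clusters` object.
#' @param strains Ordered strain labels, or a list of [strain_cds_set()]
#'   objects. Every cluster member's strain must appear here.
#' @return An object of class `pan_matrix`: list with `copy_number` and
#'   `presence` (strains x orthologs integer matrices, `presence[i,j] = 1`
#'   iff `copy_number[i,j] >= 1`).
#' @export
build_pan_matrix <- function(clusters, strains) {
  stopifnot(inherits(clusters, "ortholog_clusters"))
  if (is.list(strains) && length(strains) &&
      inherits(strains[[1]], "strain_cds_set"))
    strains <- vapply(strains, `[[`, "", "strain_id")
  ogs <- vapply(clusters, `[[`, "", "ortholog_id")
  cn <- matrix(0L, length(strains), length(ogs),
               dimnames = list(strains, ogs))
  for (cl in clusters) {
    unknown <- setdiff(cl$members$strain_id, strains)
    if (length(unknown))
      stop_stage("build_pan_matrix", "member strain not in strain list: ",
                 unknown[1L])
    t_s <- table(cl$members$strain_id)
    cn[names(t_s), cl$ortholog_id] <- as.integer(t_s)
  }
  structure(list(copy_number = cn,
                 presence = matrix(as.integer(cn >= 1L), nrow(cn), ncol(cn),
                                   dimnames = dimnames(cn))),
            class = "pan_matrix")
}

#' @export
print.pan_matrix <- function(x, ...) {
  cat(sprintf("pan_matrix: %d strains x %d orthologs (%d gene copies)\n",
              nrow(x$presence), ncol(x$presence), sum(x$copy_number)))
  invisible(x)
}

#' Pan-genome summary: core, strain-specific, group-exclusive, histogram
#'
#' Core orthologs are present in every strain; strain-specific in exactly
#' one; group-exclusive in at least one member of one group and no member
#' of any other. The sharing histogram counts orthologs over the number of
#' strains k = 1..n carrying them.
#'
#' @param matrix A [build_pan_matrix()] result.
#' @param groups Named character vector mapping strain id to group
#'   (optional; group-exclusive counts are skipped when absent).
#' @return List with `total`, `core`, `strain_specific`, `group_exclusive`
#'   (named integer vector) and `histogram` (named vector over k).
#' @export
pan_genome_summary <- function(matrix, groups = NULL) {
  stopifnot(inherits(matrix, "pan_matrix"))
  p <- matrix$presence
  n <- nrow(p)
  shared <- colSums(p)
  histogram <- setNames(tabulate(shared, nbins = n), seq_len(n))
  out <- list(total = ncol(p),
              core = sum(shared == n),
              strain_specific = sum(shared == 1L),
              histogram = histogram)
  if (!is.null(groups)) {
    gl <- unique(groups[rownames(p)])
    out$group_exclusive <- setNames(vapply(gl, function(g) {
      ing <- rownames(p)[groups[rownames(p)] == g]
      outg <- setdiff(rownames(p), ing)
      sum(colSums(p[ing, , drop = FALSE]) >= 1L &
            colSums(p[outg, , drop = FALSE]) == 0L)
    }, integer(1)), gl)
  }
  out
}

#' Fragment-based average nucleotide identity (ANIb-style)
#'
#' Concatenates the first genome's sequences, cuts consecutive fragments of
#' `fragment_size` bp (a trailing piece of at least 100 bp is kept), aligns
#' each fragment locally against the concatenated second genome, and
#' averages the identities of fragments whose best hit covers at least
#' `min_coverage` of the fragment at identity at least `min_identity` —
#' the standard fragment/filter parameters of BLAST-based ANI.
#'
#' @param genome_a,genome_b [strain_cds_set()] objects or character vectors
#'   of sequences.
#' @param fragment_size Fragment length in bp (default 1020).
#' @param min_identity,min_coverage Hit filters (defaults 0.30 and 0.70).
#' @return List with `ani_percent` (NA when no fragment qualifies, flagged
#'   by `undefined = TRUE`), `fraction_fragments_used`, `n_fragments`.
#' @export
compute_ani <- function(genome_a, genome_b, fragment_size = 1020L,
                        min_identity = 0.30, min_coverage = 0.70) {
  get_seqs <- function(x)
    if (inherits(x, "strain_cds_set")) x$cds else x
  a <- paste(get_seqs(genome_a), collapse = "")
  b <- paste(get_seqs(genome_b), collapse = "")
  if (!nzchar(a) || !nzchar(b))
    stop_stage("compute_ani", "both genomes must be non-empty")
  starts <- seq(1L, nchar(a), by = fragment_size)
  frags <- substring(a, starts, pmin(starts + fragment_size - 1L, nchar(a)))
  frags <- frags[nchar(frags) >= 100L]
  ids <- numeric(0)
  for (f in frags) {
    hit <- local_alignment(f, b)
    if (hit$query_coverage >= min_coverage && hit$identity >= min_identity)
      ids <- c(ids, hit$identity)
  }
  if (length(ids) == 0L)
    return(list(ani_percent = NA_real_, undefined = TRUE,
                fraction_fragments_used = 0, n_fragments = length(frags)))
  list(ani_percent = 100 * mean(ids), undefined = FALSE,
       fraction_fragments_used = length(ids) / length(frags),
       n_fragments = length(frags))
}
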