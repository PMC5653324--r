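# Independent oracles and fixture builders used across the test suite.
# The oracles deliberately avoid the code paths they check: the aligner
# oracle is a plain-R Gotoh DP, the Fisher oracle enumerates tables with
# choose(), ARI comes from mclust, and NJ checks run against trees whose
# additive distances are constructed from known topologies.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute exactly `k` sites of `seq` at distinct random positions
mutate_exact <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(v, collapse = "")
}

# Gotoh global affine-gap DP: match +1, mismatch -1, gap of length L costs
# 2 + L, end gaps penalised. Returns the optimal score and the identity
# (match columns / all columns) of one optimal traceback.
oracle_global_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  open <- 3; ext <- 1  # first gapped base costs 3 = opening 2 + extension 1
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)  # ends base-base
  X <- matrix(NEG, m + 1, n + 1)  # ends gap in b (a base over '-')
  Y <- matrix(NEG, m + 1, n + 1)  # ends gap in a
  M[1, 1] <- 0
  for (i in 2:(m + 1)) X[i, 1] <- -2 - (i - 1)
  for (j in 2:(n + 1)) Y[1, j] <- -2 - (j - 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open,
                     Y[i, j - 1] - ext)
    }
  }
  score <- max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
  # traceback for identity
  i <- m + 1; j <- n + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1L) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      if (s == 1) matches <- matches + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      prev <- c(M[i - 1, j] - open, X[i - 1, j] - ext, Y[i - 1, j] - open)
      state <- which.max(prev)
      i <- i - 1
    } else {
      prev <- c(M[i, j - 1] - open, X[i, j - 1] - open, Y[i, j - 1] - ext)
      state <- which.max(prev)
      j <- j - 1
    }
  }
  list(score = score, identity = matches / cols)
}

# Exhaustive two-sided Fisher oracle: hypergeometric probabilities from
# choose(), minimum-likelihood two-sided rule. Vectorised over the free
# cell given fixed margins.
oracle_fisher_p <- function(tab) {
  m <- matrix(as.numeric(tab), 2, 2)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  a <- lo:hi
  prob <- choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1)
  p_obs <- prob[a == m[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# partition recovered by clustering, aligned to the pool's CDS order
recovered_partition <- function(clusters, cds_ids) {
  out <- rep(NA_character_, length(cds_ids))
  for (cl in clusters)
    out[match(cl$members$cds_id, cds_ids)] <- cl$ortholog_id
  out
}

# recovered-cluster id holding all members of a panel gene's source ortholog
recovered_og <- function(fx, gid) {
  src <- fx$src[[gid]]
  cds <- fx$g$truth$cds_id[fx$g$truth$ortholog_id == src]
  for (cl in fx$clusters)
    if (all(cds %in% cl$members$cds_id)) return(cl$ortholog_id)
  NA_character_
}

strain_groups_of <- function(genomes) {
  tr <- genomes$truth
  setNames(tr$group[!duplicated(tr$strain_id)], unique(tr$strain_id))
}

# random additive tree: topology + positive branch lengths; returns the
# patristic distance matrix and the unrooted generating tree
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  list(tree = ape::unroot(tr), d = cophenetic(tr))
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# does `tree` (with node support labels) contain the bipartition separating
# `tips` from the rest, and at what support? Works for rooted dendrograms
# and unrooted consensus trees alike: each internal node's clade (or its
# complement) is compared against `tips`.
split_support <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  target <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  for (k in seq_along(pp)) {
    cl <- sort(pp[[k]])
    if (identical(cl, target) || identical(cl, comp))
      return(suppressWarnings(as.numeric(tree$node.label[k])))
  }
  NA_real_
}
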