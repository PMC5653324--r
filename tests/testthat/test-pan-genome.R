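test_that("pseudogene filter removes exactly the in-frame premature stops", {
  s <- strain_cds_set("S", "G", c(
    ok = "ATGAAATAA",        # stop only at the end
    bad = "ATGTAAAAATAA",    # internal TAA
    tag = "ATGGGGTAGAAATGA", # internal TAG
    frame = "ATGAAAT"))      # length not a multiple of 3
  r <- filter_pseudogenes(s)
  expect_identical(names(r$kept$cds), "ok")
  expect_identical(r$removed$cds_id, c("bad", "tag", "frame"))
  expect_identical(r$removed$reason,
                   c("premature_stop", "premature_stop", "frame"))
  empty <- strain_cds_set("S", "G", character(0))
  expect_equal(nrow(filter_pseudogenes(empty)$removed), 0L)
})

test_that("filtered pseudogene counts equal the truth table exactly", {
  spec <- pan_pool_spec(n_core = 100, within_ortholog_divergence = 0.01,
                        gene_length_range = c(90, 300),
                        pseudogene_rate = 0.1, seed = 7)
  g <- generate_strain_genomes(spec, c(A = 5, B = 5))
  for (s in g$strains) {
    removed <- filter_pseudogenes(s)$removed
    truth_pseudo <- g$truth$cds_id[g$truth$strain_id == s$strain_id &
                                     g$truth$is_pseudogene]
    expect_identical(removed$cds_id, truth_pseudo)
  }
})

test_that("pairwise identity matches the closed cases and the DP oracle", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_error(pairwise_identity("ACGU", "ACGT"), "outside")
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  # random 300-bp pairs at planted divergence 0.10: near 0.90 and exactly
  # equal to the independent Gotoh oracle (score and identity)
  set.seed(42)
  for (k in 1:6) {
    a <- rand_dna(300)
    b <- mutate_exact(a, 30)
    id <- pairwise_identity(a, b)
    expect_lt(abs(id - 0.90), 0.03)
    o <- oracle_global_align(a, b)
    expect_equal(id, o$identity)
  }
  # oracle score equality also under forced indels and length mismatch
  for (k in 1:4) {
    a <- rand_dna(80)
    b <- paste0(substr(a, 1, 30), substr(a, 37, 80))  # 6-bp deletion
    b <- mutate_exact(b, 4)
    M <- salipan:::.sub_matrix()
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = M,
      gapOpening = 2, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle_global_align(a, b)$score)
  }
  # symmetry
  set.seed(9)
  a <- rand_dna(200); b <- mutate_exact(a, 25)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
})

test_that("single-linkage chaining merges through intermediate members", {
  set.seed(13)
  a <- rand_dna(200)
  b <- mutate_exact(a, 20)            # ~0.90 to a
  c_ <- mutate_exact(b, 26)           # ~0.87 to b, ~0.78 to a
  expect_gt(pairwise_identity(a, b), 0.85)
  expect_gt(pairwise_identity(b, c_), 0.85)
  expect_lt(pairwise_identity(a, c_), 0.85)
  pool <- data.frame(strain_id = c("s1", "s2", "s3"),
                     cds_id = c("x", "y", "z"),
                     sequence = c(a, b, c_))
  cl <- cluster_orthologs(pool, prefilter = FALSE)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members$cds_id, c("x", "y", "z"))
  # mutually dissimilar sequences stay singletons
  set.seed(14)
  pool2 <- data.frame(strain_id = "s", cds_id = letters[1:5],
                      sequence = replicate(5, rand_dna(150)))
  expect_length(cluster_orthologs(pool2, prefilter = FALSE), 5L)
})

test_that("clustering is order-invariant and refines with the threshold", {
  spec <- pan_pool_spec(n_core = 8, n_accessory = 4,
                        n_group_specific = c(A = 2, B = 2),
                        within_ortholog_divergence = 0.03,
                        gene_length_range = c(300, 450), seed = 17)
  g <- generate_strain_genomes(spec, c(A = 2, B = 2))
  pool <- pool_cds(g$strains)
  part <- function(cl) {
    p <- recovered_partition(cl, sort(pool$cds_id))
    split(sort(pool$cds_id), p)
  }
  cl1 <- cluster_orthologs(pool)
  set.seed(1)
  perm <- pool[sample(nrow(pool)), ]
  cl2 <- cluster_orthologs(perm)
  expect_setequal(unname(lapply(part(cl1), unname)),
                  unname(lapply(part(cl2), unname)))
  # raising the threshold never merges: each high-threshold cluster sits
  # inside one low-threshold cluster
  cl_hi <- cluster_orthologs(pool, threshold = 0.95)
  low_of <- recovered_partition(cl1, pool$cds_id)
  names(low_of) <- pool$cds_id
  for (cl in cl_hi)
    expect_length(unique(low_of[cl$members$cds_id]), 1L)
})

test_that("prefiltered clustering equals brute force on a mixed pool", {
  spec <- pan_pool_spec(n_core = 10, n_accessory = 6,
                        n_strain_specific = 2,
                        within_ortholog_divergence = 0.04,
                        gene_length_range = c(300, 600), seed = 23)
  g <- generate_strain_genomes(spec, c(A = 2, B = 2))
  pool <- pool_cds(g$strains)
  p1 <- recovered_partition(cluster_orthologs(pool), pool$cds_id)
  p2 <- recovered_partition(cluster_orthologs(pool, prefilter = FALSE),
                            pool$cds_id)
  expect_equal(ari(p1, p2), 1.0)
  expect_identical(p1, p2)  # same canonical ordering too
})

test_that("consensus takes the column plurality with documented tie rule", {
  expect_identical(consensus_sequence("ACGTACGT"), "ACGTACGT")
  expect_identical(consensus_sequence(c("AAAA", "AAAT", "AAAT")), "AAAT")
  # 2 A vs 2 C: tie resolved by the fixed order A < C < G < T
  expect_identical(consensus_sequence(c("A", "A", "C", "C")), "A")
  expect_identical(consensus_sequence(c("T", "T", "G", "G")), "G")
  # gap-majority columns (here: end gaps of short members) are dropped
  expect_identical(consensus_sequence(c("AAATTT", "AAA", "AAA")), "AAA")
  expect_error(consensus_sequence(character(0)), "at least one")
})

test_that("pan matrix links copy numbers, presence and summaries", {
  pool <- data.frame(
    strain_id = c("S1", "S1", "S1", "S2", "S2", "S2"),
    cds_id = sprintf("c%d", 1:6),
    sequence = c(rand_dna(150), rand_dna(150), rand_dna(150),
                 rand_dna(150), rand_dna(150), rand_dna(150)))
  set.seed(3)
  base <- rand_dna(150)
  pool$sequence[4] <- base
  pool$sequence[5] <- mutate_exact(base, 5)   # S2 paralog pair
  cl <- cluster_orthologs(pool, prefilter = FALSE)
  pm <- build_pan_matrix(cl, c("S1", "S2"))
  # paralogs: one cluster holds two S2 copies
  par_og <- vapply(cl, function(x) nrow(x$members) == 2L, logical(1))
  og <- cl[[which(par_og)]]$ortholog_id
  expect_equal(pm$copy_number["S2", og], 2L)
  expect_equal(pm$presence["S2", og], 1L)
  expect_identical(pm$presence >= 1L, pm$copy_number >= 1L)
  expect_true(all(colSums(pm$presence) >= 1L))
  expect_error(build_pan_matrix(cl, "S1"), "not in strain list")

  # single strain, singleton clusters: all-ones presence row
  pool1 <- data.frame(strain_id = "S1", cds_id = c("a", "b", "c"),
                      sequence = replicate(3, rand_dna(120)))
  pm1 <- build_pan_matrix(cluster_orthologs(pool1, prefilter = FALSE), "S1")
  expect_equal(unname(pm1$presence["S1", ]), rep(1L, 3))
})

test_that("pan-genome summary reports core, specific and histogram", {
  fake <- function(p) {
    structure(list(presence = p, copy_number = p), class = "pan_matrix")
  }
  all1 <- matrix(1L, 3, 4, dimnames = list(c("a", "b", "c"), sprintf("o%d", 1:4)))
  s1 <- pan_genome_summary(fake(all1))
  expect_equal(s1$total, 4); expect_equal(s1$core, 4)
  expect_equal(s1$strain_specific, 0)
  eye <- diag(3); dimnames(eye) <- dimnames(all1)[c(1, 1)]
  colnames(eye) <- sprintf("o%d", 1:3)
  s2 <- pan_genome_summary(fake(eye))
  expect_equal(s2$core, 0); expect_equal(s2$strain_specific, 3)
  expect_equal(unname(s2$histogram), c(3L, 0L, 0L))
  # group-exclusive counts on a planted design, via the truth table
  spec <- pan_pool_spec(n_core = 6, n_group_specific = c(A = 3, B = 1),
                        n_strain_specific = 1,
                        gene_length_range = c(150, 300),
                        within_ortholog_divergence = 0.02, seed = 19)
  g <- generate_strain_genomes(spec, c(A = 2, B = 2))
  pool <- pool_cds(g$strains)
  pm <- build_pan_matrix(cluster_orthologs(pool), g$strains)
  s3 <- pan_genome_summary(pm, strain_groups_of(g))
  expect_equal(s3$total, 6 + 3 + 1 + 4)
  expect_equal(s3$core, 6)
  expect_equal(s3$strain_specific, 4)
  expect_equal(unname(s3$group_exclusive[c("A", "B")]),
               c(3 + 2, 1 + 2))  # group-specific + own strain-specific
})

test_that("fragment ANI is 100 for self and tracks planted divergence", {
  set.seed(29)
  genome <- replicate(5, rand_dna(900))
  self <- compute_ani(genome, genome)
  expect_equal(self$ani_percent, 100)
  expect_false(self$undefined)
  expect_equal(self$fraction_fragments_used, 1)
  # 1% mutated copy: ANI within [98.5, 99.5]
  mutated <- vapply(genome, function(s)
    mutate_exact(s, round(0.01 * nchar(s))), character(1))
  ani <- compute_ani(genome, mutated)
  expect_gt(ani$ani_percent, 98.5)
  expect_lt(ani$ani_percent, 99.5)
  # unrelated genome: no qualifying fragment, flagged undefined
  unrelated <- replicate(5, rand_dna(900))
  none <- compute_ani(genome, unrelated, min_identity = 0.9)
  expect_true(none$undefined)
  expect_true(is.na(none$ani_percent))
})
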