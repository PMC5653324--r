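test_that("pool spec validation rejects impossible designs", {
  expect_error(pan_pool_spec(n_core = -1), "non-negative")
  expect_error(pan_pool_spec(5, within_ortholog_divergence = 0.2), "0.15")
  expect_error(pan_pool_spec(5, gene_length_range = c(12, 60)), "30 bp")
  expect_error(pan_pool_spec(5, pseudogene_rate = 1.5), "0, 1")
  expect_error(pan_pool_spec(5, n_group_specific = c(2, 1)), "named")
  expect_error(
    generate_strain_genomes(pan_pool_spec(5), c(3, 3)), "named")
})

test_that("core-only zero-divergence design gives identical CDS sets", {
  spec <- pan_pool_spec(n_core = 10, within_ortholog_divergence = 0,
                        gene_length_range = c(90, 150), seed = 3)
  g <- generate_strain_genomes(spec, c(A = 2, B = 2))
  expect_length(g$strains, 4L)
  seq_sets <- lapply(g$strains, function(s) unname(s$cds))
  for (s in seq_sets) expect_length(s, 10L)
  for (s in seq_sets[-1]) expect_identical(s, seq_sets[[1]])
  # and every copy equals its ancestral ortholog
  expect_identical(unname(g$strains[[1]]$cds),
                   unname(g$ancestral[g$truth$ortholog_id[1:10]]))
})

test_that("group-specific orthologs count into the right group only", {
  spec <- pan_pool_spec(n_core = 5, n_group_specific = c(A = 3, B = 1),
                        gene_length_range = c(90, 150), seed = 4)
  g <- generate_strain_genomes(spec, c(A = 3, B = 3))
  n_cds <- vapply(g$strains, function(s) length(s$cds), integer(1))
  grp <- vapply(g$strains, function(s) s$group, character(1))
  expect_equal(unname(n_cds[grp == "A"]), rep(8L, 3))
  expect_equal(unname(n_cds[grp == "B"]), rep(6L, 3))
})

test_that("pseudogene fraction matches the binomial expectation", {
  # ~1000 genes at rate 0.1: observed fraction within 3 binomial SDs
  spec <- pan_pool_spec(n_core = 100, within_ortholog_divergence = 0.01,
                        gene_length_range = c(90, 300),
                        pseudogene_rate = 0.1, seed = 7)
  g <- generate_strain_genomes(spec, c(A = 5, B = 5))
  n <- nrow(g$truth)
  expect_equal(n, 1000L)
  frac <- mean(g$truth$is_pseudogene)
  band <- 3 * sqrt(0.1 * 0.9 / n)
  expect_gt(frac, 0.1 - band)
  expect_lt(frac, 0.1 + band)
  # every planted pseudogene, and nothing else, carries a premature stop
  has_stop <- vapply(g$strains, function(s)
    vapply(s$cds, salipan:::.has_premature_stop, logical(1)),
    logical(100))
  expect_identical(as.vector(has_stop), g$truth$is_pseudogene)
})

test_that("identical seeds reproduce byte-identical output", {
  spec <- pan_pool_spec(n_core = 8, n_accessory = 5,
                        n_group_specific = c(A = 2, B = 2),
                        gene_length_range = c(90, 150),
                        pseudogene_rate = 0.1, seed = 99)
  g1 <- generate_strain_genomes(spec, c(A = 2, B = 2))
  g2 <- generate_strain_genomes(spec, c(A = 2, B = 2))
  expect_identical(g1, g2)
  spec2 <- pan_pool_spec(n_core = 8, n_accessory = 5,
                         n_group_specific = c(A = 2, B = 2),
                         gene_length_range = c(90, 150),
                         pseudogene_rate = 0.1, seed = 100)
  g3 <- generate_strain_genomes(spec2, c(A = 2, B = 2))
  expect_false(identical(g1$strains, g3$strains))
})

test_that("within-ortholog identities exceed the threshold when d < (1-t)/2", {
  # truth-consistency invariant, checked by brute-force pairwise alignment
  spec <- pan_pool_spec(n_core = 6, within_ortholog_divergence = 0.05,
                        gene_length_range = c(300, 450), seed = 21)
  g <- generate_strain_genomes(spec, c(A = 3, B = 3))
  t_thr <- 0.85  # d = 0.05 < (1 - 0.85)/2
  by_og <- split(g$truth$cds_id, g$truth$ortholog_id)
  all_cds <- unlist(lapply(g$strains, function(s) s$cds))
  names(all_cds) <- unlist(lapply(g$strains, function(s) names(s$cds)))
  for (ids in by_og) {
    prs <- combn(ids, 2)
    for (k in seq_len(ncol(prs)))
      expect_gt(pairwise_identity(all_cds[[prs[1, k]]],
                                  all_cds[[prs[2, k]]]), t_thr)
  }
})

test_that("reference panel planting hits the requested identity exactly", {
  spec <- pan_pool_spec(n_core = 12, within_ortholog_divergence = 0,
                        gene_length_range = c(900, 900), seed = 31)
  g <- generate_strain_genomes(spec, c(A = 2, B = 2))
  # identity 1: panel genes equal their ancestral sources verbatim
  p1 <- generate_reference_panel(g, n_genes = 4,
                                 categories = c("tet", "erm"),
                                 identity_to_planted = 1, seed = 5)
  src <- attr(p1$panel, "source_ortholog")
  expect_identical(unname(p1$panel$sequence),
                   unname(g$ancestral[src]))
  expect_equal(as.vector(table(p1$panel$category)), c(2L, 2L))
  expect_equal(sort(unique(
    p1$truth$planted_panel_hit[!is.na(p1$truth$planted_panel_hit)])),
    sort(p1$panel$gene_id))
  # identity 0.95 at 900 bp: Hamming identity lands in [0.93, 0.97]
  p2 <- generate_reference_panel(g, n_genes = 6, categories = "eps",
                                 identity_to_planted = 0.95, seed = 6)
  src2 <- attr(p2$panel, "source_ortholog")
  for (i in seq_len(6)) {
    a <- strsplit(p2$panel$sequence[i], "")[[1]]
    b <- strsplit(g$ancestral[[src2[i]]], "")[[1]]
    h <- mean(a == b)
    expect_gt(h, 0.93); expect_lt(h, 0.97)
  }
  expect_error(generate_reference_panel(g, n_genes = 50, categories = "x"),
               "exceeds")
})

test_that("measurement tables honour means, noise and replication", {
  m0 <- generate_measurement_tables(c(SBP = 3.79, SAP = 40.25),
                                    noise_sd = 0, n_replicates = 4,
                                    seed = 1)
  expect_equal(m0$value[m0$group == "SBP"], rep(3.79, 4))
  expect_equal(m0$value[m0$group == "SAP"], rep(40.25, 4))
  expect_equal(unique(m0$timepoint_h), 48)
  # lognormal zero-noise equals the stated means too
  m1 <- generate_measurement_tables(c(A = 1e5, B = 4e5), noise_sd = 0,
                                    n_replicates = 3, seed = 1,
                                    type = "lognormal")
  expect_equal(sort(unique(m1$value)), c(1e5, 4e5))
  # one replicate per group: the downstream group test refuses to run
  m2 <- generate_measurement_tables(c(A = 1, B = 2), noise_sd = 0,
                                    n_replicates = 1, seed = 1)
  expect_error(welch_t_test(m2$value[m2$group == "A"],
                            m2$value[m2$group == "B"]),
               "insufficient")
  expect_error(generate_measurement_tables(c(A = 1), noise_sd = -1),
               ">= 0")
})

test_that("biofilm-scale group effects are detected in nearly all seeds", {
  # printed 48-h dye means/SDs; Welch rejects at 0.05 in > 95% of 200 seeds
  hits <- 0L
  for (s in seq_len(200)) {
    tab <- generate_measurement_tables(
      c(SBP = 3.79, SAP = 40.25), noise_sd = c(SBP = 1.62, SAP = 4.64),
      n_replicates = c(SBP = 6, SAP = 15), seed = s)
    p <- welch_t_test(tab$value[tab$group == "SBP"],
                      tab$value[tab$group == "SAP"])$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.95)
})

test_that("MLST loci are group-structured and deterministic", {
  sg <- setNames(rep(c("SBP", "SAP"), c(3, 4)),
                 c(sprintf("SBP%02d", 1:3), sprintf("SAP%02d", 1:4)))
  loci <- generate_mlst_loci(sg, locus_length = 300, n_diagnostic = 4,
                             divergence = 0.002, seed = 12)
  expect_named(loci, MLST_LOCI)
  expect_true(all(vapply(loci, function(a)
    all(nchar(a) == 300), logical(1))))
  expect_identical(loci, generate_mlst_loci(sg, locus_length = 300,
                                            n_diagnostic = 4,
                                            divergence = 0.002, seed = 12))
  # between-group Hamming distance exceeds within-group at every locus
  for (a in loci) {
    ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    within <- c(ham(a[["SBP01"]], a[["SBP02"]]),
                ham(a[["SAP01"]], a[["SAP02"]]))
    between <- ham(a[["SBP01"]], a[["SAP01"]])
    expect_gt(between, max(within))
  }
})

test_that("subsystem tables assign categories per ortholog with planting", {
  spec <- pan_pool_spec(n_core = 10, n_group_specific = c(A = 7, B = 2),
                        gene_length_range = c(90, 150), seed = 8)
  g <- generate_strain_genomes(spec, c(A = 3, B = 3))
  ss <- generate_subsystem_table(g, n_categories = 5,
                                 planted_category = "rhamnose",
                                 planted_group = "A",
                                 planted_orthologs = 7, seed = 2)
  expect_identical(ss$cds_id, g$truth$cds_id)
  # category is a function of the ortholog
  by_og <- split(ss$subsystem, g$truth$ortholog_id)
  expect_true(all(vapply(by_og, function(v)
    length(unique(v)) == 1L, logical(1))))
  # the planted category sits on group-A-exclusive orthologs only
  planted_og <- unique(g$truth$ortholog_id[ss$subsystem == "rhamnose"])
  expect_length(planted_og, 7L)
  expect_true(all(g$truth$group[g$truth$ortholog_id %in% planted_og] == "A"))
})
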