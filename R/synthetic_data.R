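## Synthetic strain-genome generator with full ground truth.
##
## Emulates the gene-content structure of a two-group bacterial strain
## collection: a pan-gene pool with core, accessory, group-specific and
## strain-specific orthologs; within-ortholog nucleotide divergence;
## pseudogenes carrying an in-frame premature stop; optional planted
## reference-panel homologs at a requested identity; group-structured MLST
## loci; and measurement tables (biofilm dye mass, competition cell counts)
## with group effects and noise. Every CDS is recorded in a truth table so
## downstream stages can be verified exactly.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, .STOP_CODONS)
})

#' Specification of a synthetic pan-gene pool
#'
#' Describes the ortholog structure and mutation process used by
#' [generate_strain_genomes()].
#'
#' @param n_core Number of core orthologs (present in every strain).
#' @param n_accessory Number of accessory orthologs; each strain carries each
#'   accessory ortholog independently with probability
#'   `accessory_presence_prob`.
#' @param n_group_specific Named integer vector, one entry per group, of
#'   group-exclusive ortholog counts (carried by every strain of that group,
#'   by no strain of any other).
#' @param n_strain_specific Number of private orthologs per strain.
#' @param gene_length_range Length interval in bp; generated lengths are
#'   multiples of 3 and at least 30 bp. Default 600-1200 bp, around the
#'   typical bacterial CDS length of ~900 bp.
#' @param within_ortholog_divergence Per-site substitution probability
#'   applied independently to each strain's copy of an ortholog, in
#'   `[0, 0.15)`. Must stay below `1 - identity threshold` of the intended
#'   clustering so truth clusters are recoverable.
#' @param pseudogene_rate Probability that a strain's gene copy gains a
#'   premature in-frame TAA stop (placed in a uniformly random internal codon
#'   within the first 80% of the gene).
#' @param accessory_presence_prob Per-strain carriage probability of each
#'   accessory ortholog.
#' @param seed Master RNG seed. Per-stage child seeds are derived by fixed
#'   offsets (+1000 ancestral pool, +2000 strain copies, +3000 pseudogenes,
#'   +4000 reference panel, +5000 measurements, +6000 MLST, +7000 subsystems).
#' @return An object of class `pan_pool_spec`.
#' @export
pan_pool_spec <- function(n_core,
                          n_accessory = 0,
                          n_group_specific = integer(0),
                          n_strain_specific = 0,
                          gene_length_range = c(600, 1200),
                          within_ortholog_divergence = 0.02,
                          pseudogene_rate = 0,
                          accessory_presence_prob = 0.5,
                          seed = 1L) {
  counts <- c(n_core, n_accessory, n_group_specific, n_strain_specific)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("ortholog counts must be non-negative integers", call. = FALSE)
  if (length(gene_length_range) != 2L || gene_length_range[1] < 30 ||
      diff(gene_length_range) < 0)
    stop("gene_length_range must be an interval with minimum >= 30 bp",
         call. = FALSE)
  if (within_ortholog_divergence < 0 || within_ortholog_divergence >= 0.15)
    stop("within_ortholog_divergence must lie in [0, 0.15)", call. = FALSE)
  if (pseudogene_rate < 0 || pseudogene_rate > 1)
    stop("pseudogene_rate must lie in [0, 1]", call. = FALSE)
  if (accessory_presence_prob <= 0 || accessory_presence_prob > 1)
    stop("accessory_presence_prob must lie in (0, 1]", call. = FALSE)
  if (length(n_group_specific) > 0 && is.null(names(n_group_specific)))
    stop("n_group_specific must be a named vector (one entry per group)",
         call. = FALSE)
  structure(list(
    n_core = as.integer(n_core),
    n_accessory = as.integer(n_accessory),
    n_group_specific = n_group_specific,
    n_strain_specific = as.integer(n_strain_specific),
    gene_length_range = gene_length_range,
    within_ortholog_divergence = within_ortholog_divergence,
    pseudogene_rate = pseudogene_rate,
    accessory_presence_prob = accessory_presence_prob,
    seed = as.integer(seed)), class = "pan_pool_spec")
}

#' @export
print.pan_pool_spec <- function(x, ...) {
  cat("pan_pool_spec:", x$n_core, "core,", x$n_accessory, "accessory,",
      sum(x$n_group_specific), "group-specific,", x$n_strain_specific,
      "strain-specific per strain\n")
  cat("  divergence", x$within_ortholog_divergence,
      "| pseudogene rate", x$pseudogene_rate, "| seed", x$seed, "\n")
  invisible(x)
}

#' Random CDS-like ancestral gene: ATG + sense codons + TAA
#' @noRd
.random_gene <- function(length_range) {
  nc_min <- ceiling(length_range[1] / 3)
  nc_max <- floor(length_range[2] / 3)
  nc <- if (nc_min >= nc_max) nc_min else
    sample(nc_min:nc_max, 1L)
  paste0("ATG",
         paste(sample(.SENSE_CODONS, nc - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' i.i.d. per-site substitution, uniform over the 3 alternatives.
#'
#' Substitutions that would create an in-frame premature stop are reverted to
#' the ancestral codon (purifying selection), so that the truth pseudogene
#' flag exactly determines the premature-stop filter's outcome.
#' @noRd
.mutate_cds <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    nc <- length(v) / 3L
    if (nc > 2L) {
      codon_start <- seq(4L, by = 3L, length.out = nc - 2L)
      anc <- strsplit(seq, "")[[1]]
      for (cs in codon_start) {
        if (paste(v[cs:(cs + 2L)], collapse = "") %in% .STOP_CODONS)
          v[cs:(cs + 2L)] <- anc[cs:(cs + 2L)]
      }
    }
  }
  paste(v, collapse = "")
}

#' Plant a premature TAA stop in an internal codon of the first 80%
#' @noRd
.plant_stop <- function(seq) {
  nc <- nchar(seq) / 3L
  hi <- max(2L, floor(0.8 * nc))
  hi <- min(hi, nc - 1L)          # never the final codon
  idx <- if (hi <= 2L) 2L else sample(2L:hi, 1L)
  substr(seq, (idx - 1L) * 3L + 1L, idx * 3L) <- "TAA"
  seq
}

#' Container for one strain's coding sequences
#'
#' @param strain_id Strain label.
#' @param group Group label (e.g. SBP or SAP).
#' @param cds Named character vector of nucleotide CDSs (names are CDS ids,
#'   unique within the strain).
#' @param genome_size Genome size in Mbp; defaults to the summed CDS length.
#' @param gc Percent G+C over the concatenated CDSs; computed if missing.
#' @return An object of class `strain_cds_set`.
#' @export
strain_cds_set <- function(strain_id, group, cds,
                           genome_size = NULL, gc = NULL) {
  if (length(cds) == 0L) {
    ## empty sets arise from filtering; features are undefined, not zero
    return(structure(list(strain_id = strain_id, group = group,
                          cds = setNames(character(0), character(0)),
                          genome_size = genome_size %||% NA_real_,
                          gc_percent = gc %||% NA_real_),
                     class = "strain_cds_set"))
  }
  if (is.null(names(cds)) || anyDuplicated(names(cds)))
    stop("cds must be a named vector with unique ids", call. = FALSE)
  check_dna(cds, sprintf("CDSs of strain %s", strain_id))
  gs <- genome_size %||% (sum(nchar(cds)) / 1e6)
  if (gs <= 0) stop("genome_size must be positive", call. = FALSE)
  gcp <- gc %||% gc_percent(cds)
  if (!is.na(gcp) && (gcp < 0 || gcp > 100))
    stop("gc_percent must lie in [0, 100]", call. = FALSE)
  structure(list(strain_id = strain_id, group = group, cds = cds,
                 genome_size = gs, gc_percent = gcp),
            class = "strain_cds_set")
}

#' @export
print.strain_cds_set <- function(x, ...) {
  cat(sprintf("strain_cds_set %s (group %s): %d CDSs, %.3f Mbp, %.2f%% GC\n",
              x$strain_id, x$group, length(x$cds), x$genome_size,
              x$gc_percent))
  invisible(x)
}

#' Generate synthetic strain genomes with a ground-truth table
#'
#' Builds an ancestral sequence per ortholog, distributes orthologs to
#' strains according to the core/accessory/group-specific/strain-specific
#' design, mutates each strain's copy at the specified per-site divergence,
#' and plants premature stop codons at the pseudogene rate. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [pan_pool_spec()].
#' @param n_strains_per_group Named integer vector of strains per group,
#'   e.g. `c(SBP = 6, SAP = 15)`. Group names must cover the names of
#'   `spec$n_group_specific`.
#' @return A list with components
#'   \describe{
#'     \item{strains}{list of [strain_cds_set()] objects;}
#'     \item{truth}{data.frame with one row per generated CDS: `cds_id`,
#'       `strain_id`, `group`, `ortholog_id`, `is_pseudogene`,
#'       `planted_panel_hit` (NA until a panel is planted);}
#'     \item{ancestral}{named character vector of ancestral ortholog
#'       sequences.}
#'   }
#' @export
generate_strain_genomes <- function(spec,
                                    n_strains_per_group = c(SBP = 6, SAP = 15)) {
  if (!inherits(spec, "pan_pool_spec"))
    stop("spec must be a pan_pool_spec", call. = FALSE)
  groups <- names(n_strains_per_group)
  if (is.null(groups) || any(n_strains_per_group < 1))
    stop("n_strains_per_group must be named with >= 1 strain per group",
         call. = FALSE)
  gs_names <- names(spec$n_group_specific)
  if (!all(gs_names %in% groups))
    stop("groups in spec$n_group_specific missing from n_strains_per_group",
         call. = FALSE)

  strain_ids <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", g, seq_len(n_strains_per_group[[g]]))))
  strain_group <- setNames(rep(groups, n_strains_per_group), strain_ids)

  ## stage 1: ancestral ortholog pool
  set.seed(child_seed(spec$seed, 1L))
  n_strains <- length(strain_ids)
  og_roles <- c(rep("core", spec$n_core),
                rep("accessory", spec$n_accessory),
                unlist(lapply(gs_names, function(g)
                  rep(paste0("group:", g), spec$n_group_specific[[g]]))),
                unlist(lapply(strain_ids, function(s)
                  rep(paste0("strain:", s), spec$n_strain_specific))))
  n_og <- length(og_roles)
  if (n_og == 0L) stop("pool spec generates no orthologs", call. = FALSE)
  og_ids <- sprintf("OG%04d", seq_len(n_og))
  ancestral <- setNames(
    vapply(seq_len(n_og), function(i) .random_gene(spec$gene_length_range),
           character(1)),
    og_ids)

  ## ortholog -> strain incidence
  carries <- matrix(FALSE, n_strains, n_og,
                    dimnames = list(strain_ids, og_ids))
  carries[, og_roles == "core"] <- TRUE
  acc <- which(og_roles == "accessory")
  if (length(acc))
    carries[, acc] <- matrix(
      runif(n_strains * length(acc)) < spec$accessory_presence_prob,
      n_strains, length(acc))
  for (g in gs_names)
    carries[strain_ids[strain_group == g], og_roles == paste0("group:", g)] <- TRUE
  for (s in strain_ids)
    carries[s, og_roles == paste0("strain:", s)] <- TRUE

  ## stage 2: per-strain mutated copies; stage 3: pseudogenes
  set.seed(child_seed(spec$seed, 2L))
  strains <- vector("list", n_strains)
  names(strains) <- strain_ids
  truth_rows <- vector("list", n_strains)
  for (si in seq_len(n_strains)) {
    s <- strain_ids[si]
    ogs <- og_ids[carries[s, ]]
    seqs <- vapply(ancestral[ogs], .mutate_cds,
                   rate = spec$within_ortholog_divergence,
                   FUN.VALUE = character(1))
    pseudo <- runif(length(seqs)) < spec$pseudogene_rate
    if (any(pseudo))
      seqs[pseudo] <- vapply(seqs[pseudo], .plant_stop, character(1))
    cds_ids <- sprintf("%s_g%04d", s, seq_along(seqs))
    names(seqs) <- cds_ids
    strains[[si]] <- strain_cds_set(s, strain_group[[s]], seqs)
    truth_rows[[si]] <- data.frame(
      cds_id = cds_ids, strain_id = s, group = strain_group[[s]],
      ortholog_id = ogs, is_pseudogene = pseudo,
      planted_panel_hit = NA_character_,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(strains = strains, truth = truth, ancestral = ancestral)
}

#' Plant a labelled reference gene panel into a synthetic pool
#'
#' Selects source orthologs from the generated pool and derives panel genes
#' from their ancestral sequences, substituting an exact number of sites,
#' `floor((1 - identity_to_planted) * length)`, at distinct random positions
#' so the realised identity equals the request (or exceeds it by at most
#' one part in the gene length: a request of exactly 0.90 must never land
#' below the acceptance boundary through rounding). Category labels (e.g.
#' lincosamide, tetracycline) are assigned round-robin. The truth table is
#' returned with `planted_panel_hit` filled for every CDS of each source
#' ortholog.
#'
#' @param genomes Result of [generate_strain_genomes()].
#' @param n_genes Number of panel genes; must not exceed the number of
#'   eligible source orthologs.
#' @param categories Character vector of category labels, recycled across
#'   genes.
#' @param identity_to_planted Fraction in `[0, 1]`: identity of each panel
#'   gene to its (ancestral) source sequence. May be a vector recycled over
#'   genes.
#' @param seed RNG seed (default: stage-4 child of the pool seed is not
#'   implied; pass explicitly for reproducibility).
#' @param families Optional family labels, recycled; default "unassigned".
#' @param min_members Only orthologs with at least this many member CDSs are
#'   eligible sources (consensus sequences of well-populated clusters match
#'   the ancestor, making planted identities exact downstream).
#' @return List with `panel` (a [reference_gene_panel()]) and `truth` (the
#'   updated truth table).
#' @export
generate_reference_panel <- function(genomes, n_genes, categories,
                                     identity_to_planted = 1,
                                     seed = 1L,
                                     families = "unassigned",
                                     min_members = 2L) {
  if (any(identity_to_planted < 0 | identity_to_planted > 1))
    stop("identity_to_planted must lie in [0, 1]", call. = FALSE)
  truth <- genomes$truth
  tab <- table(truth$ortholog_id)
  eligible <- names(tab)[tab >= min_members]
  if (n_genes > length(eligible))
    stop(sprintf("n_genes (%d) exceeds eligible source orthologs (%d)",
                 n_genes, length(eligible)), call. = FALSE)
  set.seed(seed)
  src <- sample(sort(eligible), n_genes)
  cats <- rep(categories, length.out = n_genes)
  fams <- rep(families, length.out = n_genes)
  idents <- rep(identity_to_planted, length.out = n_genes)
  gene_seq <- character(n_genes)
  gene_id <- character(n_genes)
  cat_count <- integer(0)
  for (i in seq_len(n_genes)) {
    anc <- genomes$ancestral[[src[i]]]
    L <- nchar(anc)
    nsub <- floor((1 - idents[i]) * L)
    v <- strsplit(anc, "")[[1]]
    if (nsub > 0) {
      pos <- sample(L, nsub)
      v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    gene_seq[i] <- paste(v, collapse = "")
    k <- if (cats[i] %in% names(cat_count)) cat_count[[cats[i]]] else 0L
    cat_count[cats[i]] <- k + 1L
    gene_id[i] <- sprintf("%s_%03d", cats[i], k + 1L)
  }
  panel <- reference_gene_panel(data.frame(
    gene_id = gene_id, category = cats, family = fams,
    sequence = gene_seq, stringsAsFactors = FALSE))
  hit <- match(truth$ortholog_id, src)
  truth$planted_panel_hit <- ifelse(is.na(hit), truth$planted_panel_hit,
                                    gene_id[hit])
  attr(panel, "source_ortholog") <- setNames(src, gene_id)
  attr(panel, "planted_identity") <- setNames(idents, gene_id)
  list(panel = panel, truth = truth)
}

#' Generate group-structured measurement tables
#'
#' Emulates assay tables (crystal-violet biofilm dye mass, competition cell
#' counts) with per-group means, replicate noise and fixed seed. Gaussian
#' noise suits dye masses; log-normal noise (meanlog at the group mean's
#' logarithm, so the group median equals the stated mean) suits cell counts.
#'
#' @param group_means Either a named numeric vector (one mean per group; a
#'   single time point, see `timepoint`) or a named list of named numeric
#'   vectors `list(GROUP = c("24" = m24, "48" = m48))` for multiple time
#'   points.
#' @param noise_sd Non-negative noise SD, in assay units (gaussian) or log
#'   units (lognormal). Scalar, or structured like `group_means` for
#'   per-group / per-time-point SDs.
#' @param n_replicates Replicates (strains) per group; scalar or named per
#'   group.
#' @param seed RNG seed.
#' @param type "gaussian" or "lognormal".
#' @param timepoint Time point in hours used when `group_means` is a plain
#'   vector (default 48).
#' @return data.frame with columns `strain_id`, `group`, `timepoint_h`,
#'   `value`. Gaussian draws below zero are clamped to 0 (assay floors).
#' @export
generate_measurement_tables <- function(group_means, noise_sd = 0,
                                        n_replicates = 6, seed = 1L,
                                        type = c("gaussian", "lognormal"),
                                        timepoint = 48) {
  type <- match.arg(type)
  if (any(unlist(noise_sd) < 0))
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.list(group_means))
    group_means <- lapply(setNames(as.list(group_means), names(group_means)),
                          function(m) setNames(m, timepoint))
  groups <- names(group_means)
  if (is.null(groups)) stop("group_means must be named", call. = FALSE)
  get_sd <- function(g, tp) {
    if (!is.list(noise_sd) && length(noise_sd) == 1L) return(noise_sd)
    v <- if (is.list(noise_sd)) noise_sd[[g]] else noise_sd[g]
    if (length(v) > 1L && !is.null(names(v))) v <- v[[as.character(tp)]]
    as.numeric(v)
  }
  nrep <- if (length(n_replicates) == 1L)
    setNames(rep(n_replicates, length(groups)), groups) else n_replicates
  set.seed(seed)
  out <- list()
  for (g in groups) {
    ids <- sprintf("%s%02d", g, seq_len(nrep[[g]]))
    for (tp in names(group_means[[g]])) {
      m <- group_means[[g]][[tp]]
      s <- get_sd(g, tp)
      val <- switch(type,
        gaussian = pmax(0, m + rnorm(length(ids), 0, s)),
        lognormal = if (s == 0) rep(m, length(ids)) else
          rlnorm(length(ids), meanlog = log(m), sdlog = s))
      out[[length(out) + 1L]] <- data.frame(
        strain_id = ids, group = g, timepoint_h = as.numeric(tp),
        value = val, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Canonical MLST locus names (fixed concatenation order)
#' @export
MLST_LOCI <- c("pstB", "rpsB", "pheS", "ftsQ", "nrdB", "rpoA", "parB")

#' Generate group-structured MLST locus alignments
#'
#' One ancestral sequence per housekeeping locus; every group beyond the
#' first receives `n_diagnostic` fixed group-diagnostic substitutions per
#' locus; every strain then receives i.i.d. substitution noise at
#' `divergence`. All sequences of a locus have equal length (gap-free
#' alignment), emulating aligned single-copy housekeeping genes.
#'
#' @param strain_groups Named character vector mapping strain id to group.
#' @param locus_length Length of each locus in bp.
#' @param n_diagnostic Group-diagnostic substitutions per locus per
#'   non-reference group.
#' @param divergence Per-site, per-strain noise substitution probability.
#' @param seed RNG seed.
#' @return Named list of 7 alignments (named character vectors), names
#'   `MLST_LOCI`.
#' @export
generate_mlst_loci <- function(strain_groups, locus_length = 480,
                               n_diagnostic = 3, divergence = 0.005,
                               seed = 1L) {
  stopifnot(!is.null(names(strain_groups)))
  set.seed(seed)
  groups <- unique(strain_groups)
  lapply(setNames(MLST_LOCI, MLST_LOCI), function(locus) {
    anc <- paste(sample(c("A", "C", "G", "T"), locus_length, TRUE),
                 collapse = "")
    group_seq <- setNames(rep(anc, length(groups)), groups)
    for (g in groups[-1]) {
      v <- strsplit(anc, "")[[1]]
      pos <- sample(locus_length, n_diagnostic)
      v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      group_seq[[g]] <- paste(v, collapse = "")
    }
    out <- vapply(names(strain_groups), function(s) {
      v <- strsplit(group_seq[[strain_groups[[s]]]], "")[[1]]
      hit <- which(runif(locus_length) < divergence)
      if (length(hit))
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      paste(v, collapse = "")
    }, character(1))
    out
  })
}

#' Generate a subsystem (functional category) assignment table
#'
#' Assigns each ortholog a functional category uniformly at random
#' (consistently across all member CDSs), then optionally plants one
#' category onto orthologs exclusive to one group, emulating a
#' group-enriched subsystem such as a sugar-utilisation pathway present in
#' one group only.
#'
#' @param genomes Result of [generate_strain_genomes()].
#' @param n_categories Number of background categories ("SS1", "SS2", ...).
#' @param planted_category Optional label for the planted enriched category.
#' @param planted_group Group whose exclusive orthologs receive the planted
#'   category.
#' @param planted_orthologs Number of group-exclusive orthologs to label
#'   with the planted category (capped at availability).
#' @param seed RNG seed.
#' @return data.frame with columns `cds_id`, `strain_id`, `subsystem`.
#' @export
generate_subsystem_table <- function(genomes, n_categories = 8,
                                     planted_category = NULL,
                                     planted_group = NULL,
                                     planted_orthologs = 7,
                                     seed = 1L) {
  truth <- genomes$truth
  set.seed(seed)
  ogs <- sort(unique(truth$ortholog_id))
  assign <- setNames(sample(paste0("SS", seq_len(n_categories)),
                            length(ogs), replace = TRUE), ogs)
  if (!is.null(planted_category)) {
    if (is.null(planted_group))
      stop("planted_group required with planted_category", call. = FALSE)
    in_group <- unique(truth$ortholog_id[truth$group == planted_group])
    out_group <- unique(truth$ortholog_id[truth$group != planted_group])
    exclusive <- setdiff(in_group, out_group)
    take <- head(sort(exclusive), planted_orthologs)
    assign[take] <- planted_category
  }
  data.frame(cds_id = truth$cds_id, strain_id = truth$strain_id,
             subsystem = unname(assign[truth$ortholog_id]),
             stringsAsFactors = FALSE)
}
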