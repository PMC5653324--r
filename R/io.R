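## Readers and writers for the formats the pipeline touches: CDS FASTA,
## reference-panel FASTA, Newick trees, TSV tables. Readers reject
## malformed records rather than silently repairing them; writers are
## deterministic given identical inputs.

#' Read one strain's CDS set from a multi-FASTA file
#'
#' Records are loaded in file order; lowercase bases are normalised to
#' uppercase; the GC percentage is computed over the concatenated CDSs.
#' Empty files, duplicate ids and characters outside A, C, G, T, N are
#' rejected with typed errors.
#'
#' @param path FASTA file path.
#' @param strain_id Strain label.
#' @param group Group label.
#' @param genome_size Optional genome size in Mbp (defaults to summed CDS
#'   length).
#' @return A [strain_cds_set()].
#' @export
read_strain_fasta <- function(path, strain_id, group, genome_size = NULL) {
  if (!file.exists(path))
    stop_stage("read_strain_fasta", "file not found: ", path)
  ## read as raw strings first: DNAStringSet would silently drop invalid
  ## letters, and readers must reject rather than repair
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop_stage("read_strain_fasta", "unparsable FASTA (",
                               conditionMessage(e), "): ", path))
  if (length(set) == 0L)
    stop_stage("read_strain_fasta", "empty FASTA: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  ## headers written as strainID|cdsID keep only the CDS id
  ids <- sub("^[^|]*\\|", "", ids)
  if (anyDuplicated(ids))
    stop_stage("read_strain_fasta", "duplicate CDS ids in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_stage("read_strain_fasta", "illegal characters in record ",
               ids[which(bad)[1L]])
  names(seqs) <- ids
  strain_cds_set(strain_id, group, seqs, genome_size = genome_size)
}

#' Write a strain CDS set as multi-FASTA (headers strainID|cdsID, 70 cols)
#'
#' @param set A [strain_cds_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_strain_fasta <- function(set, path) {
  stopifnot(inherits(set, "strain_cds_set"))
  x <- Biostrings::DNAStringSet(set$cds)
  names(x) <- paste(set$strain_id, names(set$cds), sep = "|")
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Labelled reference gene panel (AR / EPS / extracellular-protein families)
#'
#' @param records data.frame with columns `gene_id`, `category`, `family`,
#'   `sequence`. Gene ids must be unique, sequences non-empty nucleotide
#'   strings.
#' @return An object of class `reference_gene_panel` (a data.frame).
#' @export
reference_gene_panel <- function(records) {
  need <- c("gene_id", "category", "family", "sequence")
  if (!all(need %in% names(records)))
    stop("panel records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$gene_id))
    stop("panel gene_ids must be unique", call. = FALSE)
  check_dna(records$sequence, "panel sequence")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(records, class = c("reference_gene_panel", "data.frame"))
}

#' Read a reference panel from FASTA with geneID|category|family headers
#' @param path FASTA file path.
#' @return A [reference_gene_panel()].
#' @export
read_panel_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop_stage("read_panel_fasta", "empty FASTA: ", path)
  parts <- strsplit(sub("\\s.*$", "", names(set)), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop_stage("read_panel_fasta",
               "headers must be geneID|category|family")
  reference_gene_panel(data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    category = vapply(parts, `[`, "", 2L),
    family = vapply(parts, `[`, "", 3L),
    sequence = toupper(as.character(set)),
    stringsAsFactors = FALSE))
}

#' Write a reference panel to FASTA (geneID|category|family headers)
#' @param panel A [reference_gene_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  x <- Biostrings::DNAStringSet(setNames(
    panel$sequence,
    paste(panel$gene_id, panel$category, panel$family, sep = "|")))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are kept; integer bootstrap supports, when present as
#' node labels, are written as internal-node labels. Re-reading with
#' [read_newick()] reproduces the topology exactly.
#'
#' @param tree An `ape` "phylo" object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  bad <- grepl("[],;:()[]", tree$tip.label)
  if (any(bad))
    stop_stage("write_newick", "tip labels not serializable to Newick: ",
               tree$tip.label[which(bad)[1L]])
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file path.
#' @return An `ape` "phylo" object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a data.frame as a TSV with header row
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header row
#' @noRd
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
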