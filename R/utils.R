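## Internal helpers shared across modules.

## data.table is used unattached; opt in to its [ semantics
.datatable.aware <- TRUE

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a stage-labelled error
#' @noRd
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

#' Validate a DNA sequence vector over the {A,C,G,T,N} alphabet
#' @noRd
check_dna <- function(x, what = "sequence") {
  if (length(x) == 0L || any(!nzchar(x)))
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: record %d",
                 what, which(bad)[1L]), call. = FALSE)
  invisible(TRUE)
}

#' Derive a per-stage child seed from a master seed
#'
#' Child seeds are `master + 1000 * stage`, kept below 2^31 by wrapping.
#' Stages are numbered: 1 ancestral pool, 2 strain mutation, 3 pseudogenes,
#' 4 reference panel, 5 measurements, 6 MLST, 7 subsystems.
#' @noRd
child_seed <- function(master, stage) {
  as.integer((as.numeric(master) + 1000 * stage) %% .Machine$integer.max)
}

#' GC percentage of a set of sequences, over their concatenation
#' @noRd
gc_percent <- function(seqs) {
  n_gc <- sum(vapply(seqs, function(s)
    sum(strsplit(s, "")[[1]] %in% c("G", "C")), integer(1)))
  n_tot <- sum(nchar(seqs))
  if (n_tot == 0L) return(NA_real_)
  100 * n_gc / n_tot
}

#' Split sequences into a character matrix of single bases (equal lengths)
#' @noRd
seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse a character matrix back to sequences
#' @noRd
matrix_seq <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}
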