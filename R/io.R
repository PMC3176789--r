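# FASTA reading/writing (thin wrappers around Biostrings with the
# normalization rules used throughout the package)

#' Read / write DNA sequences in FASTA format
#'
#' `read_fasta()` upcases mixed-case input with a warning, warns on
#' duplicate record ids, and rejects non-ACGT characters naming the
#' offending record.  `write_fasta()` wraps sequence lines at 60 columns.
#'
#' @param path file path.
#' @param x named character vector of sequences (names become record ids).
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    warning("duplicate FASTA id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lower <- grepl("[a-z]", seqs)
  if (any(lower)) {
    warning("lowercase letters in record(s) ",
            paste(ids[lower], collapse = ", "), "; upcased")
    seqs <- toupper(seqs)
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-ACGT characters in record '", ids[which(bad)[1L]], "'")
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  ids <- names(x) %||% paste0("seq", seq_along(x))
  set <- Biostrings::DNAStringSet(unname(x))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
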