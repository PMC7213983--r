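# Alignment container: a named character vector of equal-length amino-acid
# strings (gap "-" allowed). Kept deliberately light; conversion helpers below.

#' Validate an amino-acid alignment
#'
#' Checks that all sequences have equal length, that names are unique, and
#' that every character is one of the 20 amino-acid codes or the gap symbol.
#'
#' @param alignment Named character vector of sequences.
#' @return The alignment, invisibly, if valid; otherwise an error is thrown
#'   naming the first offending sequence and character.
#' @export
validate_alignment <- function(alignment) {
  if (length(alignment) == 0) stop("alignment is empty")
  if (is.null(names(alignment)) || anyNA(names(alignment)) ||
      any(names(alignment) == ""))
    stop("every sequence must be named")
  if (anyDuplicated(names(alignment)))
    stop("duplicate sequence names: ",
         paste(unique(names(alignment)[duplicated(names(alignment))]),
               collapse = ", "))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("sequences have unequal lengths (",
         paste(range(lens), collapse = "-"), ")")
  ok <- c(AA_STATES, GAP)
  for (nm in names(alignment)) {
    ch <- strsplit(alignment[[nm]], "")[[1]]
    bad <- which(!(ch %in% ok))
    if (length(bad))
      stop("illegal character '", ch[bad[1]], "' in sequence '", nm,
           "' at site ", bad[1])
  }
  invisible(alignment)
}

#' Convert an alignment to a site-by-sequence character matrix
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Character matrix with one row per sequence, one column per site.
#' @export
alignment_matrix <- function(alignment) {
  validate_alignment(alignment)
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Read an amino-acid FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  setNames(toupper(vapply(aa, as.character, character(1))), names(aa))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  lines <- character(0)
  for (nm in names(seqs)) lines <- c(lines, paste0(">", nm), seqs[[nm]])
  writeLines(lines, path)
  invisible(path)
}

#' Hamming distance between two aligned sequences
#'
#' Counts positions at which the two sequences differ; a gap opposite a
#' residue counts as a difference. No alignment is attempted: sequences must
#' already be the same length.
#'
#' @param seq_a,seq_b Character scalars (sequences) of equal length.
#' @return Integer count of differing positions.
#' @export
count_differences <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b))
    stop("sequence lengths differ (", length(a), " vs ", length(b),
         "); sequences must be pre-aligned")
  sum(a != b)
}
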