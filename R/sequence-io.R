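#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and normalizes each
#' sequence to the DNA alphabet \code{{A,C,G,T,N}}: lowercase letters are
#' uppercased, \code{U} is mapped to \code{T}, and any other character is
#' mapped to \code{N} with a warning.
#'
#' @param path Path to a FASTA file of DNA or RNA transcript sequences.
#' @return A data frame with columns \code{id} (the FASTA header up to the
#'   first whitespace) and \code{sequence} (normalized DNA string), one row
#'   per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "AUGGCC", ">tx2", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty header in ", path)
  }
  seqs <- normalize_sequence(as.character(set))
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write transcript sequences to a FASTA file
#'
#' @param records Data frame with columns \code{id} and \code{sequence}.
#' @param path Output file path.
#' @param width Line-wrap width in nucleotides.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Uppercase, U->T, and anything outside {A,C,G,T,N} -> N (warning names the
# offending characters once per call).
normalize_sequence <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nzchar(bad))) {
    chars <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    warning("non-ACGTUN characters mapped to N: ",
            paste(chars, collapse = " "))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  seqs
}

#' Read transcript labels from a two-column TSV
#'
#' The file has two tab-separated columns, \code{id} and \code{label}
#' (0 = noncoding, 1 = coding), with an optional header line.
#'
#' @param path Path to the TSV.
#' @return Named integer vector of 0/1 labels, names are transcript ids.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file must have two columns: id<TAB>label")
  if (identical(tolower(tab[1L, 2L]), "label")) tab <- tab[-1L, , drop = FALSE]
  lab <- as.integer(tab[[2L]])
  if (any(is.na(lab)) || any(!lab %in% c(0L, 1L))) {
    stop("labels must be 0 (noncoding) or 1 (coding)")
  }
  stats::setNames(lab, tab[[1L]])
}

#' Write transcript labels as a two-column TSV
#' @param labels Named 0/1 vector (names = transcript ids).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate the longest open reading frame on the forward strand
#'
#' Scans the three forward frames. A complete ORF runs from an \code{ATG} to
#' the first in-frame stop codon; its length includes the stop codon. The
#' longest complete ORF wins, with ties broken by smaller start position, then
#' smaller frame. If no complete ORF exists, the longest incomplete ORF (from
#' an \code{ATG} with no downstream in-frame stop, running to the last full
#' codon) is returned with \code{complete = FALSE}. Transcripts are treated as
#' sense-stranded; the reverse strand is never scanned.
#'
#' @param seq A DNA string over \code{{A,C,G,T,N}}.
#' @return A list with elements \code{start} (0-based inclusive), \code{end}
#'   (0-based exclusive), \code{frame} (0/1/2), \code{complete} (logical) and
#'   \code{nt_length}, or \code{NULL} if the sequence contains no \code{ATG}.
#' @examples
#' find_longest_orf("ATGAAATAG")
#' @export
find_longest_orf <- function(seq) {
  L <- nchar(seq)
  best <- NULL
  best_incomplete <- NULL
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 1L) next
    starts <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stp <- which(codons %in% STOP_CODONS)
    for (a in atg) {
      s_after <- stp[stp >= a]
      if (length(s_after)) {
        cand <- list(start = starts[a] - 1L,
                     end = starts[s_after[1L]] + 2L,
                     frame = frame, complete = TRUE,
                     nt_length = 3L * (s_after[1L] - a + 1L))
        if (orf_better(cand, best)) best <- cand
      } else {
        cand <- list(start = starts[a] - 1L,
                     end = starts[n_cod] + 2L,
                     frame = frame, complete = FALSE,
                     nt_length = 3L * (n_cod - a + 1L))
        if (orf_better(cand, best_incomplete)) best_incomplete <- cand
      }
    }
  }
  if (!is.null(best)) best else best_incomplete
}

# longest nt_length, then leftmost start, then lowest frame
orf_better <- function(cand, incumbent) {
  if (is.null(incumbent)) return(TRUE)
  if (cand$nt_length != incumbent$nt_length)
    return(cand$nt_length > incumbent$nt_length)
  if (cand$start != incumbent$start) return(cand$start < incumbent$start)
  cand$frame < incumbent$frame
}

#' Translate a DNA string with the standard genetic code
#'
#' Translation stops at the first stop codon (the stop itself contributes no
#' residue); codons containing \code{N} or any character outside
#' \code{{A,C,G,T}} translate to \code{X}.
#'
#' @param seq DNA string whose length is a multiple of 3.
#' @return Peptide string (possibly empty).
#' @examples
#' translate("ATGAAATAG")  # "MK"
#' @export
translate <- function(seq) {
  L <- nchar(seq)
  if (L %% 3L != 0L) stop("sequence length must be a multiple of 3")
  if (L == 0L) return("")
  starts <- seq.int(1L, L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# standard code, '*' for stops; lookups of N-containing codons return NA
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})
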