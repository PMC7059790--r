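#' Composition/Transition/Distribution (CTD) nucleotide descriptors
#'
#' The 30 CTD features summarize a transcript at the nucleotide level:
#' 4 composition fractions, 6 transition fractions over unordered adjacent
#' base pairs, and 20 distribution fractions giving the relative positions of
#' the first, 25\%, 50\%, 75\% and last occurrence of each base.
#'
#' @param seq DNA string over \code{{A,C,G,T,N}}.
#' @return \code{ctd_composition}: named fractions \code{(A,T,G,C)};
#'   \code{ctd_transition}: named fractions \code{(AT,AC,AG,TG,TC,GC)};
#'   \code{ctd_distribution}: named fractions \code{A0..A4, T0..T4, G0..G4,
#'   C0..C4}; \code{ctd_features}: all 30 concatenated in that order.
#' @examples
#' ctd_composition("ATACGTACTGCTGACGTAGC")  # 0.25 each
#' ctd_transition("ATACGTACTGCTGACGTAGC")[["AC"]]  # 3/19
#' @name ctd
NULL

CTD_BASES <- c("A", "T", "G", "C")
CTD_PAIRS <- c("AT", "AC", "AG", "TG", "TC", "GC")

#' @rdname ctd
#' @export
ctd_composition <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- vapply(CTD_BASES, function(b) sum(ch == b), numeric(1))
  denom <- sum(counts)
  if (denom == 0) stop("composition undefined: sequence has no A/C/G/T base")
  counts / denom
}

#' @rdname ctd
#' @export
ctd_transition <- function(seq) {
  L <- nchar(seq)
  if (L < 2L) stop("transition needs at least 2 nucleotides")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  a <- ch[-L]
  b <- ch[-1L]
  out <- vapply(CTD_PAIRS, function(p) {
    x <- substr(p, 1L, 1L)
    y <- substr(p, 2L, 2L)
    sum((a == x & b == y) | (a == y & b == x))
  }, numeric(1))
  out / (L - 1)
}

#' @rdname ctd
#' @export
ctd_distribution <- function(seq) {
  L <- nchar(seq)
  if (L < 1L) stop("distribution needs a nonempty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- numeric(20L)
  names(out) <- paste0(rep(CTD_BASES, each = 5L), 0:4)
  for (b in CTD_BASES) {
    pos <- which(ch == b)
    m <- length(pos)
    if (m == 0L) next
    # 0% = first occurrence, 100% = last; the 25/50/75% quantiles take the
    # ceiling(q*m/4)-th occurrence
    idx <- c(1L, pmax(1L, ceiling((1:3) * m / 4)), m)
    out[paste0(b, 0:4)] <- pos[idx] / L
  }
  out
}

#' @rdname ctd
#' @export
ctd_features <- function(seq) {
  comp <- ctd_composition(seq)
  names(comp) <- paste0("comp_", CTD_BASES)
  trans <- ctd_transition(seq)
  names(trans) <- paste0("trans_", CTD_PAIRS)
  c(comp, trans, ctd_distribution(seq))
}
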