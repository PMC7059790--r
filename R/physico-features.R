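#' @name eiip
#' @title EIIP power-spectrum features
#'
#' @description
#' Each nucleotide is replaced by its electron-ion interaction pseudopotential
#' (EIIP) value (A 0.1260, C 0.1340, G 0.0806, T 0.1335; N takes the mean of
#' the four), giving a numeric signal whose discrete-Fourier power spectrum
#' shows a peak near frequency N/3 in protein-coding sequence.
NULL

EIIP_VALUES <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

eiip_series <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  x <- unname(EIIP_VALUES[ch])
  x[is.na(x)] <- mean(EIIP_VALUES)
  x
}

# |DFT|^2 of a numeric series, all N frequency bins (k = 0 .. N-1)
spectrum_of <- function(x) {
  Mod(stats::fft(x))^2
}

#' @rdname eiip
#' @param seq DNA string of length at least 4.
#' @return \code{power_spectrum}: numeric vector \code{S} of length N with
#'   \code{S[k+1]} the squared DFT magnitude at frequency k.
#' @examples
#' power_spectrum("ACGTACGT")
#' @export
power_spectrum <- function(seq) {
  if (nchar(seq) < 4L) stop("power spectrum needs at least 4 nucleotides")
  spectrum_of(eiip_series(seq))
}

#' @rdname eiip
#' @return \code{physico_features}: named vector \code{(signal_peak, snr,
#'   signal_min, signal_q1, signal_q2, signal_max)}. \code{signal_peak} is the
#'   spectral power at the period-3 frequency \code{round(N/3)}; \code{snr}
#'   divides it by the mean power over the non-DC bins; the remaining four are
#'   order statistics of the non-DC bins sorted in descending order (minimum,
#'   the values at the 75\% and 25\% descending-rank positions, maximum), so
#'   \code{signal_min <= signal_q1 <= signal_q2 <= signal_max}. The DC bin
#'   k = 0 is excluded throughout because it only reflects mean EIIP.
#' @export
physico_features <- function(seq) {
  S <- power_spectrum(seq)
  N <- length(S)
  nondc <- S[-1L]
  peak <- S[round(N / 3) + 1L]
  avg <- mean(nondc)
  dsc <- sort(nondc, decreasing = TRUE)
  m <- length(dsc)
  c(signal_peak = peak,
    snr = if (avg > 0) peak / avg else 0,
    signal_min = dsc[m],
    signal_q1 = dsc[ceiling(0.75 * m)],
    signal_q2 = dsc[ceiling(0.25 * m)],
    signal_max = dsc[1L])
}
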