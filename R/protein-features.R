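# Published amino-acid constant sets used by the six protein features.
# Kyte & Doolittle (1982) hydropathy; Guruprasad, Reddy & Pandit (1990)
# dipeptide instability weights (DIWV); ExPASy average residue masses;
# EMBOSS pKa set for the charge model.

KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# average residue masses (Da) = ExPASy amino-acid mass minus one water
RESIDUE_MASS <- c(
  A = 71.0779, C = 103.1429, D = 115.0874, E = 129.1140, F = 147.1738,
  G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576,
  M = 131.1960, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857,
  S = 87.0773, T = 101.1039, V = 99.1311, W = 186.2099, Y = 163.1733)
WATER_MASS <- 18.0153

AA_ORDER <- names(KD_HYDROPATHY)

# Guruprasad et al. (1990) DIWV: rows = first residue of the dipeptide,
# columns = second residue, alphabetical one-letter order
DIWV <- matrix(c(
  1.0, 44.94, -7.49, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 33.6, 1.0, 1.0, 20.26, 33.6, 1.0, 20.26, -6.54, 1.0, 1.0, 33.6, -6.54, 24.68, 1.0,
  1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 20.26, -14.03, 1.0, 1.0, 1.0,
  1.0, 44.94, 20.26, 33.6, 1.0, 1.0, -6.54, 20.26, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 20.26, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, 13.34, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 33.601,
  -7.49, 1.0, 1.0, -6.54, 1.0, 13.34, 1.0, -7.49, -7.49, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 13.34, -7.49,
  1.0, 1.0, 1.0, 1.0, -9.37, -9.37, 1.0, 44.94, 24.68, 1.0, 1.0, 24.68, -1.88, 1.0, 1.0, 1.0, -6.54, 1.0, -1.88, 44.94,
  1.0, 1.0, 1.0, 44.94, 1.0, 1.0, 13.34, 1.0, -7.49, 20.26, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, -7.49, 1.0, -7.49, 33.6, 1.0, -6.54, 24.64, 33.6, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 20.26, 33.6, 20.26, 1.0, 1.0, 1.0, 24.68, 1.0,
  13.34, 1.0, 1.0, 1.0, 1.0, 1.0, 58.28, 1.0, 1.0, 1.0, -1.88, 1.0, 44.94, -6.54, -6.54, 44.94, -1.88, 1.0, 1.0, 24.68,
  1.0, -1.88, 1.0, 1.0, -14.03, -14.03, 1.0, 44.94, 24.68, 1.0, 1.0, 1.0, -1.88, -6.54, 1.0, 1.0, -7.49, 1.0, -9.37, 1.0,
  20.26, -6.54, -6.54, 18.38, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 20.26, 20.26, -6.54, 20.26, 1.0, 20.26, -1.88, 1.0,
  1.0, -6.54, 20.26, 20.26, -6.54, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 44.94, 1.0, -6.54, 1.0, -6.54,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 20.26, 1.0, 1.0, 1.0, 1.0, 13.34, 20.26, 20.26, 58.28, 44.94, 1.0, 1.0, 58.28, -6.54,
  1.0, 33.6, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 44.94, 20.26, 20.26, 20.26, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 1.0, 20.26, 13.34, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, -6.54, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, -14.03, 1.0, 1.0, -7.49, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, -6.54,
  -14.03, 1.0, 1.0, 1.0, 1.0, -9.37, 24.68, 1.0, 1.0, 13.34, 24.68, 13.34, 1.0, 1.0, 1.0, 1.0, -14.03, -7.49, 1.0, 1.0,
  24.68, 1.0, 24.68, -6.54, 1.0, -7.49, 13.34, 1.0, 1.0, 1.0, 44.94, 1.0, 13.34, 1.0, -15.91, 1.0, -7.49, 1.0, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(sort(AA_ORDER), sort(AA_ORDER)))

# EMBOSS pKa values; positive groups gain a proton below their pKa,
# negative groups lose one above it
EMBOSS_PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
EMBOSS_PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Henderson-Hasselbalch net charge of a peptide (counts = named residue
# counts over the 20 standard letters) at a given pH
peptide_charge <- function(counts, ph) {
  n_pos <- c(Nterm = 1, K = counts[["K"]], R = counts[["R"]], H = counts[["H"]])
  n_neg <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]],
             C = counts[["C"]], Y = counts[["Y"]])
  pos <- sum(n_pos / (1 + 10^(ph - EMBOSS_PKA_POS)))
  neg <- sum(n_neg / (1 + 10^(EMBOSS_PKA_NEG - ph)))
  pos - neg
}

# isoelectric point by bisection on the monotone charge-vs-pH curve
peptide_pi <- function(counts, tol = 1e-6) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties of the peptide encoded by the longest ORF
#'
#' Translates the longest ORF (stop codon dropped) and computes six standard
#' protein-level descriptors. Unknown residues (\code{X}, from N-containing
#' codons) are excluded from every sum and from the residue count. Transcripts
#' without an ORF, or whose peptide is empty, return all zeros.
#'
#' @param seq DNA string.
#' @return Named vector \code{(instability, gravy, isoelectric_point,
#'   mol_weight, aromaticity, charge_ph7)}: Guruprasad instability index,
#'   mean Kyte-Doolittle hydropathy, pH of zero net charge (EMBOSS pKa set,
#'   bisection to 1e-6 pH), molecular weight in Da (average masses plus one
#'   water), fraction of F/W/Y residues, and net charge at pH 7.
#' @export
protein_features <- function(seq) {
  zero <- c(instability = 0, gravy = 0, isoelectric_point = 0,
            mol_weight = 0, aromaticity = 0, charge_ph7 = 0)
  orf <- find_longest_orf(seq)
  if (is.null(orf)) return(zero)
  pep <- translate(substr(seq, orf$start + 1L, orf$end))
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  aa <- aa[aa %in% AA_ORDER]
  n <- length(aa)
  if (n == 0L) return(zero)
  counts <- vapply(AA_ORDER, function(a) sum(aa == a), numeric(1))
  instability <- if (n >= 2L) {
    10 / n * sum(DIWV[cbind(aa[-n], aa[-1L])])
  } else 0
  c(instability = instability,
    gravy = sum(counts * KD_HYDROPATHY) / n,
    isoelectric_point = peptide_pi(counts),
    mol_weight = sum(counts * RESIDUE_MASS) + WATER_MASS,
    aromaticity = sum(counts[c("F", "W", "Y")]) / n,
    charge_ph7 = peptide_charge(counts, 7))
}
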