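#' ORF statistics of a transcript
#'
#' @param seq DNA string.
#' @return Named vector \code{(orf_length, orf_coverage, orf_integrity)}:
#'   length in nt of the longest ORF (0 if none; the stop codon counts toward
#'   the length of a complete ORF), its fraction of the transcript length, and
#'   1 if that ORF is complete (ATG start and in-frame stop), else 0.
#' @export
orf_stats <- function(seq) {
  orf <- find_longest_orf(seq)
  if (is.null(orf)) {
    return(c(orf_length = 0, orf_coverage = 0, orf_integrity = 0))
  }
  c(orf_length = orf$nt_length,
    orf_coverage = orf$nt_length / nchar(seq),
    orf_integrity = as.numeric(orf$complete))
}

# ---- Fickett TESTCODE -------------------------------------------------------
# Lookup tables from Fickett (1982) Nucleic Acids Res 10:5303-5318, as
# redistributed in the CPAT coding-potential tool. Rows are the probability
# of coding for the parameter falling in each interval; intervals are read
# downward from the first threshold the parameter reaches.

FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0)
FICKETT_POSITION_PROB <- rbind(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_CONTENT_PROB <- rbind(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

#' Fickett TESTCODE score
#'
#' Combines, for each base, a positional-asymmetry parameter (the ratio of the
#' maximal to minimal count over the three frame positions, the minimum
#' floored at 1) and a content parameter (base fraction), each converted to a
#' probability of coding by the published lookup tables and summed with the
#' published weights.
#'
#' @param seq DNA string of length at least 4.
#' @return The TESTCODE score (higher = more coding-like).
#' @export
fickett_score <- function(seq) {
  L <- nchar(seq)
  if (L < 4L) stop("Fickett score needs at least 4 nucleotides")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  phase <- (seq_len(L) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(ch == b & phase == p), numeric(1))
    pos_par <- max(cnt) / (min(cnt) + 1)
    con_par <- sum(cnt) / L
    pos_i <- which(pos_par >= FICKETT_POSITION_PARA)[1L]
    con_i <- which(con_par >= FICKETT_CONTENT_PARA)[1L]
    score <- score +
      FICKETT_POSITION_PROB[b, pos_i] * FICKETT_POSITION_WEIGHT[[b]] +
      FICKETT_CONTENT_PROB[b, con_i] * FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

# ---- hexamer usage ----------------------------------------------------------

KMER_K <- 6L
N_KMERS <- 4L^KMER_K

# k-mer counts of each sequence (rows), optionally in-frame (step = 3),
# optionally cyclic (sequence treated as circular so counts are exactly
# proportional under duplication). Windows containing N are not counted.
kmer_counts <- function(seqs, step = 1L, cyclic = FALSE) {
  if (cyclic) {
    seqs <- paste0(seqs, substr(seqs, 1L, KMER_K - 1L))
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::oligonucleotideFrequency(set, width = KMER_K, step = step)
}

#' Train a hexamer log-ratio table
#'
#' In-frame (step-3) hexamer counts are accumulated over the longest ORF of
#' every coding sequence, and sliding (step-1) counts over every noncoding
#' sequence in full. The weight of hexamer \eqn{h} is the difference of
#' add-pseudocount log-frequencies,
#' \eqn{\log\frac{c_h + p}{\sum c + 4096p} - \log\frac{n_h + p}{\sum n + 4096p}}.
#'
#' @param coding,noncoding Character vectors of DNA sequences.
#' @param pseudocount Positive smoothing constant (default 1, add-one).
#' @return Named numeric vector of 4096 hexamer weights, with attributes
#'   recording the pseudocount and the training-set sizes.
#' @export
train_hexamer_table <- function(coding, noncoding, pseudocount = 1) {
  if (!length(coding) || !length(noncoding)) {
    stop("both coding and noncoding training sets must be nonempty")
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  orfs <- vapply(coding, function(s) {
    orf <- find_longest_orf(s)
    if (is.null(orf)) "" else substr(s, orf$start + 1L, orf$end)
  }, character(1), USE.NAMES = FALSE)
  c_counts <- colSums(kmer_counts(orfs, step = 3L))
  n_counts <- colSums(kmer_counts(noncoding, step = 1L))
  w <- (log(c_counts + pseudocount) - log(sum(c_counts) + N_KMERS * pseudocount)) -
       (log(n_counts + pseudocount) - log(sum(n_counts) + N_KMERS * pseudocount))
  attr(w, "pseudocount") <- pseudocount
  attr(w, "n_coding") <- length(coding)
  attr(w, "n_noncoding") <- length(noncoding)
  w
}

#' Hexamer score of a transcript
#'
#' Mean table weight over the in-frame hexamers of the longest ORF; if the
#' transcript has no ORF, the mean over all sliding hexamers of the whole
#' sequence. Sequences (or ORFs) providing no hexamer window score 0.
#'
#' @param seq DNA string.
#' @param table Hexamer weight table from [train_hexamer_table()].
#' @return Mean log-ratio weight (higher = more coding-like).
#' @export
hexamer_score <- function(seq, table) {
  orf <- find_longest_orf(seq)
  if (!is.null(orf)) {
    sub <- substr(seq, orf$start + 1L, orf$end)
    counts <- kmer_counts(sub, step = 3L)[1L, ]
  } else {
    if (nchar(seq) < KMER_K) return(0)
    counts <- kmer_counts(seq, step = 1L)[1L, ]
  }
  tot <- sum(counts)
  if (tot == 0) return(0)
  sum(counts * table) / tot
}

# ---- GC and codon statistics ------------------------------------------------

#' GC content and per-codon-position GC variance
#'
#' @param seq DNA string.
#' @return \code{gc_content}: (G+C)/(A+C+G+T) over the whole transcript
#'   (N excluded); \code{gc_variance}: population variance of the GC fraction
#'   at the three codon positions of the longest ORF (0 if no ORF).
#' @export
gc_stats <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  acgt <- ch %in% c("A", "C", "G", "T")
  if (!any(acgt)) stop("GC content undefined: sequence has no A/C/G/T base")
  gc_content <- sum(ch %in% c("G", "C")) / sum(acgt)
  orf <- find_longest_orf(seq)
  gc_variance <- 0
  if (!is.null(orf)) {
    oc <- ch[(orf$start + 1L):orf$end]
    pos <- (seq_along(oc) - 1L) %% 3L
    fr <- vapply(0:2, function(p) {
      at <- oc[pos == p]
      ok <- at %in% c("A", "C", "G", "T")
      if (!any(ok)) return(0)
      sum(at %in% c("G", "C")) / sum(ok)
    }, numeric(1))
    gc_variance <- mean((fr - mean(fr))^2)
  }
  c(gc_content = gc_content, gc_variance = gc_variance)
}

#' Codon count of the longest ORF and its ratio to transcript capacity
#'
#' @param seq DNA string.
#' @return \code{codon_number} = ORF length / 3 (0 if no ORF);
#'   \code{codon_ratio} = codon_number / floor(transcript length / 3).
#' @export
codon_stats <- function(seq) {
  orf <- find_longest_orf(seq)
  n_cod <- if (is.null(orf)) 0 else orf$nt_length / 3
  cap <- nchar(seq) %/% 3L
  c(codon_number = n_cod,
    codon_ratio = if (cap > 0) n_cod / cap else 0)
}

# ---- k-mer distance features ------------------------------------------------

# counts of each base (cols A,C,G,T) within each of the 4096 hexamers,
# in the Biostrings column order
kmer_base_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      kn <- colnames(kmer_counts(strrep("A", KMER_K)))
      m <<- vapply(c("A", "C", "G", "T"), function(b) {
        nchar(kn) - nchar(gsub(b, "", kn, fixed = TRUE))
      }, numeric(length(kn)))
    }
    m
  }
})

# per-sequence k-mer log-ratio profiles (rows): log of the cyclic k-mer
# frequency over the frequency expected from the mononucleotide composition,
# both offset by eps = 4^-k so the log is finite and the profile is exactly
# invariant under sequence duplication
kmer_profiles <- function(seqs) {
  counts <- kmer_counts(seqs, step = 1L, cyclic = TRUE)
  tot <- pmax(rowSums(counts), 1)
  f <- counts / tot
  comp <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                      c("A", "C", "G", "T"))
  comp <- comp / pmax(rowSums(comp), 1)
  loge <- log(pmax(comp, 1e-12)) %*% t(kmer_base_matrix())
  eps <- 4^(-KMER_K)
  log(f + eps) - log(exp(loge) + eps)
}

#' Train class centroid k-mer profiles
#'
#' Each sequence is mapped to a 4096-dimensional hexamer log-ratio profile
#' (observed cyclic hexamer frequency over the frequency expected from its
#' own mononucleotide composition, log scale); the class centroid is the
#' elementwise mean profile.
#'
#' @param coding,noncoding Character vectors of DNA sequences.
#' @return List with components \code{pc} and \code{nc} (centroid profiles of
#'   the coding and noncoding classes) and \code{k} (the k-mer size, 6).
#' @export
train_reference_profiles <- function(coding, noncoding) {
  if (!length(coding) || !length(noncoding)) {
    stop("both coding and noncoding training sets must be nonempty")
  }
  list(pc = colMeans(kmer_profiles(coding)),
       nc = colMeans(kmer_profiles(noncoding)),
       k = KMER_K)
}

#' Euclidean distance features to the class centroids
#'
#' @param seq DNA string.
#' @param refs Reference profiles from [train_reference_profiles()].
#' @return Named vector \code{(dist_pc, dist_nc, dist_ratio, logdist_pc,
#'   logdist_nc, logdist_ratio)}: Euclidean distances from the transcript's
#'   hexamer log-ratio profile to the coding and noncoding centroids, the
#'   noncoding/coding distance ratio, and the same three on log1p-transformed
#'   distances. Ratios are 1 when both distances are below 1e-12.
#' @export
distance_features <- function(seq, refs) {
  p <- kmer_profiles(seq)[1L, ]
  d_pc <- sqrt(sum((p - refs$pc)^2))
  d_nc <- sqrt(sum((p - refs$nc)^2))
  c(dist_pc = d_pc, dist_nc = d_nc,
    dist_ratio = guarded_ratio(d_nc, d_pc),
    logdist_pc = log1p(d_pc), logdist_nc = log1p(d_nc),
    logdist_ratio = guarded_ratio(log1p(d_nc), log1p(d_pc)))
}

guarded_ratio <- function(num, den, eps = 1e-12) {
  if (num < eps && den < eps) return(1)
  num / max(den, eps)
}
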