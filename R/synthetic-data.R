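#' Configuration of the synthetic transcript generator
#'
#' The generator emulates the two transcript classes the classifier is built
#' for. Coding transcripts are a 5' UTR, an ATG, codons drawn from a biased
#' codon-usage table (stop codons excluded internally), a stop codon and a
#' 3' UTR, giving long complete ORFs and period-3 composition structure.
#' Noncoding transcripts are order-2 Markov sequences matched to a GC target,
#' with no ORF constraint. \code{codon_bias_strength} tempers the codon-usage
#' table geometrically between uniform (0) and increasingly skewed usage; at
#' strength 0 the two classes are drawn from one identical process (a
#' no-signal null), so any class signal is controlled by this single knob.
#'
#' @param n_coding,n_noncoding Number of transcripts per class.
#' @param length_range Transcript length bounds in nt (noncoding class, and
#'   upper bound for coding transcripts); lower bound at least 60.
#' @param orf_codon_range Range of coding-ORF lengths in codons (ATG and stop
#'   excluded from the count).
#' @param short_orf Cap coding ORFs at 100 codons (longest ORF at most
#'   303 nt), emulating the hard short-ORF stratum.
#' @param codon_bias_strength Nonnegative tempering exponent of the
#'   codon-usage table; 0 = no signal.
#' @param gc_target GC fraction of the noncoding background.
#' @param utr_range Total UTR length range (nt) of coding transcripts.
#' @param seed Integer seed; generation is a pure function of this
#'   configuration.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_coding = 500L, n_noncoding = 500L,
                         length_range = c(200L, 3000L),
                         orf_codon_range = c(40L, 500L),
                         short_orf = FALSE,
                         codon_bias_strength = 1,
                         gc_target = 0.5,
                         utr_range = c(50L, 300L),
                         seed = 1L) {
  cfg <- list(n_coding = as.integer(n_coding),
              n_noncoding = as.integer(n_noncoding),
              length_range = as.integer(length_range),
              orf_codon_range = as.integer(orf_codon_range),
              short_orf = isTRUE(short_orf),
              codon_bias_strength = codon_bias_strength,
              gc_target = gc_target,
              utr_range = as.integer(utr_range),
              seed = as.integer(seed))
  if (cfg$n_coding < 1L || cfg$n_noncoding < 1L) stop("counts must be >= 1")
  if (cfg$length_range[1L] < 60L) stop("minimum length must be >= 60 nt")
  if (cfg$codon_bias_strength < 0) stop("codon_bias_strength must be >= 0")
  if (cfg$short_orf) {
    cfg$orf_codon_range <- pmin(cfg$orf_codon_range, 100L)
  }
  if (3L * (max(cfg$orf_codon_range) + 2L) + cfg$utr_range[1L] >
      cfg$length_range[2L]) {
    stop("infeasible: longest requested ORF plus minimal UTR exceeds the ",
         "transcript length bound")
  }
  class(cfg) <- "synth_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

SENSE_CODONS <- local({
  all3 <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                          paste0))
  sort(setdiff(all3, c("TAA", "TAG", "TGA")))
})

# order-2 Markov sampler: one row of B per sequence, vectorized across
# sequences position-by-position
markov_sample <- function(lengths, trans_cum, init_p) {
  n <- length(lengths)
  maxL <- max(lengths)
  B <- matrix(0L, n, maxL)
  B[, 1L] <- sample.int(4L, n, replace = TRUE, prob = init_p)
  if (maxL >= 2L) B[, 2L] <- sample.int(4L, n, replace = TRUE, prob = init_p)
  if (maxL >= 3L) {
    for (t in 3:maxL) {
      act <- which(lengths >= t)
      if (!length(act)) next
      ctx <- (B[act, t - 2L] - 1L) * 4L + B[act, t - 1L]
      u <- stats::runif(length(act))
      B[act, t] <- 1L + (u > trans_cum[ctx, 1L]) + (u > trans_cum[ctx, 2L]) +
        (u > trans_cum[ctx, 3L])
    }
  }
  vapply(seq_len(n), function(i) {
    paste(BASES[B[i, seq_len(lengths[i])]], collapse = "")
  }, character(1))
}

# random order-2 transition table (cumulative rows) whose rows scatter mildly
# around the target base composition
markov_tables <- function(gc_target) {
  base_p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
              (1 - gc_target) / 2)
  alpha <- 20 * base_p
  rows <- t(vapply(seq_len(16L), function(i) {
    g <- stats::rgamma(4L, shape = alpha)
    g / sum(g)
  }, numeric(4)))
  list(cum = t(apply(rows, 1L, cumsum)), init = base_p)
}

rand_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

#' Generate labelled synthetic transcripts
#'
#' Byte-identical output for identical configurations. Coding transcripts are
#' rejection-sampled so that the constructed reading frame really is the
#' longest ORF of the transcript (a chance ORF in the UTRs could otherwise
#' overtake it).
#'
#' @param config A [synth_config()] object.
#' @param fasta,labels Optional output paths; when given, the records and
#'   their 0/1 labels are also written as FASTA and two-column TSV.
#' @return Data frame with columns \code{id}, \code{sequence} and
#'   \code{label} (1 = coding), coding records first.
#' @export
generate_transcripts <- function(config = synth_config(), fasta = NULL,
                                 labels = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  mk <- markov_tables(config$gc_target)
  # codon-usage table: symmetric Dirichlet draw tempered by the bias strength
  u <- stats::rgamma(length(SENSE_CODONS), shape = 2)
  u <- u / sum(u)
  usage <- u^config$codon_bias_strength
  usage <- usage / sum(usage)

  null_mode <- config$codon_bias_strength == 0
  coding <- make_coding(config$n_coding, config, usage, mk)
  noncoding <- if (null_mode) {
    # no-signal control: the noncoding class follows the identical
    # scaffolded process, so the two classes are exchangeable
    make_coding(config$n_noncoding, config, usage, mk)
  } else {
    lens <- rand_int(config$n_noncoding, config$length_range[1L],
                     config$length_range[2L])
    markov_sample(lens, mk$cum, mk$init)
  }
  out <- data.frame(
    id = c(sprintf("pc_%04d", seq_len(config$n_coding)),
           sprintf("nc_%04d", seq_len(config$n_noncoding))),
    sequence = c(coding, noncoding),
    label = rep(c(1L, 0L), c(config$n_coding, config$n_noncoding)),
    stringsAsFactors = FALSE)
  if (!is.null(fasta)) write_fasta(out, fasta)
  if (!is.null(labels)) write_labels(stats::setNames(out$label, out$id),
                                     labels)
  out
}

make_coding <- function(n, config, usage, mk) {
  vapply(seq_len(n), function(i) {
    for (attempt in 1:100) {
      n_cod <- rand_int(1L, config$orf_codon_range[1L],
                        config$orf_codon_range[2L])
      orf <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_cod, replace = TRUE,
                                 prob = usage), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      orf_nt <- nchar(orf)
      utr_max <- min(config$utr_range[2L],
                     config$length_range[2L] - orf_nt)
      utr_tot <- rand_int(1L, min(config$utr_range[1L], utr_max), utr_max)
      utr5 <- rand_int(1L, 0L, utr_tot)
      parts <- markov_sample(pmax(c(utr5, utr_tot - utr5), 1L),
                             mk$cum, mk$init)
      seq <- paste0(if (utr5 > 0L) parts[1L] else "", orf,
                    if (utr_tot - utr5 > 0L) parts[2L] else "")
      found <- find_longest_orf(seq)
      utr5_real <- if (utr5 > 0L) nchar(parts[1L]) else 0L
      if (!is.null(found) && found$complete &&
          found$start == utr5_real && found$nt_length == orf_nt) {
        return(seq)
      }
    }
    stop("could not place a dominant ORF after 100 attempts; ",
         "widen the length bounds")
  }, character(1))
}
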