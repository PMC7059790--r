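# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and literal formulas only.

random_dna <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# exhaustive ATG -> first in-frame stop enumeration over the 3 forward frames
oracle_longest_orf <- function(seq) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  best_inc <- NULL
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$nt_length != b$nt_length) return(a$nt_length > b$nt_length)
    if (a$start != b$start) return(a$start < b$start)
    a$frame < b$frame
  }
  for (i in seq_len(L - 2)) {
    if (paste(ch[i:(i + 2)], collapse = "") != "ATG") next
    frame <- (i - 1) %% 3
    j <- i + 3
    hit <- FALSE
    while (j + 2 <= L) {
      cod <- paste(ch[j:(j + 2)], collapse = "")
      if (cod %in% stops) {
        cand <- list(start = i - 1, end = j + 2, frame = frame,
                     complete = TRUE, nt_length = j + 2 - (i - 1))
        if (better(cand, best)) best <- cand
        hit <- TRUE
        break
      }
      j <- j + 3
    }
    if (!hit) {
      end <- i - 1 + 3 * ((L - (i - 1)) %/% 3)
      cand <- list(start = i - 1, end = end, frame = frame,
                   complete = FALSE, nt_length = end - (i - 1))
      if (better(cand, best_inc)) best_inc <- cand
    }
  }
  if (!is.null(best)) best else best_inc
}

# plain counting CTD oracle
oracle_ctd <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  bases <- c("A", "T", "G", "C")
  comp <- sapply(bases, function(b) sum(ch == b)) / sum(ch %in% bases)
  pairs <- list(AT = c("A", "T"), AC = c("A", "C"), AG = c("A", "G"),
                TG = c("T", "G"), TC = c("T", "C"), GC = c("G", "C"))
  trans <- sapply(pairs, function(p) {
    k <- 0
    for (i in 1:(L - 1)) {
      if ((ch[i] == p[1] && ch[i + 1] == p[2]) ||
          (ch[i] == p[2] && ch[i + 1] == p[1])) k <- k + 1
    }
    k
  }) / (L - 1)
  distr <- c()
  for (b in bases) {
    pos <- which(ch == b)
    m <- length(pos)
    vals <- if (m == 0) rep(0, 5) else {
      c(pos[1], pos[max(1, ceiling(m / 4))], pos[max(1, ceiling(m / 2))],
        pos[max(1, ceiling(3 * m / 4))], pos[m]) / L
    }
    names(vals) <- paste0(b, 0:4)
    distr <- c(distr, vals)
  }
  list(comp = comp, trans = trans, distr = distr)
}

# literal O(N^2) discrete Fourier transform magnitude squared
oracle_power_spectrum <- function(x) {
  N <- length(x)
  S <- numeric(N)
  for (k in 0:(N - 1)) {
    re <- 0
    im <- 0
    for (n in 0:(N - 1)) {
      re <- re + x[n + 1] * cos(-2 * pi * k * n / N)
      im <- im + x[n + 1] * sin(-2 * pi * k * n / N)
    }
    S[k + 1] <- re^2 + im^2
  }
  S
}

oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# AUC by exhaustive positive/negative pair comparison, ties count one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# trapezoidal area under an ROC polygon given (fpr, tpr) points
trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# small labelled synthetic set shared by model-level tests
tiny_synth <- function(n = 40, seed = 11) {
  generate_transcripts(synth_config(n_coding = n, n_noncoding = n,
                                    length_range = c(150L, 800L),
                                    orf_codon_range = c(30L, 120L),
                                    seed = seed))
}

tiny_config <- function(max_epochs = 10L, ...) {
  corenet_config(Dt = 2L, Nr = 2L, Nc = 24L, Pd = 0.2,
                 pred_widths = c(16L, 12L, 8L), batch_size = 32L,
                 max_epochs = max_epochs, patience = 5L, seed = 7L, ...)
}
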