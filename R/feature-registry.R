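#' @name feature_registry
#' @title The canonical 57-feature registry
#'
#' @description
#' Every transcript is mapped to the same ordered, named vector of 57
#' features: 15 sequence-category features (ORF statistics, Fickett score,
#' hexamer score, GC statistics, codon statistics, k-mer distance features),
#' 30 CTD features, 6 protein features and 6 EIIP power-spectrum features.
#' The order and names are fixed by \code{feature_names()} and versioned;
#' models refuse to score feature tables from a different registry version.
NULL

REGISTRY_VERSION <- "1.0"

#' @rdname feature_registry
#' @return \code{feature_names}: character vector of the 57 feature names in
#'   canonical order.
#' @export
feature_names <- function() {
  c("orf_length", "orf_coverage", "orf_integrity", "fickett", "hexamer",
    "gc_content", "gc_variance", "codon_number", "codon_ratio",
    "dist_pc", "dist_nc", "dist_ratio",
    "logdist_pc", "logdist_nc", "logdist_ratio",
    paste0("comp_", CTD_BASES), paste0("trans_", CTD_PAIRS),
    paste0(rep(CTD_BASES, each = 5L), 0:4),
    "instability", "gravy", "isoelectric_point", "mol_weight",
    "aromaticity", "charge_ph7",
    "signal_peak", "snr", "signal_min", "signal_q1", "signal_q2",
    "signal_max")
}

#' Train the reference tables used by the feature extractor
#'
#' Fits the hexamer log-ratio table and the class centroid k-mer profiles on
#' a labelled training set. These are data-derived artifacts and must be
#' trained on training sequences only.
#'
#' @param coding,noncoding Character vectors of DNA sequences.
#' @param pseudocount Smoothing constant for the hexamer table.
#' @return An object of class \code{corenet_tables}.
#' @export
train_tables <- function(coding, noncoding, pseudocount = 1) {
  structure(
    list(hexamer = train_hexamer_table(coding, noncoding, pseudocount),
         profiles = train_reference_profiles(coding, noncoding),
         n_coding = length(coding), n_noncoding = length(noncoding),
         registry_version = REGISTRY_VERSION),
    class = "corenet_tables")
}

#' @export
print.corenet_tables <- function(x, ...) {
  cat("corenet reference tables (registry v", x$registry_version, ")\n",
      sep = "")
  cat("  hexamer table: 4096 weights, trained on", x$n_coding, "coding /",
      x$n_noncoding, "noncoding sequences\n")
  cat("  k-mer centroid profiles: k =", x$profiles$k, "\n")
  invisible(x)
}

#' Extract the 57-feature vector of one transcript
#'
#' @param seq DNA string over \code{{A,C,G,T,N}}.
#' @param tables Trained reference tables from [train_tables()].
#' @return Named numeric vector of 57 features in registry order.
#' @export
extract_features <- function(seq, tables) {
  stopifnot(inherits(tables, "corenet_tables"))
  v <- c(orf_stats(seq),
         fickett = fickett_score(seq),
         hexamer = hexamer_score(seq, tables$hexamer),
         gc_stats(seq),
         codon_stats(seq),
         distance_features(seq, tables$profiles),
         ctd_features(seq),
         protein_features(seq),
         physico_features(seq))
  v[feature_names()]
}

#' Extract features for a set of transcripts
#'
#' @param records Data frame with columns \code{id} and \code{sequence}
#'   (as from [read_fasta()]).
#' @param tables Trained reference tables.
#' @return Numeric matrix, one row per record (rownames = ids), 57 named
#'   columns in registry order.
#' @export
feature_matrix <- function(records, tables) {
  out <- matrix(NA_real_, nrow(records), length(feature_names()),
                dimnames = list(records$id, feature_names()))
  for (i in seq_len(nrow(records))) {
    out[i, ] <- tryCatch(
      extract_features(records$sequence[i], tables),
      error = function(e) {
        stop("feature extraction failed for record '", records$id[i],
             "': ", conditionMessage(e), call. = FALSE)
      })
  }
  out
}

#' Write a feature table as TSV
#' @param X Feature matrix from [feature_matrix()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return Feature matrix with ids as rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  X
}

#' Serialize reference tables as TSV
#'
#' One row per hexamer with the trained log-ratio weight and the two centroid
#' profile values, preceded by \code{# provenance} comment lines.
#'
#' @param tables A \code{corenet_tables} object.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_tables <- function(tables, path) {
  stopifnot(inherits(tables, "corenet_tables"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# provenance: corenet reference tables, registry v",
           tables$registry_version),
    paste0("# trained on ", tables$n_coding, " coding / ",
           tables$n_noncoding, " noncoding sequences; k = ",
           tables$profiles$k, "; pseudocount = ",
           attr(tables$hexamer, "pseudocount"))), con)
  df <- data.frame(kmer = names(tables$hexamer),
                   hexamer_weight = as.numeric(tables$hexamer),
                   profile_pc = as.numeric(tables$profiles$pc),
                   profile_nc = as.numeric(tables$profiles$nc))
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reference tables written by [write_tables()]
#' @param path TSV path.
#' @return A \code{corenet_tables} object.
#' @export
read_tables <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) != N_KMERS) stop("malformed table file: expected ", N_KMERS,
                                " k-mer rows, found ", nrow(df))
  hx <- stats::setNames(df$hexamer_weight, df$kmer)
  structure(
    list(hexamer = hx,
         profiles = list(pc = stats::setNames(df$profile_pc, df$kmer),
                         nc = stats::setNames(df$profile_nc, df$kmer),
                         k = KMER_K),
         n_coding = NA_integer_, n_noncoding = NA_integer_,
         registry_version = REGISTRY_VERSION),
    class = "corenet_tables")
}

# ---- feature scaling --------------------------------------------------------

#' Fit a per-feature z-score scaler
#'
#' @param X Numeric feature matrix (training rows only).
#' @return List with \code{mean} and \code{sd} per column (sd floored at
#'   1e-8 so constant columns scale to zero), class \code{corenet_scaler}.
#' @export
fit_scaler <- function(X) {
  if (!nrow(X)) stop("cannot fit a scaler on an empty feature table")
  structure(list(mean = colMeans(X),
                 sd = pmax(apply(X, 2L, stats::sd), 1e-8)),
            class = "corenet_scaler")
}

#' Apply (or invert) a fitted scaler
#' @param X Feature matrix.
#' @param scaler From [fit_scaler()].
#' @param inverse Undo the scaling instead.
#' @return Scaled (or unscaled) matrix.
#' @export
apply_scaler <- function(X, scaler, inverse = FALSE) {
  stopifnot(inherits(scaler, "corenet_scaler"))
  if (inverse) {
    sweep(sweep(X, 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
  } else {
    sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
  }
}
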