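#' Fit a coding-potential classifier to labelled transcripts
#'
#' Trains the full pipeline on labelled transcripts: the hexamer table and
#' k-mer centroid profiles are learned from the training sequences, the
#' 57-feature matrix is extracted and z-scored, and the residual
#' fully-connected network is trained with binary cross-entropy. Coding
#' transcripts are the positive class internally; reported probabilities are
#' for the noncoding class, matching the tool's purpose.
#'
#' @param x Training transcripts: a data frame with columns \code{id} and
#'   \code{sequence} (as from [read_fasta()]) or a path to a FASTA file.
#' @param labels 0/1 labels (1 = coding): an unnamed vector aligned with the
#'   rows of \code{x}, a named vector keyed by transcript id, or a path to a
#'   two-column \code{id<TAB>label} TSV.
#' @param config Hyperparameters from [corenet_config()].
#' @param pseudocount Smoothing constant for the hexamer table.
#' @return An object of class \code{corenet} with \code{print}, \code{summary},
#'   \code{predict}, \code{coef}, \code{fitted}, \code{residuals} and
#'   \code{plot} methods.
#' @examples
#' \donttest{
#' syn <- generate_transcripts(synth_config(n_coding = 60, n_noncoding = 60,
#'                                          seed = 1))
#' cfg <- corenet_config(Dt = 2, Nc = 32, max_epochs = 5, batch_size = 32)
#' fit <- corenet(syn, labels = syn$label, config = cfg)
#' predict(fit, syn[1:3, ])
#' }
#' @export
corenet <- function(x, labels, config = corenet_config(), pseudocount = 1) {
  records <- as_records(x)
  labels <- align_labels(labels, records)
  if (length(unique(labels)) < 2L) {
    stop("training requires both coding and noncoding transcripts")
  }
  tables <- train_tables(records$sequence[labels == 1L],
                         records$sequence[labels == 0L],
                         pseudocount = pseudocount)
  X <- feature_matrix(records, tables)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  tr <- net_train(Xs, labels, config)
  p_coding <- net_predict(tr$net, Xs, config)
  obj <- structure(
    list(config = config, net = tr$net, scaler = scaler, tables = tables,
         history = tr$history, best_epoch = tr$best_epoch,
         registry_version = REGISTRY_VERSION,
         feature_names = feature_names(),
         fitted_p_noncoding = stats::setNames(1 - p_coding, records$id),
         labels = stats::setNames(labels, records$id),
         n_train = nrow(records), call = match.call()),
    class = "corenet")
  obj
}

as_records <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_fasta(x))
  if (is.data.frame(x) && all(c("id", "sequence") %in% names(x))) {
    if (anyDuplicated(x$id)) stop("transcript ids must be unique")
    return(x[, c("id", "sequence")])
  }
  stop("transcripts must be a FASTA path or a data frame with ",
       "columns 'id' and 'sequence'")
}

align_labels <- function(labels, records) {
  if (is.character(labels) && length(labels) == 1L) {
    labels <- read_labels(labels)
  }
  if (!is.null(names(labels)) && any(nzchar(names(labels)))) {
    miss <- setdiff(records$id, names(labels))
    if (length(miss)) stop("no label for transcript(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    labels <- labels[records$id]
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(records)) {
    stop("need one label per transcript")
  }
  if (any(is.na(labels)) || any(!labels %in% c(0L, 1L))) {
    stop("labels must be 0 (noncoding) or 1 (coding)")
  }
  labels
}

#' Predict coding potential for new transcripts
#'
#' @param object A fitted \code{corenet} model.
#' @param newdata A FASTA path, a data frame with \code{id} and
#'   \code{sequence}, or a raw (unscaled) feature matrix with the model's 57
#'   registry columns.
#' @param type \code{"response"} returns a data frame of ids, noncoding
#'   probabilities and hard labels; \code{"prob"} just the named probability
#'   vector.
#' @param ... Unused.
#' @return See \code{type}. The hard label is \code{"noncoding"} when
#'   \code{p_noncoding >= 0.5}, else \code{"coding"}.
#' @export
predict.corenet <- function(object, newdata,
                            type = c("response", "prob"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) {
    if (!identical(colnames(newdata), object$feature_names)) {
      stop("feature table does not match the model's registry (v",
           object$registry_version, "); re-extract features with this ",
           "package version")
    }
    X <- newdata
  } else {
    records <- as_records(newdata)
    X <- feature_matrix(records, object$tables)
  }
  Xs <- apply_scaler(X, object$scaler)
  p_nc <- 1 - net_predict(object$net, Xs, object$config)
  names(p_nc) <- rownames(X)
  if (type == "prob") return(p_nc)
  data.frame(id = rownames(X), p_noncoding = unname(p_nc),
             label = ifelse(p_nc >= 0.5, "noncoding", "coding"),
             stringsAsFactors = FALSE)
}

#' @export
print.corenet <- function(x, ...) {
  cat("corenet coding-potential classifier\n")
  cat(sprintf("  trained on %d transcripts (%d coding, %d noncoding)\n",
              x$n_train, sum(x$labels == 1L), sum(x$labels == 0L)))
  cat(sprintf("  Dt = %d, Nr = %d, Nc = %d, Pd = %.2f; best epoch %d\n",
              x$config$Dt, x$config$Nr, x$config$Nc, x$config$Pd,
              x$best_epoch))
  cat(sprintf("  registry v%s (%d features)\n", x$registry_version,
              length(x$feature_names)))
  invisible(x)
}

#' @method summary corenet
#' @export
summary.corenet <- function(object, ...) {
  p_nc <- object$fitted_p_noncoding
  pred_coding <- p_nc < 0.5
  acc <- mean(pred_coding == (object$labels == 1L))
  out <- list(config = object$config, n_train = object$n_train,
              best_epoch = object$best_epoch,
              history_tail = utils::tail(object$history, 3L),
              train_accuracy = acc)
  class(out) <- "summary.corenet"
  out
}

#' @export
print.summary.corenet <- function(x, ...) {
  print(x$config)
  cat(sprintf("training transcripts: %d; apparent accuracy %.4f\n",
              x$n_train, x$train_accuracy))
  cat("last epochs:\n")
  print(x$history_tail, row.names = FALSE)
  invisible(x)
}

#' @method coef corenet
#' @export
coef.corenet <- function(object, ...) {
  object$net$P
}

#' @export
fitted.corenet <- function(object, ...) {
  object$fitted_p_noncoding
}

#' @method residuals corenet
#' @export
residuals.corenet <- function(object, ...) {
  # response residuals for the coding class: y - P(coding)
  object$labels - (1 - object$fitted_p_noncoding)
}

#' Plot training history of a fitted model
#' @param x A \code{corenet} model.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, \code{x}.
#' @method plot corenet
#' @export
plot.corenet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Save or load a fitted model checkpoint
#'
#' The checkpoint is a single file embedding the configuration, network
#' weights and normalization statistics, feature scaler, reference tables,
#' registry version and training history, so predictions from a reloaded
#' model are bit-identical.
#'
#' @param model A \code{corenet} object.
#' @param path Checkpoint file path.
#' @return \code{save_model}: invisibly, \code{path}; \code{load_model}: the
#'   restored \code{corenet} object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "corenet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  force(path)
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model checkpoint '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!inherits(model, "corenet")) {
    stop("file is not a corenet checkpoint: ", path)
  }
  if (!identical(model$registry_version, REGISTRY_VERSION)) {
    stop("checkpoint registry v", model$registry_version,
         " does not match this package's registry v", REGISTRY_VERSION)
  }
  model
}
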