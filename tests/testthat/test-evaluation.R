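test_that("confusion metrics reproduce hand-computed worked examples", {
  # 8 true positives, 2 false negatives, 6 true negatives, 4 false positives
  counts <- c(TP = 8, FP = 4, TN = 6, FN = 2)
  m <- metrics(counts)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.6)
  expect_equal(m[["f1"]], 16 / 22)
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["mcc"]], (8 * 6 - 4 * 2) / sqrt(10 * 12 * 10 * 8))
  expect_length(attr(m, "degenerate"), 0)
  # counts in the hundreds: the MCC denominator must not overflow
  big <- metrics(c(TP = 450L, FP = 50L, TN = 460L, FN = 40L))
  expect_equal(big[["mcc"]],
               (450 * 460 - 50 * 40) / sqrt(490 * 500 * 510 * 500))
  # a perfect classifier scores 1 on every metric
  perfect <- metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(perfect), rep(1, 5), ignore_attr = TRUE)
})

test_that("zero-denominator metrics report 0 and are flagged, not NaN", {
  m <- metrics(confusion_counts(rep(0L, 6), rep(0L, 6)))
  expect_true(all(is.finite(m)))
  expect_equal(m[["sensitivity"]], 0)
  expect_equal(m[["specificity"]], 1)
  expect_setequal(attr(m, "degenerate"), c("sensitivity", "f1", "mcc"))
  expect_error(metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "no evaluated")
})

test_that("counts and metrics match counting oracles on random instances", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    pred <- rbinom(n, 1, 0.5)
    truth <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(pred, truth)
    expect_equal(cc, oracle_confusion(pred, truth), ignore_attr = TRUE)
    m <- metrics(cc)
    TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
    if (TP + FN > 0) expect_equal(m[["sensitivity"]], TP / (TP + FN))
    expect_equal(m[["accuracy"]], (TP + TN) / n)
  }
})

test_that("the rank AUC equals pair enumeration and the ROC trapezoid area", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    ra <- roc_auc(scores, labels)
    expect_equal(ra$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(ra$auc, trapezoid_area(ra$roc), tolerance = 1e-12)
    expect_equal(ra$roc$fpr[1], 0)
    expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  }
  # independent cross-check against pROC
  set.seed(73)
  labels <- rbinom(300, 1, 0.5)
  scores <- rnorm(300) + labels
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
  # perfectly separated scores give AUC 1; a single class is an error
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, rep(1, 4)), "single class")
  # uninformative scores sit near 1/2
  set.seed(74)
  expect_lt(abs(roc_auc(rnorm(4000), rbinom(4000, 1, 0.5))$auc - 0.5), 0.05)
})

test_that("transcripts split at the 303-nt longest-ORF boundary", {
  codon <- "GCT"
  orf_of <- function(k) paste0("ATG", strrep(codon, k), "TAA")
  at_boundary <- orf_of(99)   # 303 nt including the stop
  above <- orf_of(100)        # 306 nt
  recs <- data.frame(id = c("eq303", "gt303", "no_orf"),
                     sequence = c(at_boundary, above, strrep("C", 400)))
  expect_identical(is_long_orf(recs), c(FALSE, TRUE, FALSE))
  sp <- split_by_orf_length(recs)
  expect_identical(sp$long_orf$id, "gt303")
  expect_setequal(sp$short_orf$id, c("eq303", "no_orf"))
  expect_equal(nrow(sp$long_orf) + nrow(sp$short_orf), nrow(recs))
})

test_that("model evaluation reports whole-set and ORF-stratified metrics", {
  synth <- tiny_synth(n = 30, seed = 21)
  fit <- corenet(synth, synth$label, config = tiny_config(max_epochs = 6L))
  rep_all <- evaluate_model(fit, synth, synth$label, stratify_orf = TRUE)
  expect_true("all" %in% names(rep_all))
  r <- rep_all$all
  expect_equal(r$n, nrow(synth))
  expect_equal(sum(r$counts), nrow(synth))
  # report agrees with a recomputation from the predicted probabilities
  p <- predict(fit, synth[, c("id", "sequence")], type = "prob")
  expect_equal(r$auc, roc_auc(1 - p, synth$label)$auc)
  expect_equal(r$metrics,
               metrics(confusion_counts(as.integer(p < 0.5), synth$label)))
  # strata partition the records
  strata <- setdiff(names(rep_all), "all")
  expect_equal(sum(vapply(rep_all[strata], `[[`, numeric(1), "n")), r$n)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep_all, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$n[tab$stratum == "all"], r$n)
})

test_that("cross-validation retrains per fold and averages fold metrics", {
  synth <- tiny_synth(n = 24, seed = 31)
  cv <- cross_validate(synth, synth$label, k = 2L,
                       config = tiny_config(max_epochs = 4L))
  expect_length(cv$folds, 2)
  expect_equal(sum(vapply(cv$folds, `[[`, numeric(1), "n")), nrow(synth))
  tab <- t(vapply(cv$folds, function(r) c(r$metrics, auc = r$auc),
                  numeric(6)))
  expect_equal(cv$mean, colMeans(tab))
  expect_error(cross_validate(synth, synth$label, k = 1L), "at least 2")
  expect_error(cross_validate(synth, synth$label, k = 30L), "smaller class")
})
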