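test_that("orf_stats reports length, coverage and integrity", {
  expect_equal(orf_stats("ATGAAATAG"),
               c(orf_length = 9, orf_coverage = 1, orf_integrity = 1))
  expect_equal(orf_stats("CCCCCC"),
               c(orf_length = 0, orf_coverage = 0, orf_integrity = 0))
  expect_equal(orf_stats("TTATGAAATAGTT"),
               c(orf_length = 9, orf_coverage = 9 / 13, orf_integrity = 1))
})

test_that("fickett score is pure, bounded by its lookup tables, and matches a hand lookup", {
  s <- strrep("ACGT", 25)
  expect_identical(fickett_score(s), fickett_score(s))
  # homopolymer: every parameter sits in a saturated table bin
  expect_equal(fickett_score(strrep("A", 12)), 0.3458, tolerance = 1e-12)
  lo <- sum(apply(corenet:::FICKETT_POSITION_PROB, 1, min) *
              corenet:::FICKETT_POSITION_WEIGHT) +
        sum(apply(corenet:::FICKETT_CONTENT_PROB, 1, min) *
              corenet:::FICKETT_CONTENT_WEIGHT)
  hi <- sum(apply(corenet:::FICKETT_POSITION_PROB, 1, max) *
              corenet:::FICKETT_POSITION_WEIGHT) +
        sum(apply(corenet:::FICKETT_CONTENT_PROB, 1, max) *
              corenet:::FICKETT_CONTENT_WEIGHT)
  set.seed(5)
  for (i in 1:100) {
    sc <- fickett_score(random_dna(sample(4:400, 1)))
    expect_gte(sc, lo)
    expect_lte(sc, hi)
  }
  expect_error(fickett_score("ACG"), "at least 4")
})

test_that("hexamer table is zero for symmetric corpora and positive for enriched hexamers", {
  sym <- c("ATGTAA", "ATGTGA")
  tab <- train_hexamer_table(sym, sym)
  expect_equal(max(abs(tab)), 0)

  # poly-A ORF vs a C-homopolymer background with equal hexamer totals:
  # absent hexamers get exactly zero weight, AAAAAA a positive one
  coding <- paste0("ATG", strrep("AAA", 32), "TAG")
  noncoding <- strrep("C", 3 * 32 + 6 + 3 * ((6 - 3) / 3) - 3 + 5)
  n_hex_coding <- (nchar(coding) - 6) / 3 + 1
  noncoding <- strrep("C", n_hex_coding + 5)   # same number of windows
  tab <- train_hexamer_table(coding, noncoding)
  expect_gt(tab[["AAAAAA"]], 0)
  absent <- setdiff(names(tab), c("AAAAAA", "ATGAAA", "AAAAAT", "AAATAG",
                                  "AAGAAA", "CCCCCC"))
  expect_equal(max(abs(tab[absent])), 0)
  expect_error(train_hexamer_table(character(0), "ACGTACG"), "nonempty")
})

test_that("hexamer table matches an independent count-and-log oracle on a toy corpus", {
  set.seed(21)
  coding <- replicate(3, paste0(random_dna(9), "ATG", random_dna(45),
                                random_dna(6)))
  noncoding <- replicate(2, random_dna(80))
  tab <- train_hexamer_table(coding, noncoding, pseudocount = 1)

  count_hex <- function(seqs, step) {
    counts <- integer(0)
    for (s in seqs) {
      if (nchar(s) < 6) next
      for (i in seq(1, nchar(s) - 5, by = step)) {
        h <- substr(s, i, i + 5)
        counts[h] <- (if (is.na(counts[h])) 0L else counts[h]) + 1L
      }
    }
    counts
  }
  orfs <- vapply(coding, function(s) {
    o <- oracle_longest_orf(s)
    if (is.null(o)) "" else substr(s, o$start + 1, o$end)
  }, character(1))
  cc <- count_hex(orfs, 3)
  nc <- count_hex(noncoding, 1)
  for (h in c(names(cc), names(nc), "GATTAC")) {
    c_h <- if (h %in% names(cc)) cc[[h]] else 0
    n_h <- if (h %in% names(nc)) nc[[h]] else 0
    expected <- log((c_h + 1) / (sum(cc) + 4096)) -
      log((n_h + 1) / (sum(nc) + 4096))
    expect_equal(tab[[h]], expected, tolerance = 1e-12, info = h)
  }
})

test_that("hexamer score averages table weights over in-frame ORF hexamers", {
  zero_tab <- structure(rep(0, 4096),
                        names = names(train_hexamer_table("ATGTAA", "ACGTAC")))
  expect_equal(hexamer_score("ATGAAAAAATAG", zero_tab), 0)
  tab <- zero_tab
  tab[c("ATGAAA", "AAAAAA", "AAATAG")] <- 1
  expect_equal(hexamer_score("ATGAAAAAATAG", tab), 1)
  # linearity in the weights
  set.seed(13)
  tab2 <- zero_tab + stats::rnorm(4096)
  s <- random_dna(200)
  expect_equal(2 * hexamer_score(s, tab2), hexamer_score(s, 2 * tab2))
  # degenerate lengths score zero
  expect_equal(hexamer_score("ACGTA", zero_tab + 1), 0)
})

test_that("GC statistics: content over the transcript, variance over ORF codon positions", {
  expect_equal(gc_stats("GGCC"), c(gc_content = 1, gc_variance = 0))
  expect_equal(gc_stats("ATAT"), c(gc_content = 0, gc_variance = 0))
  # ATG|GCA|TGA: per-position GC = (1/3, 2/3, 1/3)
  expect_equal(gc_stats("ATGGCATGA"),
               c(gc_content = 4 / 9, gc_variance = 2 / 81))
  expect_error(gc_stats("NN"), "undefined")
})

test_that("codon statistics relate ORF codons to transcript capacity", {
  expect_equal(codon_stats("ATGAAATAG"), c(codon_number = 3, codon_ratio = 1))
  expect_equal(codon_stats("CCCCCC"), c(codon_number = 0, codon_ratio = 0))
  expect_equal(codon_stats("TTATGAAATAGTT"),
               c(codon_number = 3, codon_ratio = 3 / 4))
})

# independent profile oracle: cyclic hexamer frequency over the expectation
# from mononucleotide composition, log scale with eps = 4^-6
oracle_profile <- function(s) {
  kmers <- sort(do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                                6))))
  s2 <- paste0(s, substr(s, 1, 5))
  counts <- structure(numeric(4096), names = kmers)
  tot <- 0
  for (i in 1:nchar(s)) {
    h <- substr(s2, i, i + 5)
    if (grepl("[^ACGT]", h)) next
    counts[h] <- counts[h] + 1
    tot <- tot + 1
  }
  f <- counts / max(tot, 1)
  ch <- strsplit(s, "")[[1]]
  bf <- sapply(c("A", "C", "G", "T"), function(b) mean(ch == b))
  e <- vapply(kmers, function(h) {
    prod(vapply(strsplit(h, "")[[1]], function(b) max(bf[[b]], 1e-12),
                numeric(1)))
  }, numeric(1))
  eps <- 4^-6
  log(f + eps) - log(e + eps)
}

test_that("reference profiles are centroids of per-sequence log-ratio profiles", {
  set.seed(8)
  cls_a <- replicate(3, random_dna(150))
  cls_b <- replicate(2, random_dna(120))
  refs <- train_reference_profiles(cls_a, cls_b)
  oracle_pc <- colMeans(t(vapply(cls_a, oracle_profile, numeric(4096))))
  expect_equal(unname(refs$pc), unname(oracle_pc), tolerance = 1e-10)
  # identical classes give identical centroids and unit ratios downstream
  refs2 <- train_reference_profiles(cls_a, cls_a)
  expect_equal(refs2$pc, refs2$nc)
  d <- distance_features(random_dna(100), refs2)
  expect_equal(d[["dist_ratio"]], 1)
  expect_equal(d[["logdist_ratio"]], 1)
})

test_that("distance features match a hand Euclidean computation and guard degeneracy", {
  set.seed(30)
  cls_a <- replicate(2, random_dna(100))
  cls_b <- replicate(2, random_dna(100))
  rec <- random_dna(90)
  refs <- train_reference_profiles(cls_a, cls_b)
  d <- distance_features(rec, refs)
  p <- oracle_profile(rec)
  pc <- colMeans(t(vapply(cls_a, oracle_profile, numeric(4096))))
  nc <- colMeans(t(vapply(cls_b, oracle_profile, numeric(4096))))
  expect_equal(d[["dist_pc"]], sqrt(sum((p - pc)^2)), tolerance = 1e-9)
  expect_equal(d[["dist_nc"]], sqrt(sum((p - nc)^2)), tolerance = 1e-9)
  expect_equal(d[["dist_ratio"]], d[["dist_nc"]] / d[["dist_pc"]])
  expect_equal(d[["logdist_pc"]], log1p(d[["dist_pc"]]))
  # a record generating a single-sequence class sits on that centroid
  refs1 <- train_reference_profiles(cls_a[1], cls_b)
  d1 <- distance_features(cls_a[1], refs1)
  expect_equal(d1[["dist_pc"]], 0)
  expect_true(is.finite(d1[["dist_ratio"]]))
})

test_that("distance features are invariant under sequence duplication", {
  set.seed(60)
  refs <- train_reference_profiles(replicate(2, random_dna(300)),
                                   replicate(2, random_dna(300)))
  for (i in 1:5) {
    s <- random_dna(sample(600:900, 1))
    expect_equal(distance_features(s, refs),
                 distance_features(paste0(s, s), refs), tolerance = 1e-6)
  }
})
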