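test_that("pwm constructors validate and summarize", {
  expect_error(pwm(matrix(c(0.5, 0.5, 0.1, 0.1), 1)), "sum to 1")
  expect_error(pwm(matrix(c(1, 0, 0, 0), 1)), "strictly positive")
  m <- pwm_from_kmer("CANNTG")
  expect_equal(pwm_width(m), 6)
  expect_equal(m$probs[3, ], c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(unname(m$probs[1, "C"]), 1 - 3e-3)
  rc <- pwm_reverse_complement(pwm_from_kmer("AACGTT"))
  expect_equal(pwm_consensus(rc), "AACGTT")  # palindrome
  rc2 <- pwm_reverse_complement(pwm_from_kmer("AAACCC"))
  expect_equal(pwm_consensus(rc2), "GGGTTT")
})

test_that("exact score distribution matches hand-enumerable cases", {
  eps <- 1e-3
  ac <- pwm(rbind(c(1 - 3 * eps, eps, eps, eps),
                  c(eps, 1 - 3 * eps, eps, eps)), "AC")
  d <- exact_score_pvalues(ac, background_model())
  # only the word AC achieves the top score: P = 1/16 under uniform bg
  expect_equal(d$tail[length(d$tail)], 1 / 16)
  expect_equal(d$tail[1], 1)  # P(score >= min) = 1
  expect_true(all(diff(d$tail) <= 0))

  unif <- pwm(matrix(0.25, 3, 4), "unif")
  du <- exact_score_pvalues(unif, background_model())
  expect_equal(length(du$tail), 1)
  expect_equal(du$tail, 1)

  expect_error(exact_score_pvalues(ac, background_model(), precision = 0),
               "positive")
})

test_that("score-distribution DP equals exhaustive word enumeration", {
  withr::local_seed(51)
  for (rep in 1:6) {
    w <- sample(3:5, 1)
    pw <- random_pwm(w)
    bg <- background_model(stats::runif(4, 0.1, 1))
    d <- exact_score_pvalues(pw, bg)
    enum <- enumerate_word_scores(pw, bg)
    for (k in sort(unique(enum$ints))) {
      expect_equal(score_pvalue(d, k),
                   sum(enum$probs[enum$ints >= k]), tolerance = 1e-9)
    }
  }
})

test_that("scanning recovers planted consensus sites on the correct strand", {
  withr::local_seed(61)
  bgseq <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  motif <- "ACGGTTCA"  # non-palindromic
  planted <- bgseq
  substr(planted, 18, 25) <- motif
  occ <- scan_sequences(c(s1 = planted), pwm_from_kmer(motif),
                        background_model())
  expect_true(any(occ$offset == 17 & occ$strand == "+"))

  flipped <- bgseq
  substr(flipped, 18, 25) <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  occ2 <- scan_sequences(c(s1 = flipped), pwm_from_kmer(motif),
                         background_model())
  expect_true(any(occ2$offset == 17 & occ2$strand == "-"))

  # no hits on all-A sequences with a C-rich motif; no error on short ones
  occ3 <- scan_sequences(c(a = strrep("A", 50), tiny = "ACG"),
                         pwm_from_kmer("CCCCCCCC"), background_model())
  expect_equal(nrow(occ3), 0)

  # windows containing N are skipped
  withN <- planted
  substr(withN, 20, 20) <- "N"
  occ4 <- scan_sequences(c(s1 = withN), pwm_from_kmer(motif),
                         background_model())
  expect_false(any(occ4$offset == 17))
})

test_that("scan hit set equals a brute-force window scanner and is monotone in the threshold", {
  withr::local_seed(62)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:5)
  pw <- random_pwm(5)
  bg <- background_model(c(0.3, 0.2, 0.2, 0.3))
  enum <- enumerate_word_scores(pw, bg)
  word_p <- function(int) sum(enum$probs[enum$ints >= int])
  for (thr in c(1e-2, 1e-3)) {
    occ <- scan_sequences(seqs, pw, bg, p_threshold = thr,
                          both_strands = FALSE)
    # brute force: score every window by word lookup
    brute <- list()
    smat <- round(t(log2(sweep(pw$probs, 2, bg$freqs, "/"))) / 0.01)
    for (nm in names(seqs)) {
      codes <- match(strsplit(seqs[[nm]], "")[[1]], c("A", "C", "G", "T"))
      for (o in 0:(120 - 5)) {
        int <- sum(smat[cbind(codes[(o + 1):(o + 5)], 1:5)])
        if (word_p(int) <= thr)
          brute[[length(brute) + 1]] <- c(nm, o)
      }
    }
    got <- paste(occ$seq_id, occ$offset)
    want <- vapply(brute, paste, "", collapse = " ")
    expect_setequal(got, want)
  }
  loose <- scan_sequences(seqs, pw, bg, p_threshold = 1e-2)
  tight <- scan_sequences(seqs, pw, bg, p_threshold = 1e-3)
  expect_true(all(paste(tight$seq_id, tight$offset, tight$strand) %in%
                    paste(loose$seq_id, loose$offset, loose$strand)))
})

test_that("k-mer discovery finds a planted word and matches the hypergeometric tail", {
  withr::local_seed(71)
  mk <- function(n, len = 60) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  targets <- mk(100)
  idx <- sample(100, 50)
  for (i in idx) substr(targets[i], 20, 25) <- "CAGCTG"
  background <- mk(100)
  res <- discover_enriched_kmers(targets, background, k_range = 6)
  expect_gt(nrow(res), 0)
  expect_equal(res$pattern[1], "CAGCTG")  # palindromic: own canonical form

  # toy counts 5/10 vs 0/10: one-sided Fisher equals hypergeometric tail
  t2 <- c(vapply(1:5, function(i) strrep("ACGTAC", 3), ""),
          vapply(1:5, function(i) strrep("GGATCC", 3), ""))
  b2 <- vapply(1:10, function(i) strrep("TTTTTT", 3), "")
  res2 <- discover_enriched_kmers(t2, b2, k_range = 6, e_threshold = 1,
                                  max_motifs = 100)
  row <- res2[res2$pattern == "ACGTAC", ]
  expect_equal(row$n_target, 5)
  expect_equal(row$p_fisher,
               sum(stats::dhyper(5:10, 10, 10, 5 + 0)), tolerance = 1e-12)
  expect_true(all(res2$e_value >= res2$p_fisher))
  expect_error(discover_enriched_kmers(t2, b2, k_range = integer(0)),
               "empty k_range")
})

test_that("k-mer discovery is calibrated when targets equal background in distribution", {
  withr::local_seed(72)
  hits <- vapply(1:10, function(rep) {
    seqs <- vapply(1:60, function(i)
      paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""), "")
    res <- discover_enriched_kmers(seqs[1:30], seqs[31:60], k_range = 6:8)
    nrow(res) > 0
  }, logical(1))
  expect_lte(sum(hits), 1)  # no E <= 0.05 motif in >= 90% of replicates
})

test_that("motif matching recovers identity, orientation, and offsets", {
  lib <- demo_motif_library()
  for (nm in names(lib)) {
    m <- match_to_known_motifs(lib[[nm]], lib)
    expect_equal(m$name[1], nm)
    expect_equal(m$score[1], 1)
    expect_equal(m$orientation[1], "+")
    expect_equal(m$offset[1], 0)
  }
  # reverse complement of a library motif is matched with orientation "-"
  m <- match_to_known_motifs(pwm_reverse_complement(lib$decoy_ZF), lib)
  expect_equal(m$name[1], "decoy_ZF")
  expect_equal(m$score[1], 1)
  expect_equal(m$orientation[1], "-")
  # interior columns align at the true offset
  inner <- pwm(lib$decoy_ZF$probs[2:7, ], "inner")
  m2 <- match_to_known_motifs(inner, lib["decoy_ZF"])
  expect_equal(m2$offset[1], 1)
  expect_equal(m2$score[1], 1)
  expect_error(match_to_known_motifs(inner, list()), "empty")
})

test_that("peak subsetting applies containment, exclusion rules, and covers all peaks", {
  peaks <- interval_set(rep("chr1", 3), c(0, 200, 400),
                        c(100, 300, 500), name = c("p1", "p2", "p3"),
                        label = "peaks")
  occ <- function(seq_id, offset, width = 8, motif = "m1")
    data.frame(motif = motif, seq_id = seq_id, offset = offset,
               width = width, strand = "+", score = 1, pvalue = 1e-5)
  occs <- list(
    m1 = rbind(occ("p1", 10), occ("p3", 50)),
    m2 = occ("p2", 95),                     # extends 3 bp past the end
    m3 = occ("p1", 99)[0, ])                # zero occurrences
  res <- subset_peaks_by_motif(peaks, occs, min_subset = 1)
  expect_equal(sort(res$subsets$m1$df$name), c("p1", "p3"))
  expect_null(res$subsets$m2)
  expect_equal(res$no_motif$df$name, "p2")
  expect_true(all(c("m2", "m3") %in% res$exclusions$motif))
  expect_equal(res$exclusions$rule[res$exclusions$motif == "m3"],
               "no significant motif occurrences")
  expect_equal(res$exclusions$rule[res$exclusions$motif == "m2"],
               "no significant motif occurrences")

  # coverage and disjointness: subsets + noMotif partition the peaks
  all_names <- c(unlist(lapply(res$subsets, function(s) s$df$name)),
                 res$no_motif$df$name)
  expect_setequal(all_names, peaks$df$name)
  expect_length(intersect(res$subsets$m1$df$name,
                          res$no_motif$df$name), 0)

  # known-match requirement and size rule are logged with their rules
  res2 <- subset_peaks_by_motif(peaks, occs, min_subset = 1,
                                require_known_match = TRUE,
                                matched = character(0))
  expect_equal(res2$exclusions$rule[res2$exclusions$motif == "m1"],
               "no match to a known motif")
  res3 <- subset_peaks_by_motif(peaks, occs["m1"], min_subset = 3)
  expect_match(res3$exclusions$rule[res3$exclusions$motif == "m1"],
               "smaller than 3")
  expect_error(subset_peaks_by_motif(peaks, list(mx = occ("nope", 1))),
               "nope")
})

test_that("peak sequence extraction and library I/O round-trip", {
  genome <- c(chr1 = "AACCGGTTAACCGGTT", chr2 = "TTTTAAAA")
  peaks <- interval_set(c("chr1", "chr2"), c(2, 0), c(6, 4),
                        name = c("pk1", "pk2"))
  seqs <- extract_peak_sequences(genome, peaks)
  expect_equal(as.character(seqs), c(pk1 = "CCGG", pk2 = "TTTT"))
  expect_error(extract_peak_sequences(genome["chr1"], peaks), "chr2")

  lib <- demo_motif_library()
  path <- withr::local_tempfile()
  write_motif_library(lib, path)
  back <- read_motif_library(path)
  expect_equal(names(back), names(lib))
  expect_equal(back$Ebox_bHLH$probs, lib$Ebox_bHLH$probs,
               tolerance = 1e-5)
})
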