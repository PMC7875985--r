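# Independent brute-force oracles and small fixture builders used across
# the suite.  Oracles deliberately avoid the package's interval / DP code
# paths they are checking.

# Base-resolution membership bitmap of an interval_set over a toy genome.
bitmap_of <- function(set, chroms, genome_len) {
  bits <- lapply(stats::setNames(chroms, chroms),
                 function(ch) logical(genome_len))
  df <- set$df
  for (i in seq_len(nrow(df))) {
    bits[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  bits
}

bitmap_jaccard <- function(a, b, chroms, genome_len) {
  ba <- bitmap_of(a, chroms, genome_len)
  bb <- bitmap_of(b, chroms, genome_len)
  inter <- sum(mapply(function(x, y) sum(x & y), ba, bb))
  uni <- sum(mapply(function(x, y) sum(x | y), ba, bb))
  if (uni == 0) 0 else inter / uni
}

random_interval_set <- function(n, chroms, genome_len, max_len = 500,
                                label = "rand") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(genome_len - max_len, n) - 1
  len <- sample.int(max_len, n)
  interval_set(chrom, start, start + len, label = label)
}

# r2 from the 2x2 haplotype table (count 00/01/10/11), not moments.
r2_tabulated <- function(x, y) {
  n11 <- sum(x == 1 & y == 1)
  n <- length(x)
  pa <- sum(x) / n
  pb <- sum(y) / n
  d <- n11 / n - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# P(X >= s) by full enumeration of all 2^n Bernoulli outcomes.
poisbin_tail_enum <- function(probs, s) {
  n <- length(probs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= s)
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
  }
  total
}

# Exhaustive word-level score distribution of a PWM: integer score and
# background probability of every one of the 4^w words, using the same
# discretization as the package.
enumerate_word_scores <- function(pw, bg, precision = 0.01) {
  smat <- round(t(log2(sweep(pw$probs, 2, bg$freqs, "/"))) / precision)
  w <- ncol(smat)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  ints <- rowSums(vapply(seq_len(w), function(j) smat[words[, j], j],
                         numeric(nrow(words))))
  probs <- exp(rowSums(vapply(seq_len(w), function(j)
    log(bg$freqs)[words[, j]], numeric(nrow(words)))))
  list(ints = ints, probs = probs)
}

# Tail probability P(score >= k) for every unique achieved integer score,
# from the word enumeration (ascending score order).
enum_tails <- function(enum) {
  by_int <- tapply(enum$probs, enum$ints, sum)
  ints <- as.numeric(names(by_int))
  list(ints = ints, tails = rev(cumsum(rev(as.numeric(by_int)))))
}

random_pwm <- function(width, name = "rand") {
  m <- matrix(stats::rgamma(width * 4, shape = 1) + 0.01, width, 4)
  pwm(m / rowSums(m), name = name)
}

# A tiny deterministic panel used by LD / matched-control unit tests:
# 4 haplotypes; four singleton columns (maf 0.25, mutually low LD), a
# duplicate of the first (perfect LD), and three maf-0.5 columns in
# pairwise linkage equilibrium.  All on chr1, well inside one LD window.
toy_panel <- function() {
  cols <- cbind(
    e1 = c(1, 0, 0, 0), e2 = c(0, 1, 0, 0), e3 = c(0, 0, 1, 0),
    e4 = c(0, 0, 0, 1), e1dup = c(1, 0, 0, 0),
    h1 = c(1, 1, 0, 0), h2 = c(1, 0, 1, 0), h3 = c(0, 1, 1, 0))
  haplotype_panel(cols, variant_table(colnames(cols), "chr1",
                                      pos = c(100, 200, 300, 400, 500,
                                              600, 700, 800)))
}

# Small-scale synthetic configuration for fast unit tests (not the study
# conditions used by the acceptance suite).  Peaks are denser than at full
# scale so that planted effects up to 1 remain satisfiable at 20 loci.
mini_config <- function(...) {
  args <- list(seed = 424242, chrom_length = 5e5, n_peaks = 150,
               peak_length_mean = 400, plant_rate = 0.5,
               n_haplotypes = 80, n_variants = 400, block_length = 1e4,
               n_loci = 20, n_genes = 20, n_decoys = 1,
               n_background = 150, min_controls = 5)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

.study_cache <- new.env(parent = emptyenv())

# Memoized studies so several test files can share one generation.
cached_study <- function(key, cfg) {
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- synthetic_study(cfg)
  .study_cache[[key]]
}
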