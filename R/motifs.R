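BASES <- c("A", "C", "G", "T")

#' Position weight matrices
#'
#' A PWM is a width-by-4 matrix of base probabilities over (A, C, G, T);
#' every row sums to 1 and all entries are strictly positive (a pseudocount
#' is applied when building from counts or consensus patterns).  Width is
#' limited to 30 columns.
#'
#' @param probs width x 4 numeric matrix (columns A, C, G, T).
#' @param name motif name.
#' @param pseudocount the pseudocount the matrix was built with (recorded).
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif", pseudocount = 0) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, nrow(probs) >= 1, nrow(probs) <= 30)
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("each PWM row must sum to 1")
  if (any(probs <= 0))
    stop("PWM entries must be strictly positive (use a pseudocount)")
  dimnames(probs) <- list(NULL, BASES)
  structure(list(name = name, probs = probs, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", sQuote(x$name), "width", nrow(x$probs),
      "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm`.
#' @export
pwm_width <- function(x) nrow(x$probs)

#' @rdname pwm
#' @export
pwm_consensus <- function(x) paste(BASES[max.col(x$probs)], collapse = "")

#' @rdname pwm
#' @param counts width x 4 matrix of base counts.
#' @export
pwm_from_counts <- function(counts, name = "motif", pseudocount = 0.01) {
  counts <- as.matrix(counts) + pseudocount
  pwm(counts / rowSums(counts), name = name, pseudocount = pseudocount)
}

#' @rdname pwm
#' @param pattern consensus string over `{A,C,G,T,N}` (e.g. a discovered
#'   k-mer); the planted base gets probability `1 - 3 * pseudocount`, `N`
#'   positions are uniform.
#' @export
pwm_from_kmer <- function(pattern, name = pattern, pseudocount = 0.001) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% c(BASES, "N")))
    stop("pattern must be over {A,C,G,T,N}")
  probs <- t(vapply(chars, function(ch) {
    if (ch == "N") rep(0.25, 4) else {
      p <- rep(pseudocount, 4)
      p[match(ch, BASES)] <- 1 - 3 * pseudocount
      p
    }
  }, numeric(4)))
  pwm(probs, name = name, pseudocount = pseudocount)
}

#' Reverse complement of a PWM
#'
#' @param x a `pwm`.
#' @return The reverse-complemented `pwm`.
#' @export
pwm_reverse_complement <- function(x) {
  probs <- x$probs[rev(seq_len(nrow(x$probs))), c(4, 3, 2, 1), drop = FALSE]
  pwm(probs, name = x$name, pseudocount = x$pseudocount)
}

#' Background base composition
#'
#' Order-0 background model: single-nucleotide frequencies, typically
#' estimated from the scanned sequences themselves.
#'
#' @param freqs probabilities over (A, C, G, T); normalized if needed.
#' @return An object of class `background_model`.
#' @export
background_model <- function(freqs = rep(0.25, 4)) {
  stopifnot(length(freqs) == 4, all(freqs >= 0), sum(freqs) > 0)
  freqs <- freqs / sum(freqs)
  if (any(freqs == 0))
    stop("background frequencies must be strictly positive")
  names(freqs) <- BASES
  structure(list(freqs = freqs), class = "background_model")
}

#' @rdname background_model
#' @param seqs sequences (character vector or `DNAStringSet`); one
#'   pseudo-observation per base keeps all frequencies positive.
#' @export
background_from_sequences <- function(seqs) {
  seqs <- .as_dnastringset(seqs)
  counts <- colSums(Biostrings::letterFrequency(seqs, BASES)) + 1
  background_model(counts / sum(counts))
}

.as_dnastringset <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) return(seqs)
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

## Integer (discretized) log-odds score matrix, 4 x width, in units of
## `precision` bits.
.score_ints <- function(pwm, bg, precision) {
  t(round(log2(sweep(pwm$probs, 2, bg$freqs, "/")) / precision))
}

#' Exact score distribution of a PWM under a background model
#'
#' Computes, by dynamic programming over motif positions on a log-odds scale
#' discretized at `precision` bits, the exact null distribution of the
#' match score of a random background word, and from it the p-value
#' `P(score' >= score)` for every achievable score.  This is the standard
#' calibration behind fixed p-value thresholds for motif scanning.
#'
#' @param pwm a [pwm()].
#' @param bg a [background_model()].
#' @param precision score discretization step in bits (default 0.01; must be
#'   positive).
#' @return An object of class `score_distribution` with elements `min_int`
#'   (smallest achievable integer score), `tail` (p-values for consecutive
#'   integer scores starting at `min_int`), `smat` (the 4 x width integer
#'   score matrix) and `precision`.
#' @export
exact_score_pvalues <- function(pwm, bg, precision = 0.01) {
  if (!is.numeric(precision) || precision <= 0)
    stop("precision must be positive")
  s <- .score_ints(pwm, bg, precision)
  w <- ncol(s)
  lo <- sum(apply(s, 2, min))
  hi <- sum(apply(s, 2, max))
  dist <- 1
  cur_lo <- 0
  for (j in seq_len(w)) {
    cmin <- min(s[, j])
    cmax <- max(s[, j])
    nd <- numeric(length(dist) + cmax - cmin)
    for (b in 1:4) {
      sh <- s[b, j] - cmin
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + bg$freqs[b] * dist
    }
    dist <- nd
    cur_lo <- cur_lo + cmin
  }
  stopifnot(cur_lo == lo, length(dist) == hi - lo + 1)
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  structure(list(min_int = lo, tail = tail, smat = s,
                 precision = precision, motif = pwm$name),
            class = "score_distribution")
}

#' @rdname exact_score_pvalues
#' @param dist a `score_distribution`.
#' @param score_int integer score(s) on the discretized scale.
#' @return `score_pvalue()`: the exact p-value(s) `P(score' >= score_int)`.
#' @export
score_pvalue <- function(dist, score_int) {
  i <- score_int - dist$min_int + 1
  out <- numeric(length(i))
  out[i < 1] <- 1
  out[i > length(dist$tail)] <- 0
  ok <- i >= 1 & i <= length(dist$tail)
  out[ok] <- dist$tail[i[ok]]
  out
}

## Smallest integer score with tail p-value <= p, or Inf if unattainable.
.score_threshold <- function(dist, p) {
  k <- which(dist$tail <= p)
  if (!length(k)) return(Inf)
  dist$min_int + k[1] - 1
}

## Integer window scores of a coded sequence (NA where a window contains N).
.window_scores <- function(codes, smat) {
  w <- ncol(smat)
  n <- length(codes) - w + 1
  if (n < 1) return(numeric(0))
  sc <- smat[codes[seq_len(n)], 1]
  if (w > 1) for (j in 2:w) sc <- sc + smat[codes[j:(n + j - 1)], j]
  sc
}

#' Scan sequences for motif occurrences with exact p-values
#'
#' Scores every window of every sequence (both orientations by default)
#' against the PWM and reports the windows whose exact score p-value under
#' the background model is at or below `p_threshold`.  Offsets are 0-based
#' and refer to the forward-strand start of the window; windows containing
#' `N` are skipped; sequences shorter than the motif yield no occurrences.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param pwm a [pwm()].
#' @param bg a [background_model()]; defaults to the order-0 composition of
#'   `seqs`.
#' @param p_threshold report occurrences with `pvalue <= p_threshold`
#'   (default `1e-4`).
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @param precision score discretization step in bits.
#' @return A data frame of occurrences: `motif`, `seq_id`, `offset`,
#'   `width`, `strand`, `score` (log-odds bits), `pvalue`.
#' @export
scan_sequences <- function(seqs, pwm, bg = NULL, p_threshold = 1e-4,
                           both_strands = TRUE, precision = 0.01) {
  .scan_many(seqs, list(pwm), bg = bg, p_threshold = p_threshold,
             both_strands = both_strands, precision = precision)[[1]]
}

## Scan several PWMs over one coded sequence collection (codes computed
## once).  Returns a list of occurrence data frames, one per PWM.
.scan_many <- function(seqs, pwms, bg = NULL, p_threshold = 1e-4,
                       both_strands = TRUE, precision = 0.01) {
  seqs <- .as_dnastringset(seqs)
  if (is.null(bg)) bg <- background_from_sequences(seqs)
  chars <- as.character(seqs)
  coded <- lapply(chars, function(s)
    match(strsplit(toupper(s), "")[[1]], BASES))
  empty <- data.frame(motif = character(), seq_id = character(),
                      offset = numeric(), width = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  strands <- if (both_strands) c("+", "-") else "+"
  lapply(pwms, function(pw) {
    mats <- list("+" = pw, "-" = if (both_strands)
      pwm_reverse_complement(pw) else NULL)
    dists <- lapply(mats[strands], exact_score_pvalues, bg = bg,
                    precision = precision)
    out <- list()
    for (st in strands) {
      d <- dists[[st]]
      thr <- .score_threshold(d, p_threshold)
      if (!is.finite(thr)) next
      for (i in seq_along(coded)) {
        sc <- .window_scores(coded[[i]], d$smat)
        hit <- which(!is.na(sc) & sc >= thr)
        if (!length(hit)) next
        out[[length(out) + 1]] <- data.frame(
          motif = pw$name, seq_id = names(chars)[i], offset = hit - 1,
          width = pwm_width(pw), strand = st,
          score = sc[hit] * precision,
          pvalue = score_pvalue(d, sc[hit]), stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    res <- res[order(res$seq_id, res$offset, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}

#' Write motif occurrences as BED6-style records
#'
#' One record per occurrence; the score column holds the log-odds score in
#' bits.  With `peaks` supplied, peak-relative offsets are lifted to genome
#' coordinates; otherwise records are sequence-relative.
#'
#' @param occ occurrence data frame from [scan_sequences()].
#' @param path output path.
#' @param peaks optional `interval_set` whose names match `occ$seq_id`.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occ, path, peaks = NULL) {
  if (is.null(peaks)) {
    chrom <- occ$seq_id
    start <- occ$offset
  } else {
    i <- match(occ$seq_id, peaks$df$name)
    if (anyNA(i)) stop("occurrence seq_id not found among peak names: ",
                       occ$seq_id[which(is.na(i))[1]])
    chrom <- peaks$df$chrom[i]
    start <- peaks$df$start[i] + occ$offset
  }
  df <- data.frame(chrom = chrom, start = start, end = start + occ$width,
                   name = occ$motif, score = round(occ$score, 4),
                   strand = occ$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write a position-probability-matrix library
#'
#' Plain-text motif library: for each motif a header line `>name` followed
#' by one line per position with four whitespace-separated probabilities in
#' A C G T order.
#'
#' @param path library file.
#' @return `read_motif_library()`: a named list of [pwm()] objects.
#' @export
read_motif_library <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers ('>name') in ", path)
  bounds <- c(heads, length(lines) + 1)
  out <- list()
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    probs <- do.call(rbind, lapply(body, function(l)
      as.numeric(strsplit(l, "\\s+")[[1]])))
    if (ncol(probs) != 4 || anyNA(probs))
      stop("malformed matrix for motif ", name)
    out[[name]] <- pwm(probs / rowSums(probs), name = name)
  }
  out
}

#' @rdname read_motif_library
#' @param library named list of [pwm()] objects.
#' @export
write_motif_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library) {
    writeLines(paste0(">", m$name), con)
    utils::write.table(format(m$probs, digits = 6), con, sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Extract peak sequences from a genome
#'
#' The `getfasta` step: cuts each interval's sequence out of the genome.
#'
#' @param genome `DNAStringSet` (or named character) with one entry per
#'   chromosome.
#' @param peaks an `interval_set` with non-missing, unique interval names.
#' @return A `DNAStringSet` named by peak.
#' @export
extract_peak_sequences <- function(genome, peaks) {
  genome <- .as_dnastringset(genome)
  df <- peaks$df
  if (any(is.na(df$name)) || anyDuplicated(df$name))
    stop("peaks must have unique non-missing names")
  out <- character(nrow(df))
  for (ch in unique(df$chrom)) {
    if (!ch %in% names(genome)) stop("chromosome missing from genome: ", ch)
    s <- as.character(genome[[match(ch, names(genome))]])
    sel <- which(df$chrom == ch)
    if (any(df$end[sel] > nchar(s)))
      stop("interval beyond chromosome end on ", ch)
    out[sel] <- substring(s, df$start[sel] + 1, df$end[sel])
  }
  names(out) <- df$name
  Biostrings::DNAStringSet(out)
}
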