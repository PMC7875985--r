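## Reverse complement of plain character patterns (vectorized).
.revcomp <- function(pats) {
  if (!length(pats)) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pats)))
}

## Canonical form: lexicographic minimum of a pattern and its reverse
## complement (a pattern and its RC are one candidate motif).
.canonical <- function(pats) pmin(pats, .revcomp(pats))

## Per-sequence sets of unique canonical k-mers (ZOOPS counting unit).
## Canonicalization happens once over the union of patterns.
.seq_kmer_sets <- function(seqs, k) {
  raw <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    subs <- unique(substring(s, 1:n, k:(k + n - 1)))
    subs[!grepl("[^ACGT]", subs)]
  })
  pats <- unique(unlist(raw, use.names = FALSE))
  if (!length(pats)) return(raw)
  canon <- stats::setNames(.canonical(pats), pats)
  lapply(raw, function(x) unique(canon[x]))
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' De novo discovery of enriched k-mer motifs
#'
#' A discriminative short-motif search in the spirit of regular-expression
#' motif elicitation: every literal k-mer present in the target sequences
#' (zero-or-one occurrence per sequence; a pattern and its reverse
#' complement collapse into one candidate) is tested for enrichment of
#' target-vs-background sequence counts with a one-sided Fisher exact test,
#' and its E-value is the p-value scaled by the number of candidate
#' patterns evaluated across all widths.  Candidates with `E <=
#' e_threshold` are ranked by ascending E-value and greedily deduplicated:
#' a motif within Hamming distance 1 (in either orientation) of a
#' better-ranked motif of equal width is dropped.
#'
#' @param targets,background sequence collections (character or
#'   `DNAStringSet`), both non-empty.
#' @param k_range motif widths to consider (default `6:8`).
#' @param e_threshold E-value cutoff (default 0.05).
#' @param max_motifs maximum number of motifs returned (default 25).
#' @return A data frame of class `kmer_motifs`: `pattern` (canonical
#'   orientation), `width`, target/background positive and total sequence
#'   counts, `p_fisher`, `e_value`.
#' @export
discover_enriched_kmers <- function(targets, background, k_range = 6:8,
                                    e_threshold = 0.05, max_motifs = 25) {
  if (!length(k_range)) stop("empty k_range")
  targets <- toupper(as.character(.as_dnastringset(targets)))
  background <- toupper(as.character(.as_dnastringset(background)))
  if (!length(targets) || !length(background))
    stop("both sequence collections must be non-empty")
  nt <- length(targets)
  nb <- length(background)
  rows <- list()
  n_candidates <- 0
  for (k in sort(unique(k_range))) {
    tcount <- table(unlist(.seq_kmer_sets(targets, k), use.names = FALSE))
    if (!length(tcount)) next
    bcount <- table(unlist(.seq_kmer_sets(background, k),
                           use.names = FALSE))
    pats <- names(tcount)
    n_candidates <- n_candidates + length(pats)
    a <- as.integer(tcount)
    b <- as.integer(bcount[pats])
    b[is.na(b)] <- 0L
    ## one-sided Fisher exact = hypergeometric upper tail on the 2x2 table
    ## with margins (nt, nb; a + b, nt + nb - a - b)
    p <- stats::phyper(a - 1, a + b, nt + nb - a - b, nt,
                       lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      pattern = pats, width = k, n_target = a, target_total = nt,
      n_background = b, background_total = nb, p_fisher = p,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(pattern = character(), width = integer(),
                     n_target = integer(), target_total = integer(),
                     n_background = integer(), background_total = integer(),
                     p_fisher = numeric(), e_value = numeric(),
                     stringsAsFactors = FALSE)
    class(df) <- c("kmer_motifs", "data.frame")
    return(df)
  }
  df$e_value <- pmin(df$p_fisher * n_candidates, Inf)
  df <- df[df$e_value <= e_threshold, , drop = FALSE]
  df <- df[order(df$e_value, df$p_fisher, df$pattern), , drop = FALSE]
  keep <- character(0)
  take <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- df$pattern[i]
    dup <- any(vapply(keep, function(q)
      nchar(q) == nchar(p) && (.hamming(p, q) <= 1 ||
                                 .hamming(p, .revcomp(q)) <= 1),
      logical(1)))
    if (!dup) {
      take[i] <- TRUE
      keep <- c(keep, p)
    }
    if (length(keep) >= max_motifs) break
  }
  out <- df[take, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kmer_motifs", "data.frame")
  out
}

## Mean per-column Pearson correlation of two aligned PWM blocks.
.column_correlation <- function(qa, qb) {
  mean(vapply(seq_len(nrow(qa)), function(i) {
    x <- qa[i, ]
    y <- qb[i, ]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      if (max(abs(x - y)) < 1e-9) 1 else 0
    } else {
      stats::cor(x, y)
    }
  }, numeric(1)))
}

#' Match a motif against a library of known motifs
#'
#' For every library motif, finds the best ungapped alignment of the query
#' over all offsets and both orientations, scored as the mean per-column
#' Pearson correlation of the base-probability columns over the overlap
#' (minimum overlap 4 columns), and returns the library ranked by
#' descending similarity.  A similarity surrogate for motif-comparison
#' tools; no alignment p-values are computed.
#'
#' @param query a [pwm()], or a consensus pattern / `kmer_motifs` row
#'   (converted with [pwm_from_kmer()]).
#' @param library non-empty named list of [pwm()] objects.
#' @param min_overlap minimum aligned columns (default 4).
#' @return A data frame `name`, `score`, `orientation` (`"+"`/`"-"`),
#'   `offset` (query start relative to the library motif), sorted by
#'   descending score.  Library motifs with no admissible offset are
#'   skipped with a warning.
#' @export
match_to_known_motifs <- function(query, library, min_overlap = 4) {
  if (!length(library)) stop("empty motif library")
  if (is.character(query)) query <- pwm_from_kmer(query)
  if (is.data.frame(query)) query <- pwm_from_kmer(query$pattern[1])
  stopifnot(inherits(query, "pwm"))
  q <- query$probs
  wq <- nrow(q)
  res <- lapply(names(library), function(nm) {
    lw <- library[[nm]]
    best <- NULL
    ## ties in score (common for repetitive motifs) break toward the
    ## longer overlap, then the smaller |offset|, then the + orientation
    for (orient in c("+", "-")) {
      l <- if (orient == "+") lw$probs else
        pwm_reverse_complement(lw)$probs
      wl <- nrow(l)
      for (off in seq(-(wq - min_overlap), wl - min_overlap)) {
        qi <- max(1, 1 - off):min(wq, wl - off)
        if (length(qi) < min_overlap) next
        li <- qi + off
        sc <- .column_correlation(q[qi, , drop = FALSE],
                                  l[li, , drop = FALSE])
        better <- is.null(best) || sc > best$score + 1e-12 ||
          (sc > best$score - 1e-12 &&
             (length(qi) > best$overlap ||
                (length(qi) == best$overlap && abs(off) < abs(best$offset))))
        if (better)
          best <- list(score = sc, orientation = orient, offset = off,
                       overlap = length(qi))
      }
    }
    if (is.null(best)) {
      warning("no alignment with >= ", min_overlap,
              " overlapping columns for motif ", nm, "; skipped")
      return(NULL)
    }
    data.frame(name = nm, score = best$score,
               orientation = best$orientation, offset = best$offset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(name = character(), score = numeric(),
                      orientation = character(), offset = integer()))
  out <- out[order(-out$score, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Divide peaks into motif-containing subsets
#'
#' `subset(m)` holds the peaks containing at least one occurrence of motif
#' `m` whose window lies fully inside the peak; `noMotif` holds the peaks
#' in no subset (negative-control annotation).  Motifs are excluded -- and
#' logged with the applied rule -- when they have no significant
#' occurrences, when `require_known_match` is set and they lack a known
#' match, or when their subset is smaller than `min_subset` peaks (the
#' size rule is also applied, and logged, for `noMotif`).
#'
#' @param peaks an `interval_set` with unique non-missing peak names.
#' @param occurrences a named list of occurrence data frames (one per
#'   motif, as from [scan_sequences()]) or a single data frame with a
#'   `motif` column.  `seq_id` values must resolve to peak names; offsets
#'   are peak-relative.
#' @param min_subset minimum peaks per tested subset (default 1000).
#' @param require_known_match drop motifs not named in `matched`.
#' @param matched motif names with a known-motif match.
#' @return A list with `subsets` (named list of `interval_set`s),
#'   `no_motif` (an `interval_set`, possibly excluded -- see log),
#'   `exclusions` (data frame `motif`, `rule`, `n_peaks`).
#' @export
subset_peaks_by_motif <- function(peaks, occurrences, min_subset = 1000,
                                  require_known_match = FALSE,
                                  matched = character()) {
  df <- peaks$df
  if (any(is.na(df$name)) || anyDuplicated(df$name))
    stop("peaks must have unique non-missing names")
  if (is.data.frame(occurrences))
    occurrences <- split(occurrences, occurrences$motif)
  peak_len <- stats::setNames(df$end - df$start, df$name)
  excl <- list()
  members <- list()
  for (m in names(occurrences)) {
    occ <- occurrences[[m]]
    unknown <- setdiff(unique(occ$seq_id), df$name)
    if (length(unknown))
      stop("occurrence seq_id does not resolve to a peak: ", unknown[1])
    contained <- occ$offset >= 0 &
      occ$offset + occ$width <= peak_len[occ$seq_id]
    ids <- unique(occ$seq_id[contained])
    if (!length(ids)) {
      excl[[m]] <- data.frame(motif = m,
                              rule = "no significant motif occurrences",
                              n_peaks = 0, stringsAsFactors = FALSE)
      next
    }
    if (require_known_match && !(m %in% matched)) {
      excl[[m]] <- data.frame(motif = m,
                              rule = "no match to a known motif",
                              n_peaks = length(ids),
                              stringsAsFactors = FALSE)
      next
    }
    members[[m]] <- ids
  }
  in_any <- df$name %in% unique(unlist(members, use.names = FALSE))
  no_motif_ids <- df$name[!in_any]
  subset_of <- function(ids, label) {
    sel <- df$name %in% ids
    interval_set(df$chrom[sel], df$start[sel], df$end[sel],
                 name = df$name[sel], label = label)
  }
  subsets <- list()
  for (m in names(members)) {
    if (length(members[[m]]) < min_subset) {
      excl[[m]] <- data.frame(
        motif = m, rule = sprintf("subset smaller than %d peaks",
                                  min_subset),
        n_peaks = length(members[[m]]), stringsAsFactors = FALSE)
    } else {
      subsets[[m]] <- subset_of(members[[m]], m)
    }
  }
  no_motif <- subset_of(no_motif_ids, "noMotif")
  if (length(no_motif_ids) < min_subset)
    excl[["noMotif"]] <- data.frame(
      motif = "noMotif", rule = sprintf("subset smaller than %d peaks",
                                        min_subset),
      n_peaks = length(no_motif_ids), stringsAsFactors = FALSE)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(motif = character(), rule = character(),
               n_peaks = integer(), stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  list(subsets = subsets, no_motif = no_motif, exclusions = exclusions)
}
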