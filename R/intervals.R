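#' Genomic interval sets
#'
#' An `interval_set` holds genomic intervals in BED conventions: 0-based,
#' half-open `[start, end)` coordinates, chromosome names compared as opaque
#' strings (`"chr1" != "1"`).  It is the unit of overlap arithmetic and
#' Jaccard similarity between annotation sets (e.g. ATAC-seq peak sets).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors, 0-based half-open; `0 <= start < end`.
#' @param name optional interval labels (e.g. peak identifiers).
#' @param label a name for the whole set (e.g. `"STC"`).
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, name = NULL, label = "") {
  n <- length(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chromosome names must be non-empty strings")
    bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
    if (length(bad))
      stop("invalid interval at row ", bad[1],
           ": need 0 <= start < end, got [", start[bad[1]], ", ",
           end[bad[1]], ")")
  }
  if (is.null(name)) name <- rep(NA_character_, n)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), stringsAsFactors = FALSE)
  structure(list(df = df, label = label, normalized = FALSE),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set", if (nzchar(x$label)) sQuote(x$label) else "",
      "with", nrow(x$df), "intervals on",
      length(unique(x$df$chrom)), "chromosome(s);",
      format(total_bases(x), big.mark = ","), "bases",
      if (x$normalized) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' @rdname interval_set
#' @param x an `interval_set`.
#' @export
n_intervals <- function(x) nrow(x$df)

#' Total covered bases of an interval set
#'
#' Sum of `end - start` over the intervals as stored.  Only after
#' [normalize_intervals()] does this equal the number of distinct covered
#' positions.
#'
#' @param x an `interval_set`.
#' @return A non-negative number of bases.
#' @export
total_bases <- function(x) {
  if (nrow(x$df) == 0) return(0)
  sum(x$df$end - x$df$start)
}

## interval_set <-> GRanges (internal; GRanges is 1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$df$chrom,
    ranges = IRanges::IRanges(start = x$df$start + 1, end = x$df$end))
}

.granges_to_set <- function(gr, label, normalized = FALSE) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   name = NA_character_, stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start)
  structure(list(df = df[o, , drop = FALSE], label = label,
                 normalized = normalized), class = "interval_set")
}

#' Read a BED3+ file into an interval set
#'
#' Parses tab-separated BED records (0-based half-open).  Columns beyond the
#' fourth are ignored; column 4, when present, is kept as the interval name.
#' Lines starting with `track`, `browser` or `#` are skipped.  Malformed
#' records (non-integer or negative coordinates, `start >= end`) raise an
#' error naming the offending line.
#'
#' @param path path to a BED file.
#' @param label set label; defaults to the file name without extension.
#' @return An `interval_set` in raw file order.
#' @export
read_bed <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    warning("no records in ", path, "; returning an empty set")
    return(interval_set(character(), numeric(), numeric(), label = label))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("line ", idx[bad[1]], ": start/end do not parse as integers")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("line ", idx[bad[1]], ": need 0 <= start < end, got [",
         start[bad[1]], ", ", end[bad[1]], ")")
  name <- ifelse(nf >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  interval_set(chrom, start, end, name = name, label = label)
}

#' Write an interval set as BED
#'
#' @param x an `interval_set`.
#' @param path output path.  Writes BED3, or BED4 when any name is set.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- x$df
  cols <- c("chrom", "start", "end")
  if (any(!is.na(df$name))) {
    df$name[is.na(df$name)] <- "."
    cols <- c(cols, "name")
  }
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize an interval set
#'
#' Sorts intervals and merges any that overlap or are bookended
#' (`[0,10)` + `[10,20)` becomes `[0,20)`), per chromosome.  Idempotent.
#' Jaccard similarity is defined on normalized sets; interval names are
#' dropped by merging.
#'
#' @param x an `interval_set`.
#' @return A normalized `interval_set` with the same label.
#' @export
normalize_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  if (nrow(x$df) == 0) {
    x$normalized <- TRUE
    return(x)
  }
  out <- .granges_to_set(GenomicRanges::reduce(.as_granges(x)),
                         label = x$label, normalized = TRUE)
  out
}

.ensure_normalized <- function(x) if (isTRUE(x$normalized)) x else
  normalize_intervals(x)

#' Jaccard similarity of two interval sets
#'
#' Base-level Jaccard statistic: intersection bases over union bases, so 0
#' means no overlap and 1 full overlap.  Inputs are normalized first if
#' needed.  Two empty sets return 0 by convention (keeps pairwise matrices
#' total).
#'
#' @param a,b `interval_set` objects.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- .ensure_normalized(a)
  b <- .ensure_normalized(b)
  if (nrow(a$df) == 0 && nrow(b$df) == 0) return(0)
  ga <- .as_granges(a)
  gb <- .as_granges(b)
  lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lev
  GenomeInfoDb::seqlevels(gb) <- lev
  inter <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(ga, gb))))
  uni <- sum(as.numeric(GenomicRanges::width(GenomicRanges::union(ga, gb))))
  if (uni == 0) return(0)
  inter / uni
}

#' Pairwise Jaccard matrix over annotation sets
#'
#' @param sets a list of `interval_set` objects (at least one).
#' @return A symmetric numeric matrix with row/column names taken from set
#'   labels; the diagonal is 1 for non-empty sets (0 for empty ones, matching
#'   the empty-set convention of [jaccard_similarity()]).
#' @export
pairwise_jaccard <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  sets <- lapply(sets, .ensure_normalized)
  labels <- vapply(seq_along(sets), function(i) {
    l <- sets[[i]]$label
    if (nzchar(l)) l else paste0("set", i)
  }, "")
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- jaccard_similarity(sets[[i]], sets[[j]])
    }
  }
  m
}

#' Write a Jaccard matrix as a labelled TSV table
#'
#' @param m matrix from [pairwise_jaccard()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaccard_matrix <- function(m, path) {
  utils::write.table(data.frame(set = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Membership of point positions (0-based) in a normalized set; vectorized.
.positions_in_set <- function(x, chrom, pos) {
  x <- .ensure_normalized(x)
  out <- logical(length(pos))
  if (nrow(x$df) == 0 || length(pos) == 0) return(out)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- x$df[x$df$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    idx <- findInterval(pos[sel], sub$start)
    hit <- idx > 0
    hit[hit] <- pos[sel][hit] < sub$end[idx[hit]]
    out[sel] <- hit
  }
  out
}

## Intervals of a normalized set overlapping [start, end) on chrom.
.intervals_overlapping <- function(x, chrom, start, end) {
  x <- .ensure_normalized(x)
  sub <- x$df[x$df$chrom == chrom, , drop = FALSE]
  sub[sub$start < end & sub$end > start, , drop = FALSE]
}
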