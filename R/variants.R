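#' Variant tables
#'
#' A variant table is a data frame with columns `id`, `chrom`, `pos`
#' (0-based) and optionally `maf` (minor allele frequency in `[0, 0.5]`).
#'
#' @param id character variant identifiers (unique).
#' @param chrom chromosome names.
#' @param pos 0-based positions.
#' @param maf optional minor allele frequencies.
#' @return A validated data frame of class `variant_table`.
#' @export
variant_table <- function(id, chrom, pos, maf = NA_real_) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   pos = as.numeric(pos), maf = as.numeric(maf),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("variant ids must be unique")
  if (any(df$pos < 0)) stop("positions must be >= 0")
  ok <- is.na(df$maf) | (df$maf >= 0 & df$maf <= 0.5)
  if (!all(ok)) stop("maf must lie in [0, 0.5] when set")
  class(df) <- c("variant_table", "data.frame")
  df
}

#' @rdname variant_table
#' @param path tab-separated file with header columns `id`, `chrom`, `pos`
#'   and optionally `maf`.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  variant_table(df$id, df$chrom, df$pos,
                if ("maf" %in% names(df)) df$maf else NA_real_)
}

#' @rdname variant_table
#' @param x a `variant_table`.
#' @export
write_variants <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation for distance matching
#'
#' Stores transcription start sites per chromosome (sorted).  Used to match
#' control variants on distance to the nearest gene.
#'
#' @param chrom chromosome of each TSS.
#' @param tss 0-based TSS positions.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(chrom, tss) {
  stopifnot(length(chrom) == length(tss), all(tss >= 0))
  sp <- split(as.numeric(tss), as.character(chrom))
  structure(list(tss = lapply(sp, sort)), class = "gene_annotation")
}

#' @rdname gene_annotation
#' @param path two-column tab-separated file (`chrom`, `tss`), with header.
#' @export
read_gene_tss <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "tss") %in% names(df)))
    stop("gene table needs columns: chrom, tss")
  gene_annotation(df$chrom, df$tss)
}

#' @rdname gene_annotation
#' @param x a `gene_annotation`.
#' @export
write_gene_tss <- function(x, path) {
  df <- data.frame(
    chrom = rep(names(x$tss), lengths(x$tss)),
    tss = unlist(x$tss, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Distance from a position to the nearest transcription start site
#'
#' Vectorized over positions.  A position on a chromosome with no TSS gets
#' the sentinel `Inf` ("unmatched chromosome").
#'
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based position(s).
#' @param genes a [gene_annotation()].
#' @return Numeric vector of distances in bases.
#' @export
distance_to_nearest_gene <- function(chrom, pos, genes) {
  stopifnot(inherits(genes, "gene_annotation"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- rep(Inf, n)
  for (ch in unique(chrom)) {
    tss <- genes$tss[[ch]]
    if (is.null(tss) || length(tss) == 0) next
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], tss)
    lo <- ifelse(idx >= 1, abs(pos[sel] - tss[pmax(idx, 1)]), Inf)
    hi <- ifelse(idx < length(tss), abs(tss[pmin(idx + 1, length(tss))] -
                                          pos[sel]), Inf)
    out[sel] <- pmin(lo, hi)
  }
  out
}

#' Haplotype panel
#'
#' A phased reference panel: a haplotypes-by-variants 0/1 allele matrix plus
#' the aligned variant table.  Minor allele frequencies are (re)computed from
#' the panel as `min(f, 1 - f)` where `f` is the column mean.
#'
#' @param alleles integer/numeric matrix with entries in `{0, 1}`; rows are
#'   haplotypes (at least 2), columns are variants.
#' @param variants a [variant_table()] with one row per column of `alleles`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, variants) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) < 2) stop("a panel needs at least 2 haplotypes")
  if (!all(alleles %in% c(0, 1))) stop("allele entries must be 0 or 1")
  if (ncol(alleles) != nrow(variants))
    stop("column count must equal the number of variants")
  f <- colMeans(alleles)
  variants$maf <- pmin(f, 1 - f)
  storage.mode(alleles) <- "integer"
  colnames(alleles) <- variants$id
  structure(list(alleles = alleles, variants = variants),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @rdname haplotype_panel
#' @param alleles_path plain matrix file (tab-separated 0/1, no header; rows
#'   are haplotypes).
#' @param variants_path variant table for [read_variants()].
#' @export
read_haplotype_panel <- function(alleles_path, variants_path) {
  m <- as.matrix(utils::read.table(alleles_path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  haplotype_panel(m, read_variants(variants_path))
}

#' @rdname haplotype_panel
#' @param x a `haplotype_panel`.
#' @param dir directory receiving `haplotypes.tsv` and `variants.tsv`.
#' @export
write_haplotype_panel <- function(x, dir) {
  utils::write.table(x$alleles, file.path(dir, "haplotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_variants(x$variants, file.path(dir, "variants.tsv"))
  invisible(dir)
}

.panel_col <- function(panel, v) {
  if (is.character(v)) {
    i <- match(v, panel$variants$id)
    if (is.na(i)) stop("variant not in panel: ", v)
    i
  } else {
    stopifnot(v >= 1, v <= ncol(panel$alleles))
    as.integer(v)
  }
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Computed from phased haplotypes as `D^2 / (pA qA pB qB)` with
#' `D = pAB - pA pB`, where `pA`, `pB` are allele frequencies and `pAB` the
#' haplotype frequency of the 1/1 configuration.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j variant ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(panel, i, j) {
  i <- .panel_col(panel, i)
  j <- .panel_col(panel, j)
  x <- panel$alleles[, i]
  y <- panel$alleles[, j]
  pa <- mean(x)
  pb <- mean(y)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("LD is undefined for a monomorphic variant")
  d <- mean(x * y) - pa * pb
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  min(max(r2, 0), 1)
}

## r2 of column i against columns js (vectorized); NA where monomorphic.
.r2_profile <- function(panel, i, js) {
  x <- panel$alleles[, i]
  m <- panel$alleles[, js, drop = FALSE]
  pa <- mean(x)
  pb <- colMeans(m)
  pab <- as.numeric(crossprod(x, m)) / nrow(m)
  d <- pab - pa * pb
  den <- pa * (1 - pa) * pb * (1 - pb)
  out <- d^2 / den
  out[den == 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

.new_risk_locus <- function(index, proxies, window) {
  pos <- c(index$pos, proxies$pos)
  structure(list(index = index, proxies = proxies, chrom = index$chrom,
                 span = c(start = min(pos), end = max(pos) + 1),
                 window = window),
            class = "risk_locus")
}

#' @export
print.risk_locus <- function(x, ...) {
  cat("risk_locus", x$index$id, "at", x$chrom, x$index$pos, "with",
      nrow(x$proxies), "LD proxies; span [", x$span[1], ",", x$span[2],
      ")\n")
  invisible(x)
}

#' Expand an index variant into a risk locus of LD proxies
#'
#' Proxies are all other panel variants on the index chromosome within
#' `window` bases (inclusive, centre-to-centre) with strictly
#' `r2 > r2_threshold`.  The locus span covers the index and all proxies.
#'
#' @param panel a [haplotype_panel()].
#' @param index variant id or column index (must be polymorphic).
#' @param r2_threshold LD threshold; default `0.8` (strict inequality).
#' @param window maximum index-to-proxy distance in bases (default 1 Mb).
#' @return An object of class `risk_locus`.
#' @export
find_proxies <- function(panel, index, r2_threshold = 0.8, window = 1e6) {
  i <- .panel_col(panel, index)
  v <- panel$variants
  if (v$maf[i] <= 0) stop("index variant is monomorphic: ", v$id[i])
  cand <- which(v$chrom == v$chrom[i] &
                  abs(v$pos - v$pos[i]) <= window &
                  seq_len(nrow(v)) != i)
  idx_row <- as.list(v[i, , drop = FALSE])
  if (length(cand) == 0)
    return(.new_risk_locus(idx_row,
                           cbind(v[0, , drop = FALSE], r2 = numeric(0)),
                           window))
  r2 <- .r2_profile(panel, i, cand)
  keep <- which(!is.na(r2) & r2 > r2_threshold)
  proxies <- v[cand[keep], , drop = FALSE]
  proxies$r2 <- r2[keep]
  proxies <- proxies[order(proxies$id), , drop = FALSE]
  rownames(proxies) <- NULL
  .new_risk_locus(idx_row, proxies, window)
}

## 0-based positions (index + proxies) of a risk locus.
.locus_positions <- function(locus) c(locus$index$pos, locus$proxies$pos)

## Does the locus (index or any proxy) overlap the annotation?
.locus_overlaps <- function(locus, annotation) {
  any(.positions_in_set(annotation, rep(locus$chrom,
                                        1 + nrow(locus$proxies)),
                        .locus_positions(locus)))
}

#' Drop risk loci whose index variant lies in the MHC region
#'
#' The extended major histocompatibility complex region has unusually long
#' LD; sensitivity analyses exclude risk signals whose index variant falls in
#' it.  The region is half-open `[start, end)` and applied to the index
#' position only.
#'
#' @param loci list of `risk_locus` objects.
#' @param chrom,start,end region definition; default chr6 26-34 Mb.
#' @return The filtered list, in the original order.  Idempotent.
#' @export
filter_mhc <- function(loci, chrom = "chr6", start = 26e6, end = 34e6) {
  keep <- vapply(loci, function(l)
    !(l$chrom == chrom && l$index$pos >= start && l$index$pos < end),
    logical(1))
  loci[keep]
}

## All-pairs proxy computation for a panel: per-chromosome r2 by crossprod.
## Returns a list of integer vectors (proxy columns per variant).
.all_proxy_cols <- function(panel, r2_threshold = 0.8, window = 1e6) {
  v <- panel$variants
  out <- vector("list", nrow(v))
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    m <- panel$alleles[, cols, drop = FALSE]
    h <- nrow(m)
    p <- colMeans(m)
    pab <- crossprod(m) / h
    d <- pab - outer(p, p)
    den <- outer(p * (1 - p), p * (1 - p))
    r2 <- d^2 / den
    r2[den == 0] <- NA
    pos <- v$pos[cols]
    near <- abs(outer(pos, pos, "-")) <= window
    hit <- !is.na(r2) & r2 > r2_threshold & near
    diag(hit) <- FALSE
    for (k in seq_along(cols)) out[[cols[k]]] <- cols[hit[, k]]
  }
  out
}
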