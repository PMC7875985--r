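#' Enrichment test results
#'
#' Container for one (variant-set x annotation) enrichment test: the observed
#' statistic, the raw p-value, and its Bonferroni adjustment.
#'
#' @param method `"locus_shift"` or `"matched_control"`.
#' @param observed observed statistic (proportion of loci overlapping for the
#'   locus-shift test; count of overlapping loci for the matched-control
#'   test).
#' @param p_raw unadjusted p-value in `(0, 1]`.
#' @param n_tests Bonferroni factor (default 1, i.e. unadjusted).
#' @param n_null description of the null: permutation count, or a summary of
#'   control counts.
#' @param annotation_label label of the tested annotation.
#' @return An object of class `enrichment_result`.
#' @export
enrichment_result <- function(method, observed, p_raw, n_tests = 1,
                              n_null = NA, annotation_label = "") {
  stopifnot(method %in% c("locus_shift", "matched_control"),
            p_raw > 0, p_raw <= 1, n_tests >= 1)
  structure(list(method = method, observed = observed, p_raw = p_raw,
                 p_adjusted = bonferroni_adjust(p_raw, n_tests),
                 n_tests = n_tests, n_null = n_null,
                 annotation_label = annotation_label),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s test of %s: observed = %s, p = %.3g (adj. %.3g over %d tests)\n",
              x$method, x$annotation_label, format(x$observed), x$p_raw,
              x$p_adjusted, x$n_tests))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, p_raw * n_tests)`, delegated to [stats::p.adjust()].
#'
#' @param p_raw p-value(s) in `(0, 1]`.
#' @param n_tests number of tests in the family (`>= 1`).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p_raw, n_tests) {
  stopifnot(all(p_raw > 0), all(p_raw <= 1), n_tests >= 1,
            n_tests == floor(n_tests))
  stats::p.adjust(p_raw, method = "bonferroni", n = max(n_tests, length(p_raw)))
}

#' Upper tail of a Poisson-binomial distribution
#'
#' Exact `P(X >= s)` for `X` a sum of independent Bernoulli variables with
#' success probabilities `probs`, computed by dynamic-programming
#' convolution.  This is the null of the matched-control enrichment test.
#'
#' @param probs per-locus success probabilities in `[0, 1]`.
#' @param s observed count, `0 <= s <= length(probs)`.
#' @return `P(X >= s)`; 1 when `s == 0`.
#' @export
poisson_binomial_tail <- function(probs, s) {
  stopifnot(all(probs >= 0), all(probs <= 1), s >= 0, s == floor(s))
  n <- length(probs)
  if (s > n) stop("observed count s exceeds the number of loci")
  if (s == 0) return(1)
  f <- c(1, numeric(n))  # f[k+1] = P(X = k) over processed loci
  for (p in probs) {
    f <- c(f[1] * (1 - p), f[-1] * (1 - p) + f[-(n + 1)] * p)
  }
  min(sum(f[(s + 1):(n + 1)]), 1)
}

## ---- locus-shift (circular permutation) test --------------------------

## Shift window of a locus: the span extended on each side by
## max(flank_min, longest annotation interval intersecting the span).
.locus_shift_window <- function(locus, annotation, flank_min = 5e4) {
  span <- locus$span
  inter <- .intervals_overlapping(annotation, locus$chrom, span[1], span[2])
  longest <- if (nrow(inter)) max(inter$end - inter$start) else 0
  flank <- max(flank_min, longest)
  c(span[1] - flank, span[2] + flank)
}

## Offsets d in [0, W) under which some locus variant is covered by the
## annotation circularly shifted by d within the window.  Returns merged
## integer intervals (inclusive starts/ends), the window width W, and the
## number of favourable offsets.  A variant at relative position p and an
## interval [a, b) give the favourable range [p - b + 1, p - a] mod W.
.favorable_offsets <- function(locus, annotation, window) {
  ws <- window[1]
  we <- window[2]
  w_len <- we - ws
  ann <- .intervals_overlapping(annotation, locus$chrom, ws, we)
  if (nrow(ann) && any(ann$end - ann$start > w_len))
    warning("annotation interval longer than the shift window of locus ",
            locus$index$id, "; clipped")
  if (nrow(ann) == 0)
    return(list(starts = numeric(0), ends = numeric(0), W = w_len,
                measure = 0))
  a <- pmax(ann$start, ws) - ws
  b <- pmin(ann$end, we) - ws
  p <- .locus_positions(locus) - ws
  lo <- as.vector(outer(p + 1, b, "-"))  # p - b + 1
  hi <- as.vector(outer(p, a, "-"))      # p - a
  lo <- lo %% w_len
  hi <- hi %% w_len
  wrap <- lo > hi
  starts <- c(lo[!wrap], rep(0, sum(wrap)), lo[wrap])
  ends <- c(hi[!wrap], hi[wrap], rep(w_len - 1, sum(wrap)))
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  ## merge overlapping/adjacent integer ranges
  ms <- me <- numeric(length(starts))
  k <- 0
  for (t in seq_along(starts)) {
    if (k > 0 && starts[t] <= me[k] + 1) {
      me[k] <- max(me[k], ends[t])
    } else {
      k <- k + 1
      ms[k] <- starts[t]
      me[k] <- ends[t]
    }
  }
  ms <- ms[seq_len(k)]
  me <- me[seq_len(k)]
  list(starts = ms, ends = me, W = w_len, measure = sum(me - ms + 1))
}

.offsets_hit <- function(fav, d) {
  if (length(fav$starts) == 0) return(rep(FALSE, length(d)))
  idx <- findInterval(d, fav$starts)
  hit <- idx > 0
  hit[hit] <- d[hit] <= fav$ends[idx[hit]]
  hit
}

#' Locus-shift permutation test of annotation enrichment
#'
#' The observed statistic is the proportion of risk loci where the index
#' variant or any LD proxy falls inside an annotation interval.  The null is
#' generated by circularly shifting, independently for each locus and
#' permutation, all annotation intervals within the locus window by one
#' shared uniform offset (wrapping around the window), preserving local
#' annotation density and spacing.  The permutation p-value uses the add-one
#' estimator `(1 + k) / (1 + n_perm)` with ties counting toward rejection.
#'
#' The shift window is the locus span plus a flank of
#' `max(flank_min, longest annotation interval intersecting the span)` on
#' each side, so that every overlapping interval can also shift off the
#' variants.
#'
#' @param loci non-empty list of `risk_locus` objects.
#' @param annotation an `interval_set` (normalized internally).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed; the test is bit-reproducible given it.
#' @param exhaustive if `TRUE` (single-locus aid), enumerate all integer
#'   offsets instead of sampling; then `p_raw = #{offsets with statistic >=
#'   observed} / #offsets`.
#' @param flank_min minimum flank in bases (default 50 kb).
#' @param windows optional list of explicit `c(start, end)` shift windows,
#'   one per locus, overriding the span-plus-flank rule (diagnostic aid).
#' @return An [enrichment_result()] with `method = "locus_shift"`.
#' @export
locus_shift_test <- function(loci, annotation, n_perm = 10000, seed = NULL,
                             exhaustive = FALSE, flank_min = 5e4,
                             windows = NULL) {
  if (!length(loci)) stop("empty locus list")
  annotation <- .ensure_normalized(annotation)
  stopifnot(exhaustive || n_perm >= 1,
            is.null(windows) || length(windows) == length(loci))
  fav <- lapply(seq_along(loci), function(i)
    .favorable_offsets(loci[[i]], annotation,
                       if (is.null(windows))
                         .locus_shift_window(loci[[i]], annotation,
                                             flank_min)
                       else windows[[i]]))
  obs_ind <- vapply(loci, .locus_overlaps, logical(1),
                    annotation = annotation)
  obs_count <- sum(obs_ind)
  n <- length(loci)
  if (exhaustive) {
    if (n != 1)
      stop("exhaustive enumeration is supported for a single locus only")
    f <- fav[[1]]
    p_raw <- if (obs_count == 1) f$measure / f$W else 1
    p_raw <- max(p_raw, .Machine$double.xmin)
    return(enrichment_result("locus_shift", observed = obs_count / n,
                             p_raw = p_raw, n_null = f$W,
                             annotation_label = annotation$label))
  }
  run <- function() {
    perm_counts <- integer(n_perm)
    for (i in seq_len(n)) {
      d <- floor(stats::runif(n_perm) * fav[[i]]$W)
      perm_counts <- perm_counts + .offsets_hit(fav[[i]], d)
    }
    perm_counts
  }
  perm_counts <- if (is.null(seed)) run() else
    withr::with_seed(seed, run())
  p_raw <- (1 + sum(perm_counts >= obs_count)) / (1 + n_perm)
  enrichment_result("locus_shift", observed = obs_count / n, p_raw = p_raw,
                    n_null = n_perm, annotation_label = annotation$label)
}

## ---- matched-control (SNP-matching) test ------------------------------

#' Matching bins for control-variant selection
#'
#' Control variants are matched to index variants on three covariates:
#' number of LD proxies, minor allele frequency, and distance to the nearest
#' gene.  Matching is by shared bin triple.
#'
#' @param ld_breaks increasing lower bin edges for the LD-proxy count;
#'   default bins `{0-1, 2-5, 6-10, 11-25, 26-50, >50}`.
#' @param maf_width width of the MAF bins on `[0, 0.5]` (default 0.05).
#' @param dist_breaks increasing lower edges for gene distance; default bins
#'   `{<1 kb, 1-10 kb, 10-100 kb, 100 kb-1 Mb, >= 1 Mb}` (the last bin also
#'   holds the unmatched-chromosome sentinel `Inf`).
#' @param min_controls minimum matched controls required per index variant
#'   (default 500).
#' @return An object of class `matching_bins`.
#' @export
matching_bins <- function(ld_breaks = c(0, 2, 6, 11, 26, 51),
                          maf_width = 0.05,
                          dist_breaks = c(0, 1e3, 1e4, 1e5, 1e6),
                          min_controls = 500) {
  stopifnot(all(diff(ld_breaks) > 0), all(diff(dist_breaks) > 0),
            maf_width > 0, min_controls >= 1)
  structure(list(ld_breaks = ld_breaks, maf_width = maf_width,
                 dist_breaks = dist_breaks, min_controls = min_controls),
            class = "matching_bins")
}

.covariate_bin <- function(ld_count, maf, dist, bins) {
  paste0("L", findInterval(ld_count, bins$ld_breaks),
         "|M", findInterval(maf, seq(0, 0.5, by = bins$maf_width),
                            rightmost.closed = TRUE),
         "|D", findInterval(dist, bins$dist_breaks))
}

#' Build a matched-control pool from a haplotype panel
#'
#' Expands every panel variant into a locus (LD proxies at
#' `r2 > r2_threshold` within `window`), computes the three matching
#' covariates and the bin triple, and records which pool variants can
#' actually serve as index variants (at least `bins$min_controls` matched
#' controls surviving LD exclusion).
#'
#' @param panel a [haplotype_panel()].
#' @param genes a [gene_annotation()] (same one used for the index
#'   variants).
#' @param bins a [matching_bins()].
#' @param r2_threshold,window LD-proxy definition (defaults 0.8 and 1 Mb).
#' @param exclude_ids variant ids to drop from the pool (e.g. study index
#'   variants).
#' @return An object of class `control_pool`.
#' @export
control_pool <- function(panel, genes, bins = matching_bins(),
                         r2_threshold = 0.8, window = 1e6,
                         exclude_ids = NULL) {
  v <- panel$variants
  proxy_cols <- .all_proxy_cols(panel, r2_threshold, window)
  keep <- which(!(v$id %in% exclude_ids) & v$maf > 0)
  tab <- data.frame(id = v$id[keep], col = keep, chrom = v$chrom[keep],
                    pos = v$pos[keep], maf = v$maf[keep],
                    ld_count = lengths(proxy_cols)[keep],
                    stringsAsFactors = FALSE)
  tab$gene_dist <- distance_to_nearest_gene(tab$chrom, tab$pos, genes)
  tab$bin <- .covariate_bin(tab$ld_count, tab$maf, tab$gene_dist, bins)
  ## flat position table (index + proxies) for fast overlap computation
  npos <- 1L + tab$ld_count
  prox <- proxy_cols[keep]
  pos_tab <- data.frame(
    row = rep(seq_len(nrow(tab)), npos),
    chrom = rep(tab$chrom, npos),
    pos = unlist(lapply(seq_len(nrow(tab)), function(k)
      c(tab$pos[k], v$pos[prox[[k]]])), use.names = FALSE))
  pool <- structure(list(panel = panel, table = tab, positions = pos_tab,
                        proxy_cols = proxy_cols, bins = bins,
                        r2_threshold = r2_threshold, window = window,
                        cache = new.env(parent = emptyenv())),
                   class = "control_pool")
  ## eligibility: LD exclusion can drop at most ld_count bin mates, so
  ## most variants are decided by counting; only borderline ones need the
  ## exact matched-row computation
  bin_size <- table(tab$bin)
  n_bin <- as.integer(bin_size[tab$bin])
  eligible <- (n_bin - 1L - tab$ld_count) >= bins$min_controls
  border <- which(!eligible & (n_bin - 1L) >= bins$min_controls)
  for (k in border)
    eligible[k] <- length(.matched_rows(pool, tab$col[k], tab$bin[k])) >=
      bins$min_controls
  pool$eligible <- eligible
  pool
}

#' @export
print.control_pool <- function(x, ...) {
  cat("control_pool:", nrow(x$table), "candidate loci,",
      sum(x$eligible), "eligible as index;",
      length(unique(x$table$bin)), "occupied covariate bins\n")
  invisible(x)
}

## Pool rows matched to panel column `col` with covariate bin `bin`: same
## bin, not the variant itself, not in LD (r2 > threshold) with it.
## Ordered by id.
.matched_rows <- function(pool, col, bin) {
  v <- pool$panel$variants
  rows <- which(pool$table$bin == bin & pool$table$col != col)
  if (!length(rows)) return(integer(0))
  ## LD exclusion only applies on the same chromosome within the window
  same <- pool$table$chrom[rows] == v$chrom[col] &
    abs(pool$table$pos[rows] - v$pos[col]) <= pool$window
  if (any(same)) {
    r2 <- .r2_profile(pool$panel, col, pool$table$col[rows[same]])
    drop <- !is.na(r2) & r2 > pool$r2_threshold
    rows <- c(rows[!same], rows[same][!drop])
  }
  rows[order(pool$table$id[rows])]
}

#' Select matched control variants for one risk locus
#'
#' Returns the pool loci sharing the index variant's (LD count, MAF, gene
#' distance) bin triple, excluding the index itself and any pool variant in
#' LD (`r2 > threshold`) with it, in deterministic id order.
#'
#' @param locus a `risk_locus` (its index must come from the pool's panel).
#' @param pool a [control_pool()] built with the same panel and genes.
#' @param genes the [gene_annotation()] used for distance matching.
#' @return A data frame of matched pool rows.
#' @export
select_matched_controls <- function(locus, pool, genes) {
  col <- .panel_col(pool$panel, locus$index$id)
  bin <- .covariate_bin(nrow(locus$proxies), locus$index$maf,
                        distance_to_nearest_gene(locus$chrom,
                                                 locus$index$pos, genes),
                        pool$bins)
  rows <- .matched_rows(pool, col, bin = bin)
  if (length(rows) < pool$bins$min_controls)
    stop("insufficient controls for index ", locus$index$id, " (bin ", bin,
         "): ", length(rows), " matched, ", pool$bins$min_controls,
         " required")
  pool$table[rows, , drop = FALSE]
}

## Overlap indicator of every pool locus with an annotation.  rowsum sorts
## groups numerically and every row 1..n is present, so row k of the result
## is pool locus k.
.pool_overlap <- function(pool, annotation) {
  hit <- .positions_in_set(annotation, pool$positions$chrom,
                           pool$positions$pos)
  as.vector(rowsum(as.integer(hit), pool$positions$row) > 0)
}

#' Matched-control enrichment test (Poisson-binomial null)
#'
#' Counts the risk loci whose index variant or an LD proxy overlaps the
#' annotation, then compares the count to its expectation under matched
#' control variants: for each locus the per-locus null probability is the
#' fraction of its matched controls whose locus overlaps the annotation
#' (floored at `1/(n+1)` and capped at `n/(n+1)` for `n` controls), and the
#' p-value is the exact upper Poisson-binomial tail at the observed count.
#'
#' @param loci non-empty list of `risk_locus` objects.
#' @param annotation an `interval_set`.
#' @param pool a [control_pool()].
#' @param genes the [gene_annotation()] used for matching.
#' @return An [enrichment_result()] with `method = "matched_control"`;
#'   `observed` is the overlap count.
#' @export
matched_control_test <- function(loci, annotation, pool, genes) {
  if (!length(loci)) stop("empty locus list")
  annotation <- .ensure_normalized(annotation)
  ov <- .pool_overlap(pool, annotation)
  s <- sum(vapply(loci, .locus_overlaps, logical(1),
                  annotation = annotation))
  ## control ids per index are annotation-independent; memoized in the pool
  ctrl_rows <- lapply(loci, function(l) {
    key <- l$index$id
    if (!is.null(pool$cache[[key]])) return(pool$cache[[key]])
    rows <- match(select_matched_controls(l, pool, genes)$id,
                  pool$table$id)
    pool$cache[[key]] <- rows
    rows
  })
  probs <- vapply(ctrl_rows, function(rows) {
    n <- length(rows)
    min(max(mean(ov[rows]), 1 / (n + 1)), n / (n + 1))
  }, numeric(1))
  p_raw <- poisson_binomial_tail(probs, s)
  enrichment_result("matched_control", observed = s, p_raw = p_raw,
                    n_null = stats::median(lengths(ctrl_rows)),
                    annotation_label = annotation$label)
}

#' Tabulate paired enrichment results
#'
#' Combines locus-shift and matched-control results for a family of
#' annotations into one table mirroring the reporting layout of dual-test
#' enrichment analyses, with Bonferroni adjustment over the family and the
#' dual-significance rule (both adjusted p-values below `alpha`).
#'
#' @param ls_results,mc_results lists of [enrichment_result()] objects of
#'   the two methods, aligned by annotation.
#' @param n_intervals interval counts of the annotations (reported).
#' @param alpha significance level for the dual rule (default 0.05).
#' @return A data frame with one row per annotation.
#' @export
enrichment_report <- function(ls_results, mc_results, n_intervals = NA,
                              alpha = 0.05) {
  stopifnot(length(ls_results) == length(mc_results))
  n_tests <- length(ls_results)
  df <- data.frame(
    label = vapply(ls_results, `[[`, "", "annotation_label"),
    n_intervals = n_intervals,
    shift_observed = vapply(ls_results, `[[`, 0, "observed"),
    shift_p = vapply(ls_results, `[[`, 0, "p_raw"),
    matched_observed = vapply(mc_results, `[[`, 0, "observed"),
    matched_p = vapply(mc_results, `[[`, 0, "p_raw"),
    stringsAsFactors = FALSE)
  df$shift_p_adj <- bonferroni_adjust(df$shift_p, n_tests)
  df$matched_p_adj <- bonferroni_adjust(df$matched_p, n_tests)
  df$n_tests <- n_tests
  df$dual_significant <- df$shift_p_adj < alpha & df$matched_p_adj < alpha
  df <- df[order(df$shift_p_adj, df$matched_p_adj), , drop = FALSE]
  rownames(df) <- make.unique(df$label)
  df
}

#' @rdname enrichment_report
#' @param df a report data frame.
#' @param path output TSV path.
#' @export
write_enrichment_report <- function(df, path) {
  utils::write.table(format(df, digits = 6, scientific = 10), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
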