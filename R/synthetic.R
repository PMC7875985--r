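#' Configuration of a synthetic enrichment study
#'
#' Defines the study conditions for a fully synthetic analogue of a
#' GWAS-variants-versus-open-chromatin enrichment analysis: an i.i.d.
#' genome with tunable GC, disjoint peaks carrying planted motif
#' instances, an LD-block structured haplotype panel, risk loci with a
#' controllable excess overlap of a designated peak subset (the planted
#' enrichment effect), matched-control pools and negative-control variant
#' sets.  Every quantity downstream derives deterministically from `seed`.
#'
#' @param seed integer master seed (default 20210210).
#' @param n_chrom,chrom_length genome shape (default 2 chromosomes x 2 Mb).
#' @param gc_content genomic GC fraction (default 0.41, the human value).
#' @param n_peaks,peak_length_mean,peak_length_sd,peak_length_min focus
#'   peak-set geometry (default 500 peaks, 300 +/- 60 bp, >= 100 bp).
#' @param motif_set named character vector of consensus patterns planted
#'   into peaks (default one 8-bp E-box-core motif, `GCAGCTGC`).
#' @param plant_rate fraction of focus peaks receiving each motif
#'   (default 0.3).
#' @param n_haplotypes,n_variants,block_length,mutation_rate,maf_min
#'   haplotype-panel shape: haplotype count, retained variant count, LD
#'   block length, per-site mutation probability off the block founders,
#'   and minimum retained minor allele frequency (defaults 200, 2000,
#'   20 kb, 0.02, 0.05).
#' @param n_loci number of risk signals (default 60).
#' @param effect planted enrichment: the fraction of index variants drawn
#'   conditional on their locus overlapping the target subset (default 0,
#'   i.e. no effect).
#' @param n_control_sets negative-control variant sets (default 2).
#' @param n_genes TSS count for distance matching (default 60).
#' @param n_decoys additional unrelated annotation peak sets (default 3).
#' @param n_background background sequences for motif discovery
#'   (default 500).
#' @param r2_threshold,ld_window LD-proxy definition (0.8, 1 Mb).
#' @param min_controls minimum matched controls per index variant at this
#'   synthetic scale (default 10; the full-scale module default of 500
#'   presumes a genome-wide variant pool).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 20210210, n_chrom = 2,
                             chrom_length = 2e6, gc_content = 0.41,
                             n_peaks = 500, peak_length_mean = 300,
                             peak_length_sd = 60, peak_length_min = 100,
                             motif_set = c(ebox8 = "GCAGCTGC"),
                             plant_rate = 0.3, n_haplotypes = 200,
                             n_variants = 2000, block_length = 2e4,
                             mutation_rate = 0.02, maf_min = 0.05,
                             n_loci = 60, effect = 0, n_control_sets = 2,
                             n_genes = 60, n_decoys = 3,
                             n_background = 500, r2_threshold = 0.8,
                             ld_window = 1e6, min_controls = 10) {
  cfg <- as.list(environment())
  fracs <- c(gc_content = gc_content, plant_rate = plant_rate,
             mutation_rate = mutation_rate, effect = effect,
             maf_min = maf_min)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  pos <- c(n_chrom, chrom_length, n_peaks, peak_length_mean,
           n_haplotypes, n_variants, block_length, n_loci, n_genes,
           n_background, min_controls)
  if (any(pos <= 0)) stop("lengths and counts must be positive")
  stopifnot(n_haplotypes >= 2, seed == floor(seed), abs(seed) < 2^31)
  structure(cfg, class = "synthetic_config")
}

.chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chrom))

#' Generate an i.i.d. genome with tunable GC content
#'
#' @param cfg a [synthetic_config()].
#' @return Named character vector of chromosome sequences (upper case).
#' @export
gen_genome <- function(cfg) {
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  withr::with_seed(cfg$seed, {
    out <- vapply(seq_len(cfg$n_chrom), function(i)
      paste(sample(names(p), cfg$chrom_length, replace = TRUE, prob = p),
            collapse = ""), "")
  })
  names(out) <- .chrom_names(cfg)
  out
}

## Place n disjoint intervals of the given lengths uniformly over the
## genome, avoiding `occupied` (data frame chrom/start/end).  Errors after
## bounded retries.
.place_disjoint <- function(n, lengths, cfg, occupied = NULL) {
  chroms <- .chrom_names(cfg)
  placed <- list()
  per_chrom <- lapply(stats::setNames(chroms, chroms), function(ch) {
    if (is.null(occupied)) return(data.frame(start = numeric(0),
                                             end = numeric(0)))
    occupied[occupied$chrom == ch, c("start", "end"), drop = FALSE]
  })
  tries <- 0
  k <- 0
  while (k < n) {
    tries <- tries + 1
    if (tries > 50 * n)
      stop("could not place ", n, " disjoint intervals; ",
           "reduce n_peaks or peak lengths")
    len <- lengths[k + 1]
    ch <- chroms[sample.int(cfg$n_chrom, 1)]
    start <- floor(stats::runif(1) * (cfg$chrom_length - len))
    occ <- per_chrom[[ch]]
    if (nrow(occ) && any(occ$start < start + len & occ$end > start)) next
    k <- k + 1
    placed[[k]] <- data.frame(chrom = ch, start = start,
                              end = start + len)
    per_chrom[[ch]] <- rbind(occ, placed[[k]][, c("start", "end")])
  }
  do.call(rbind, placed)
}

.peak_lengths <- function(n, cfg) {
  pmax(round(stats::rnorm(n, cfg$peak_length_mean, cfg$peak_length_sd)),
       cfg$peak_length_min)
}

#' Generate a peak-geometry annotation set without sequences
#'
#' Places `n_peaks` disjoint intervals with the configured peak geometry.
#' Useful wherever only interval structure matters (decoy annotations,
#' calibration studies); [plant_motif_peaks()] additionally edits motif
#' instances into a genome.
#'
#' @param cfg a [synthetic_config()].
#' @param label set label and name prefix.
#' @param seed placement seed (defaults to `cfg$seed + 1`).
#' @param occupied optional data frame (`chrom`, `start`, `end`) of
#'   regions to avoid.
#' @return A named `interval_set`.
#' @export
gen_peak_intervals <- function(cfg, label = "peaks",
                               seed = cfg$seed + 1L, occupied = NULL) {
  withr::with_seed(seed, {
    lens <- .peak_lengths(cfg$n_peaks, cfg)
    placed <- .place_disjoint(cfg$n_peaks, lens, cfg, occupied = occupied)
  })
  o <- order(placed$chrom, placed$start)
  placed <- placed[o, , drop = FALSE]
  interval_set(placed$chrom, placed$start, placed$end,
               name = sprintf("%s_%04d", label, seq_len(nrow(placed))),
               label = label)
}

#' Place peaks and plant motif instances into the genome
#'
#' Places `n_peaks` disjoint focus peaks, then for each motif of
#' `cfg$motif_set` substitutes one exact consensus instance (random strand,
#' uniform internal offset) into a `plant_rate` fraction of peaks.  The
#' truth table records every planted instance; planted offsets always
#' satisfy full containment (`offset + width <= peak length`).
#'
#' @param cfg a [synthetic_config()].
#' @param genome named character vector from [gen_genome()].
#' @return A list: `peaks` (named `interval_set`), `genome` (with instances
#'   substituted), `truth` (data frame `peak`, `motif`, `offset`,
#'   `strand`).
#' @export
plant_motif_peaks <- function(cfg, genome) {
  withr::with_seed(cfg$seed + 1L, {
    lens <- .peak_lengths(cfg$n_peaks, cfg)
    placed <- .place_disjoint(cfg$n_peaks, lens, cfg)
    o <- order(placed$chrom, placed$start)
    placed <- placed[o, , drop = FALSE]
    placed$name <- sprintf("peak_%04d", seq_len(cfg$n_peaks))
    ## per-chromosome character vectors: in-place slice assignment avoids
    ## copying whole chromosome strings per planted instance
    chars <- lapply(genome, function(s) strsplit(s, "")[[1]])
    truth <- list()
    for (mi in seq_along(cfg$motif_set)) {
      motif <- names(cfg$motif_set)[mi]
      if (is.null(motif) || !nzchar(motif)) motif <- cfg$motif_set[[mi]]
      pat <- toupper(cfg$motif_set[[mi]])
      w <- nchar(pat)
      n_plant <- round(cfg$plant_rate * cfg$n_peaks)
      rows <- sort(sample.int(cfg$n_peaks, n_plant))
      for (r in rows) {
        plen <- placed$end[r] - placed$start[r]
        off <- sample.int(plen - w + 1, 1) - 1
        strand <- sample(c("+", "-"), 1)
        inst <- if (strand == "+") pat else .revcomp(pat)
        ch <- placed$chrom[r]
        gpos <- placed$start[r] + off
        chars[[ch]][(gpos + 1):(gpos + w)] <- strsplit(inst, "")[[1]]
        truth[[length(truth) + 1]] <- data.frame(
          peak = placed$name[r], motif = motif, offset = off,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    genome <- vapply(chars, paste, "", collapse = "")
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(peak = character(), motif = character(),
               offset = integer(), strand = character())
  peaks <- interval_set(placed$chrom, placed$start, placed$end,
                        name = placed$name, label = "focus")
  list(peaks = peaks, genome = genome, truth = truth)
}

#' Generate an LD-structured haplotype panel
#'
#' Variants are placed uniformly over the genome.  Within each block of
#' `block_length` bases the haplotypes descend from 2-4 founder haplotypes
#' (random founder assignment per haplotype per block) with per-site
#' mutation probability `mutation_rate`, producing high within-block and
#' low between-block r-squared.  Columns with minor allele frequency below
#' `maf_min` (including monomorphic ones) are dropped, and the panel is
#' thinned to exactly `n_variants` retained variants.
#'
#' @param cfg a [synthetic_config()].
#' @return A [haplotype_panel()].
#' @export
gen_haplotype_panel <- function(cfg) {
  withr::with_seed(cfg$seed + 2L, {
    n_draw <- 2L * cfg$n_variants
    chrom <- .chrom_names(cfg)[sample.int(cfg$n_chrom, n_draw,
                                          replace = TRUE)]
    pos <- floor(stats::runif(n_draw) * cfg$chrom_length)
    dup <- duplicated(paste(chrom, pos))
    chrom <- chrom[!dup]
    pos <- pos[!dup]
    o <- order(chrom, pos)
    chrom <- chrom[o]
    pos <- pos[o]
    m <- length(pos)
    h <- cfg$n_haplotypes
    block <- paste(chrom, floor(pos / cfg$block_length))
    alleles <- matrix(0L, h, m)
    for (b in unique(block)) {
      cols <- which(block == b)
      k <- sample(2:4, 1)
      founders <- matrix(stats::rbinom(k * length(cols), 1, 0.5), k)
      assign <- sample.int(k, h, replace = TRUE)
      alleles[, cols] <- founders[assign, , drop = FALSE]
    }
    if (cfg$mutation_rate > 0) {
      flips <- matrix(stats::rbinom(h * m, 1, cfg$mutation_rate), h)
      alleles <- (alleles + flips) %% 2L
    }
    f <- colMeans(alleles)
    maf <- pmin(f, 1 - f)
    keep <- which(maf >= cfg$maf_min)
    if (length(keep) < cfg$n_variants)
      stop("only ", length(keep), " variants with MAF >= ", cfg$maf_min,
           " (need ", cfg$n_variants, "); increase n_variants or lower ",
           "maf_min")
    if (length(keep) > cfg$n_variants)
      keep <- sort(sample(keep, cfg$n_variants))
    alleles <- alleles[, keep, drop = FALSE]
    variants <- variant_table(sprintf("rs%05d", seq_along(keep)),
                              chrom[keep], pos[keep])
  })
  haplotype_panel(alleles, variants)
}

#' Generate gene transcription start sites
#'
#' @param cfg a [synthetic_config()].
#' @return A [gene_annotation()] with `n_genes` TSS placed uniformly.
#' @export
gen_genes <- function(cfg) {
  withr::with_seed(cfg$seed + 3L, {
    chrom <- .chrom_names(cfg)[sample.int(cfg$n_chrom, cfg$n_genes,
                                          replace = TRUE)]
    pos <- floor(stats::runif(cfg$n_genes) * cfg$chrom_length)
  })
  gene_annotation(chrom, pos)
}

#' Generate risk loci with a planted enrichment effect
#'
#' Samples `n_loci` index variants from the panel: a fraction `effect` is
#' drawn conditional on the index-or-proxy locus overlapping `target`, the
#' remainder unconditionally.  Index variants are drawn only from pool
#' variants eligible for matched-control selection (at least
#' `min_controls` matched controls), since the matched-control test
#' requires controls for every locus.  Also returns the control pool (all
#' remaining panel variants with precomputed covariates) and
#' `n_control_sets` negative-control variant sets drawn with no effect.
#'
#' @param cfg a [synthetic_config()].
#' @param panel a [haplotype_panel()].
#' @param target the designated annotation subset (an `interval_set`).
#' @param genes a [gene_annotation()].
#' @param bins a [matching_bins()]; defaults to the standard bins with
#'   `cfg$min_controls`.
#' @param pool optionally a precomputed [control_pool()] for this panel.
#' @param seed seed for the draws; defaults to `cfg$seed + 4`.
#' @return A list: `loci`, `pool` (study indices removed), `control_sets`
#'   (list of locus lists), `eligible_ids`.
#' @export
gen_risk_loci <- function(cfg, panel, target, genes, bins = NULL,
                          pool = NULL, seed = NULL) {
  if (is.null(bins)) bins <- matching_bins(min_controls = cfg$min_controls)
  if (is.null(pool))
    pool <- control_pool(panel, genes, bins, cfg$r2_threshold,
                         cfg$ld_window)
  if (is.null(seed)) seed <- cfg$seed + 4L
  target <- .ensure_normalized(target)
  ov <- .pool_overlap(pool, target)
  eligible <- pool$table$id[pool$eligible]
  n_eff <- round(cfg$effect * cfg$n_loci)
  overlap_ids <- pool$table$id[pool$eligible & ov]
  if (length(overlap_ids) < n_eff)
    stop("only ", length(overlap_ids), " eligible variants overlap the ",
         "target; cannot plant effect = ", cfg$effect)
  if (length(eligible) < cfg$n_loci)
    stop("only ", length(eligible), " eligible index variants; need ",
         cfg$n_loci)
  ## Matched-control counts were computed against the full pool; removing
  ## the chosen study indices from it can push a thin bin below
  ## min_controls, so draws are repaired (deterministically, under the
  ## seed) until every study and control locus keeps enough controls.
  n_after_drop <- function(ids, pool2) {
    vapply(ids, function(id) {
      i <- match(id, pool$table$id)
      length(.matched_rows(pool2, pool$table$col[i], pool$table$bin[i]))
    }, integer(1))
  }
  withr::with_seed(seed, {
    idx_eff <- sample(overlap_ids, n_eff)
    idx_rest <- sample(setdiff(eligible, idx_eff), cfg$n_loci - n_eff)
    banned <- character(0)
    for (iter in 1:50) {
      study_ids <- c(idx_eff, idx_rest)
      pool2 <- .pool_drop_ids(pool, study_ids)
      bad <- study_ids[n_after_drop(study_ids, pool2) <
                         pool$bins$min_controls]
      if (!length(bad)) break
      banned <- c(banned, bad)
      for (id in bad) {
        cand_pool <- if (id %in% idx_eff) overlap_ids else eligible
        cand <- setdiff(cand_pool, c(idx_eff, idx_rest, banned))
        if (!length(cand))
          stop("cannot place ", cfg$n_loci, " index variants with >= ",
               pool$bins$min_controls, " matched controls each")
        new <- sample(cand, 1)
        if (id %in% idx_eff) idx_eff[idx_eff == id] <- new else
          idx_rest[idx_rest == id] <- new
      }
    }
    if (length(bad))
      stop("cannot place ", cfg$n_loci, " index variants with >= ",
           pool$bins$min_controls, " matched controls each")
    study_ids <- sort(study_ids)
    ctrl_ids <- lapply(seq_len(cfg$n_control_sets), function(k) {
      ids <- sample(setdiff(eligible, c(study_ids, banned)), cfg$n_loci)
      for (iter in 1:50) {
        bad <- ids[n_after_drop(ids, pool2) < pool$bins$min_controls]
        if (!length(bad)) break
        banned <- c(banned, bad)
        repl <- sample(setdiff(eligible, c(study_ids, banned, ids)),
                       length(bad))
        ids[match(bad, ids)] <- repl
      }
      sort(ids)
    })
  })
  make_loci <- function(ids) lapply(ids, function(id)
    .locus_from_pool(pool, id))
  loci <- make_loci(study_ids)
  control_sets <- lapply(ctrl_ids, make_loci)
  list(loci = loci, pool = pool2, control_sets = control_sets,
       eligible_ids = eligible)
}

## Build a risk_locus from pool-cached proxies.
.locus_from_pool <- function(pool, id) {
  col <- .panel_col(pool$panel, id)
  v <- pool$panel$variants
  proxies <- v[pool$proxy_cols[[col]], , drop = FALSE]
  proxies$r2 <- rep(NA_real_, nrow(proxies))
  proxies <- proxies[order(proxies$id), , drop = FALSE]
  rownames(proxies) <- NULL
  .new_risk_locus(as.list(v[col, , drop = FALSE]), proxies, pool$window)
}

## Remove ids from a pool (study indices are not control candidates).
## The memoization cache is reset: cached control rows refer to table rows.
.pool_drop_ids <- function(pool, ids) {
  pool$cache <- new.env(parent = emptyenv())
  keep <- !(pool$table$id %in% ids)
  rows <- which(keep)
  pool$positions <- pool$positions[pool$positions$row %in% rows, ,
                                   drop = FALSE]
  pool$positions$row <- match(pool$positions$row, rows)
  pool$table <- pool$table[keep, , drop = FALSE]
  rownames(pool$table) <- NULL
  pool$eligible <- pool$eligible[keep]
  pool
}

#' A small synthetic library of known motifs
#'
#' A constructed stand-in for a curated transcription-factor motif
#' database, used for known-motif matching in synthetic studies: a
#' softened E-box-core motif (the bHLH consensus context), plus GC-box,
#' AP-1, TATA and an unrelated longer decoy.  Entirely synthetic; not
#' derived from any curated database.
#'
#' @param sharpness probability of the consensus base at non-degenerate
#'   positions (default 0.85).
#' @return Named list of [pwm()] objects.
#' @export
demo_motif_library <- function(sharpness = 0.85) {
  soften <- function(pattern, name) {
    chars <- strsplit(pattern, "")[[1]]
    probs <- t(vapply(chars, function(ch) {
      if (ch == "N") return(rep(0.25, 4))
      p <- rep((1 - sharpness) / 3, 4)
      p[match(ch, BASES)] <- sharpness
      p
    }, numeric(4)))
    pwm(probs, name = name)
  }
  list(
    Ebox_bHLH = soften("GCAGCTGC", "Ebox_bHLH"),
    GCbox_SP = soften("GGGGCGGGG", "GCbox_SP"),
    AP1_TRE = soften("TGACTCA", "AP1_TRE"),
    TATA_box = soften("TATAAA", "TATA_box"),
    decoy_ZF = soften("ACGTAGCGATCG", "decoy_ZF"))
}

#' Generate a complete synthetic enrichment study
#'
#' Runs the whole generator: genome, focus peaks with planted motifs,
#' decoy annotation sets, background sequences, gene TSS, haplotype panel,
#' control pool, risk loci with the configured planted effect, and
#' negative-control variant sets.  Deterministic given `cfg$seed`.
#'
#' The designated target of the planted effect is the subset of focus
#' peaks carrying a planted motif instance, so that both the focus
#' annotation (stage 1) and the motif-defined subset (stage 3) are
#' genuinely enriched when `effect > 0`.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_study` with components `genome`
#'   (`DNAStringSet`), `peaks`, `truth`, `target_subset`, `annotations`
#'   (named list: focus + decoys), `background` (`DNAStringSet`), `panel`,
#'   `genes`, `bins`, `loci`, `pool`, `control_sets`, `library`, `config`.
#' @export
synthetic_study <- function(cfg = synthetic_config()) {
  genome <- gen_genome(cfg)
  planted <- plant_motif_peaks(cfg, genome)
  genome <- planted$genome
  annotations <- list(focus = planted$peaks)
  withr::with_seed(cfg$seed + 5L, {
    if (cfg$n_decoys > 0) {
      for (d in seq_len(cfg$n_decoys)) {
        lens <- .peak_lengths(cfg$n_peaks, cfg)
        placed <- .place_disjoint(cfg$n_peaks, lens, cfg,
                                  occupied = planted$peaks$df)
        o <- order(placed$chrom, placed$start)
        placed <- placed[o, , drop = FALSE]
        lab <- paste0("decoy", d)
        annotations[[lab]] <- interval_set(
          placed$chrom, placed$start, placed$end,
          name = sprintf("%s_%04d", lab, seq_len(nrow(placed))),
          label = lab)
      }
    }
    bg_lens <- .peak_lengths(cfg$n_background, cfg)
    bg_placed <- .place_disjoint(cfg$n_background, bg_lens, cfg,
                                 occupied = planted$peaks$df)
  })
  background <- stats::setNames(substring(
    genome[bg_placed$chrom], bg_placed$start + 1, bg_placed$end),
    sprintf("bg_%04d", seq_len(nrow(bg_placed))))
  planted_peaks <- unique(planted$truth$peak)
  sel <- planted$peaks$df$name %in% planted_peaks
  target_subset <- interval_set(
    planted$peaks$df$chrom[sel], planted$peaks$df$start[sel],
    planted$peaks$df$end[sel], name = planted$peaks$df$name[sel],
    label = "planted_subset")
  panel <- gen_haplotype_panel(cfg)
  genes <- gen_genes(cfg)
  bins <- matching_bins(min_controls = cfg$min_controls)
  risk <- gen_risk_loci(cfg, panel, target_subset, genes, bins = bins)
  structure(list(
    genome = Biostrings::DNAStringSet(genome), peaks = planted$peaks,
    truth = planted$truth, target_subset = target_subset,
    annotations = annotations,
    background = Biostrings::DNAStringSet(background), panel = panel,
    genes = genes, bins = bins, loci = risk$loci, pool = risk$pool,
    control_sets = risk$control_sets, library = demo_motif_library(),
    config = cfg), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat("synthetic_study (seed ", cfg$seed, "): ", cfg$n_chrom, " x ",
      cfg$chrom_length, " bp genome, ", n_intervals(x$peaks),
      " focus peaks (", nrow(x$truth), " planted motif instances), ",
      ncol(x$panel$alleles), " variants x ", nrow(x$panel$alleles),
      " haplotypes, ", length(x$loci), " risk loci (effect ",
      cfg$effect, "), ", length(x$control_sets),
      " control variant sets\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to plain-text fixture files
#'
#' Writes genome FASTA, one BED per annotation set, truth-table TSV,
#' variant and haplotype tables, gene TSS TSV, risk-locus and control-set
#' TSVs, background FASTA, motif-library text and a JSON echo of the
#' configuration.  Byte-identical across runs with the same seed.
#'
#' @param study a [synthetic_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(study$genome, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(study$background,
                              file.path(dir, "background.fa"))
  for (nm in names(study$annotations))
    write_bed(study$annotations[[nm]],
              file.path(dir, paste0("peaks_", nm, ".bed")))
  write_bed(study$target_subset, file.path(dir, "target_subset.bed"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_haplotype_panel(study$panel, dir)
  write_gene_tss(study$genes, file.path(dir, "genes.tsv"))
  loci_df <- function(loci) do.call(rbind, lapply(loci, function(l)
    data.frame(id = l$index$id, chrom = l$chrom, pos = l$index$pos,
               maf = l$index$maf, n_proxies = nrow(l$proxies),
               span_start = l$span[1], span_end = l$span[2])))
  utils::write.table(loci_df(study$loci), file.path(dir, "loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ctrl <- do.call(rbind, lapply(seq_along(study$control_sets), function(k)
    cbind(set = k, loci_df(study$control_sets[[k]]))))
  utils::write.table(ctrl, file.path(dir, "control_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_motif_library(study$library, file.path(dir, "library.txt"))
  cfg <- study$config
  class(cfg) <- NULL
  cfg$motif_set <- as.list(cfg$motif_set)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
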