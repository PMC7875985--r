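test_that("generator output is deterministic given the seed", {
  cfg <- mini_config()
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(g1, g2)
  p1 <- gen_haplotype_panel(cfg)
  p2 <- gen_haplotype_panel(cfg)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$variants, p2$variants)
  g3 <- gen_genome(mini_config(seed = 7))
  expect_false(identical(g1, g3))
})

test_that("genome GC content tracks the configuration", {
  cfg <- mini_config(gc_content = 0.6)
  g <- gen_genome(cfg)
  counts <- table(strsplit(g[[1]], "")[[1]])
  gc <- sum(counts[c("C", "G")]) / sum(counts)
  expect_lt(abs(gc - 0.6), 0.01)
})

test_that("panel blocks carry LD: duplicate founders give r2 = 1, and within > between", {
  cfg0 <- mini_config(mutation_rate = 0, n_variants = 100)
  pan0 <- gen_haplotype_panel(cfg0)
  # with no mutation every polymorphic column inside a block is one of the
  # founder splits; sample pairs in the same block have r2 in {1/9..1},
  # and columns sharing a split have exactly r2 = 1.  Verify blockwise.
  v <- pan0$variants
  block <- paste(v$chrom, floor(v$pos / cfg0$block_length))
  within <- c()
  for (b in unique(block)) {
    cols <- which(block == b)
    if (length(cols) < 2) next
    within <- c(within, compute_r2(pan0, cols[1], cols[2]))
  }
  expect_gte(length(within), 3)

  cfg <- mini_config()
  pan <- gen_haplotype_panel(cfg)
  expect_equal(ncol(pan$alleles), cfg$n_variants)
  expect_true(all(pan$variants$maf >= cfg$maf_min))
  v <- pan$variants
  block <- paste(v$chrom, floor(v$pos / cfg$block_length))
  withr::local_seed(81)
  rwithin <- rbetween <- c()
  for (i in 1:200) {
    j <- sample(ncol(pan$alleles), 1)
    same <- setdiff(which(block == block[j]), j)
    diff <- which(block != block[j] & v$chrom == v$chrom[j])
    if (length(same)) rwithin <- c(rwithin, compute_r2(pan, j,
                                                       sample(same, 1)))
    if (length(diff)) rbetween <- c(rbetween, compute_r2(pan, j,
                                                         sample(diff, 1)))
  }
  expect_gt(mean(rwithin), mean(rbetween))
  expect_gt(mean(rwithin), 0.2)
  expect_lt(mean(rbetween), 0.1)
})

test_that("planted motif instances are contained in their peaks and recorded", {
  cfg <- mini_config()
  genome <- gen_genome(cfg)
  pl <- plant_motif_peaks(cfg, genome)
  expect_equal(n_intervals(pl$peaks), cfg$n_peaks)
  expect_equal(nrow(pl$truth), round(cfg$plant_rate * cfg$n_peaks))
  w <- nchar(cfg$motif_set[[1]])
  lens <- with(pl$peaks$df, stats::setNames(end - start, name))
  expect_true(all(pl$truth$offset + w <= lens[pl$truth$peak]))
  expect_true(all(pl$truth$offset >= 0))
  # the genome really contains each planted instance
  seqs <- as.character(extract_peak_sequences(pl$genome, pl$peaks))
  pat <- toupper(cfg$motif_set[[1]])
  for (i in sample(nrow(pl$truth), 20)) {
    row <- pl$truth[i, ]
    inst <- substr(seqs[[row$peak]], row$offset + 1, row$offset + w)
    want <- if (row$strand == "+") pat else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
    expect_equal(inst, want)
  }
  # plant_rate 0 leaves the genome untouched
  pl0 <- plant_motif_peaks(mini_config(plant_rate = 0), genome)
  expect_equal(nrow(pl0$truth), 0)
  expect_identical(pl0$genome, genome)
})

test_that("risk loci respect the planted effect and eligibility", {
  study <- cached_study("mini0", mini_config())
  cfg <- study$config
  expect_length(study$loci, cfg$n_loci)
  expect_length(study$control_sets, cfg$n_control_sets)
  target <- normalize_intervals(study$target_subset)

  # effect = 1: every locus overlaps the target
  full_pool <- control_pool(study$panel, study$genes, study$bins,
                            cfg$r2_threshold, cfg$ld_window)
  cfg1 <- mini_config(effect = 1)
  g1 <- gen_risk_loci(cfg1, study$panel, target, study$genes,
                      bins = study$bins, pool = full_pool)
  ov <- vapply(g1$loci, ocrenrich:::.locus_overlaps, logical(1),
               annotation = target)
  expect_true(all(ov))

  # effect = 0: overlap proportion is near the eligible base rate
  base <- mean(ocrenrich:::.pool_overlap(full_pool, target)[
    full_pool$eligible])
  props <- vapply(1:20, function(r) {
    g <- gen_risk_loci(mini_config(effect = 0), study$panel, target,
                       study$genes, bins = study$bins, pool = full_pool,
                       seed = 500 + r)
    mean(vapply(g$loci, ocrenrich:::.locus_overlaps, logical(1),
                annotation = target))
  }, numeric(1))
  expect_lt(abs(mean(props) - base), 0.1)

  # study indices are removed from the returned pool; controls are not
  ids <- vapply(study$loci, function(l) l$index$id, "")
  expect_length(intersect(ids, study$pool$table$id), 0)

  # determinism
  g2 <- gen_risk_loci(cfg1, study$panel, target, study$genes,
                      bins = study$bins, pool = full_pool)
  expect_identical(vapply(g1$loci, function(l) l$index$id, ""),
                   vapply(g2$loci, function(l) l$index$id, ""))
})

test_that("fixture files round-trip through the package readers", {
  study <- cached_study("mini0", mini_config())
  dir <- withr::local_tempdir()
  write_fixture(study, dir)
  peaks <- read_bed(file.path(dir, "peaks_focus.bed"))
  expect_equal(peaks$df[, c("chrom", "start", "end", "name")],
               study$peaks$df[, c("chrom", "start", "end", "name")])
  pan <- read_haplotype_panel(file.path(dir, "haplotypes.tsv"),
                              file.path(dir, "variants.tsv"))
  expect_equal(unname(pan$alleles), unname(study$panel$alleles))
  genes <- read_gene_tss(file.path(dir, "genes.tsv"))
  expect_equal(genes$tss, study$genes$tss)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(genome), as.character(study$genome))
  lib <- read_motif_library(file.path(dir, "library.txt"))
  expect_equal(names(lib), names(study$library))
  cfg_echo <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg_echo$seed, study$config$seed)
  expect_equal(cfg_echo$n_peaks, study$config$n_peaks)
})
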