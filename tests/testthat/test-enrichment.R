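# single-variant locus helper
single_locus <- function(pos, chrom = "chr1", id = "v") {
  p <- haplotype_panel(cbind(c(1, 0, 1, 0)),
                       variant_table(id, chrom, pos))
  find_proxies(p, id)
}

test_that("locus-shift test saturates on tiling annotations and empties", {
  loc <- single_locus(1000)
  tiling <- interval_set("chr1", 0, 1e6, label = "tiling")
  # annotation tiling the whole shift window: every offset overlaps
  r <- locus_shift_test(list(loc), tiling, n_perm = 50, seed = 1,
                        windows = list(c(0, 1e6)))
  expect_equal(r$observed, 1)
  expect_equal(r$p_raw, 1)

  empty <- interval_set(character(), numeric(), numeric(), label = "none")
  r0 <- locus_shift_test(list(loc), empty, n_perm = 50, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_raw, 1)

  expect_error(locus_shift_test(list(), tiling), "empty locus list")
})

test_that("exhaustive locus-shift enumeration matches offset counting", {
  # window [0,100), variant at 10, annotation [5,15): 10 of 100 offsets hit
  loc <- single_locus(10)
  ann <- interval_set("chr1", 5, 15, label = "one")
  r <- locus_shift_test(list(loc), ann, exhaustive = TRUE,
                        windows = list(c(0, 100)))
  expect_equal(r$observed, 1)
  expect_equal(r$p_raw, 10 / 100)
  # observed = 0 (variant outside annotation reachable by shifts): p = 1
  loc2 <- single_locus(90)
  r2 <- locus_shift_test(list(loc2), ann, exhaustive = TRUE,
                         windows = list(c(0, 100)))
  expect_equal(r2$observed, 0)
  expect_equal(r2$p_raw, 1)
  expect_error(locus_shift_test(list(loc, loc2), ann, exhaustive = TRUE),
               "single locus")
})

test_that("sampled locus-shift p approaches the exhaustive value and is seed-reproducible", {
  loc <- single_locus(10)
  ann <- interval_set("chr1", 5, 15, label = "one")
  a <- locus_shift_test(list(loc), ann, n_perm = 4000, seed = 99,
                        windows = list(c(0, 100)))
  b <- locus_shift_test(list(loc), ann, n_perm = 4000, seed = 99,
                        windows = list(c(0, 100)))
  expect_identical(a$p_raw, b$p_raw)
  expect_lt(abs(a$p_raw - 0.1), 0.02)
  c <- locus_shift_test(list(loc), ann, n_perm = 4000, seed = 100,
                        windows = list(c(0, 100)))
  expect_false(identical(a$p_raw, c$p_raw))
})

test_that("poisson-binomial tail matches closed forms and enumeration", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5, 0.5), 2), 0.5)
  expect_equal(poisson_binomial_tail(c(0.2, 0.4), 2), 0.08)
  expect_equal(poisson_binomial_tail(c(0.9, 0.1, 0.3), 0), 1)
  expect_error(poisson_binomial_tail(c(0.5, 0.5), 3), "exceeds")

  # identical probs reduce to the binomial survival function
  expect_equal(poisson_binomial_tail(rep(0.3, 10), 4),
               stats::pbinom(3, 10, 0.3, lower.tail = FALSE))

  # four-locus toy: overlap fractions {1/2, 1/2, 1/4, 3/4}, S = 3
  probs <- c(1 / 2, 1 / 2, 1 / 4, 3 / 4)
  expect_equal(poisson_binomial_tail(probs, 3),
               poisbin_tail_enum(probs, 3), tolerance = 1e-12)

  withr::local_seed(41)
  for (rep in 1:10) {
    n <- sample(2:10, 1)
    pr <- stats::runif(n)
    s <- sample(0:n, 1)
    expect_equal(poisson_binomial_tail(pr, s), poisbin_tail_enum(pr, s),
                 tolerance = 1e-10)
  }
})

test_that("matched-control selection matches on bins and excludes self and LD mates", {
  pan <- toy_panel()
  genes <- gene_annotation("chr1", 0)
  bins <- matching_bins(min_controls = 3)
  pool <- control_pool(pan, genes, bins)
  loc <- find_proxies(pan, "e1")

  ctrl <- select_matched_controls(loc, pool, genes)
  # same maf/ld/distance bin: e2, e3, e4; e1 excluded as self, e1dup by LD
  expect_equal(ctrl$id, c("e2", "e3", "e4"))

  strict <- control_pool(pan, genes, matching_bins(min_controls = 4))
  expect_error(select_matched_controls(loc, strict, genes),
               "insufficient controls")
})

test_that("matched-control test matches a hand-enumerated toy and its conventions", {
  pan <- toy_panel()
  genes <- gene_annotation("chr1", 0)
  pool <- control_pool(pan, genes, matching_bins(min_controls = 2))
  loci <- list(find_proxies(pan, "h1"), find_proxies(pan, "h2"))

  empty <- interval_set(character(), numeric(), numeric(), label = "none")
  r0 <- matched_control_test(loci, empty, pool, genes)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_raw, 1)

  tiling <- interval_set("chr1", 0, 1e6, label = "all")
  r1 <- matched_control_test(loci, tiling, pool, genes)
  expect_equal(r1$observed, 2)
  # all controls overlap too: probs capped at n/(n+1) = 2/3 per locus
  expect_equal(r1$p_raw, (2 / 3)^2)

  # annotation covering h1 (600) and h3 (800) but not h2 (700):
  # each maf-0.5 locus has the other two as controls.
  # h1: controls {h2, h3} -> overlap fraction 1/2; h2: {h1, h3} -> 1
  # (capped at 2/3); S = 1 -> P(X >= 1) = 1 - (1/2) * (1/3) = 5/6
  ann <- interval_set(c("chr1", "chr1"), c(595, 795), c(605, 805),
                      label = "picked")
  r <- matched_control_test(loci, ann, pool, genes)
  expect_equal(r$observed, 1)
  expect_equal(r$p_raw, 1 - (1 / 2) * (1 / 3))
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(2.00e-3, 14), 0.028)
  expect_equal(bonferroni_adjust(0.5, 14), 1)
  expect_equal(bonferroni_adjust(1e-6, 1), 1e-6)
  expect_error(bonferroni_adjust(0, 5))
})

test_that("enrichment_report adjusts over the family and applies the dual rule", {
  mk <- function(method, p, lab)
    enrichment_result(method, observed = 0.5, p_raw = p,
                      annotation_label = lab)
  ls <- list(mk("locus_shift", 0.002, "a"), mk("locus_shift", 0.2, "b"))
  mc <- list(mk("matched_control", 0.001, "a"),
             mk("matched_control", 0.01, "b"))
  rep <- enrichment_report(ls, mc, n_intervals = c(10, 20), alpha = 0.05)
  expect_equal(rep$shift_p_adj[rep$label == "a"], 0.004)
  expect_equal(rep$matched_p_adj[rep$label == "b"], 0.02)
  expect_equal(rep$dual_significant, c(TRUE, FALSE))
  expect_equal(unique(rep$n_tests), 2)
})
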