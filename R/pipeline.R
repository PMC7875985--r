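## Run both enrichment tests for each annotation in a named list and
## tabulate with family-wise Bonferroni adjustment.
.stage_tests <- function(loci, annotations, pool, genes, n_perm, seed,
                         alpha) {
  labels <- names(annotations)
  ls_res <- vector("list", length(annotations))
  mc_res <- vector("list", length(annotations))
  for (i in seq_along(annotations)) {
    ann <- .ensure_normalized(annotations[[i]])
    ann$label <- labels[i]
    ls_res[[i]] <- locus_shift_test(loci, ann, n_perm = n_perm,
                                    seed = seed + i)
    mc_res[[i]] <- matched_control_test(loci, ann, pool, genes)
  }
  enrichment_report(ls_res, mc_res,
                    n_intervals = vapply(annotations, n_intervals,
                                         integer(1)),
                    alpha = alpha)
}

#' Run the full enrichment workflow on a synthetic study
#'
#' Orchestrates the three analysis stages end-to-end:
#'
#' * Stage 1 tests every annotation set with both enrichment statistics
#'   (Bonferroni factor = number of annotation sets) and applies the
#'   dual-test rule: an annotation is significant only when both adjusted
#'   p-values fall below `alpha`.
#' * Stage 2 performs de novo k-mer motif discovery within the top
#'   dual-significant annotation (smallest matched-control adjusted p),
#'   matches discovered motifs to the known-motif library, scans for
#'   occurrences at the exact p-value threshold `fimo_p`, and subsets the
#'   annotation's peaks by motif content (including the `noMotif`
#'   negative-control subset), logging every exclusion.  In `"denovo"`
#'   mode the discovered patterns themselves are scanned (requiring a
#'   known match); in `"known"` mode the best-matched known motifs are
#'   scanned instead.
#' * Stage 3 tests every retained subset with both statistics (Bonferroni
#'   factor = number of subsets tested).
#'
#' Negative-control variant sets are run through the identical stage-1 and
#' stage-3 tests.  If no annotation is dual-significant in stage 1, stages
#' 2-3 are skipped with an explicit report line (not an error).  The whole
#' run is deterministic given `seed`.
#'
#' @param study a [synthetic_study()].
#' @param mode `"denovo"` or `"known"` motif-subsetting track.
#' @param n_perm locus-shift permutations (default 10000).
#' @param alpha significance level of the dual-test rule (default 0.05).
#' @param fimo_p exact scan p-value threshold (default 1e-4).
#' @param min_subset minimum peaks per tested subset; default 25 at the
#'   synthetic scale (the full-scale module default is 1000).
#' @param e_threshold,max_motifs motif-discovery settings (0.05, 25).
#' @param match_min minimum similarity for a known-motif match
#'   (default 0.6).
#' @param exclude_mhc drop risk loci inside the MHC region first.
#' @param seed integer seed; defaults to the study seed.
#' @param out_dir optional directory for TSV reports and a JSON manifest.
#' @return A list of class `workflow_result` with `stage1`, `stage2`,
#'   `stage3`, `controls`, and `manifest`.
#' @export
run_workflow <- function(study, mode = c("denovo", "known"),
                         n_perm = 10000, alpha = 0.05, fimo_p = 1e-4,
                         min_subset = 25, e_threshold = 0.05,
                         max_motifs = 25, match_min = 0.6,
                         exclude_mhc = FALSE, seed = study$config$seed,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "synthetic_study"))
  loci <- study$loci
  control_sets <- study$control_sets
  if (exclude_mhc) {
    loci <- filter_mhc(loci)
    control_sets <- lapply(control_sets, filter_mhc)
  }
  stage1 <- .stage_tests(loci, study$annotations, study$pool,
                         study$genes, n_perm, seed, alpha)
  dual <- stage1[stage1$dual_significant, , drop = FALSE]
  stage2 <- list(skipped = FALSE, note = "", motifs = NULL,
                 matches = NULL, occurrences = NULL, subsets = NULL,
                 exclusions = NULL, target = NA_character_)
  stage3 <- NULL
  subsets_tested <- list()
  if (nrow(dual) == 0) {
    stage2$skipped <- TRUE
    stage2$note <- paste("no annotation passed the dual-test significance",
                         "rule in stage 1; stages 2-3 skipped")
  } else {
    target_label <- dual$label[which.min(dual$matched_p_adj)]
    stage2$target <- target_label
    target_ann <- study$annotations[[target_label]]
    target_seqs <- extract_peak_sequences(study$genome, target_ann)
    motifs <- discover_enriched_kmers(target_seqs, study$background,
                                      e_threshold = e_threshold,
                                      max_motifs = max_motifs)
    stage2$motifs <- motifs
    matches <- lapply(motifs$pattern, match_to_known_motifs,
                      library = study$library)
    names(matches) <- motifs$pattern
    best <- vapply(matches, function(m)
      if (nrow(m)) m$score[1] else -Inf, numeric(1))
    best_name <- vapply(matches, function(m)
      if (nrow(m)) m$name[1] else NA_character_, "")
    stage2$matches <- data.frame(
      pattern = motifs$pattern, best_match = best_name,
      similarity = best, matched = best >= match_min,
      stringsAsFactors = FALSE)
    bg <- background_from_sequences(target_seqs)
    if (mode == "denovo") {
      pwms <- lapply(motifs$pattern, pwm_from_kmer)
      occ <- .scan_many(target_seqs, pwms, bg = bg, p_threshold = fimo_p)
      names(occ) <- motifs$pattern
      sub <- subset_peaks_by_motif(
        target_ann, occ, min_subset = min_subset,
        require_known_match = TRUE,
        matched = motifs$pattern[best >= match_min])
    } else {
      known <- unique(stats::na.omit(best_name[best >= match_min]))
      occ <- .scan_many(target_seqs, study$library[known], bg = bg,
                        p_threshold = fimo_p)
      names(occ) <- known
      sub <- subset_peaks_by_motif(target_ann, occ,
                                   min_subset = min_subset)
    }
    stage2$occurrences <- do.call(rbind, c(occ, list(make.row.names = FALSE)))
    stage2$subsets <- sub$subsets
    stage2$exclusions <- sub$exclusions
    subsets_tested <- sub$subsets
    if (!("noMotif" %in% sub$exclusions$motif))
      subsets_tested <- c(subsets_tested, list(noMotif = sub$no_motif))
    if (length(subsets_tested))
      stage3 <- .stage_tests(loci, subsets_tested, study$pool,
                             study$genes, n_perm, seed + 100L, alpha)
  }
  controls <- lapply(seq_along(control_sets), function(k) {
    cl <- control_sets[[k]]
    c1 <- .stage_tests(cl, study$annotations, study$pool, study$genes,
                       n_perm, seed + 1000L * k, alpha)
    c3 <- if (length(subsets_tested))
      .stage_tests(cl, subsets_tested, study$pool, study$genes, n_perm,
                   seed + 1000L * k + 100L, alpha) else NULL
    list(stage1 = c1, stage3 = c3,
         flagged = any(c1$dual_significant) ||
           (!is.null(c3) && any(c3$dual_significant)))
  })
  manifest <- list(
    package = "ocrenrich",
    version = as.character(utils::packageVersion("ocrenrich")),
    seed = seed, mode = mode, n_perm = n_perm, alpha = alpha,
    fimo_p = fimo_p, min_subset = min_subset, e_threshold = e_threshold,
    max_motifs = max_motifs, match_min = match_min,
    exclude_mhc = exclude_mhc, n_loci = length(loci),
    n_annotations = length(study$annotations),
    n_subsets_tested = length(subsets_tested),
    n_control_sets = length(control_sets),
    stage2_skipped = stage2$skipped, stage2_target = stage2$target)
  res <- structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                        controls = controls, manifest = manifest),
                   class = "workflow_result")
  if (!is.null(out_dir)) write_workflow_reports(res, out_dir)
  res
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("workflow_result (mode ", x$manifest$mode, ", seed ",
      x$manifest$seed, ")\n", sep = "")
  cat("stage 1:", sum(x$stage1$dual_significant), "of",
      nrow(x$stage1), "annotations dual-significant\n")
  if (x$stage2$skipped) {
    cat("stage 2:", x$stage2$note, "\n")
  } else {
    cat("stage 2: target ", x$stage2$target, "; ",
        nrow(x$stage2$motifs), " motifs discovered, ",
        length(x$stage2$subsets), " subsets retained, ",
        nrow(x$stage2$exclusions), " exclusions\n", sep = "")
    if (!is.null(x$stage3))
      cat("stage 3:", sum(x$stage3$dual_significant), "of",
          nrow(x$stage3), "subsets dual-significant\n")
  }
  flagged <- vapply(x$controls, `[[`, logical(1), "flagged")
  cat("negative controls flagged:", sum(flagged), "of", length(flagged),
      "\n")
  invisible(x)
}

#' Write workflow reports as TSV plus a JSON manifest
#'
#' @param res a `workflow_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_workflow_reports <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_enrichment_report(res$stage1, file.path(dir, "stage1.tsv"))
  if (res$stage2$skipped) {
    writeLines(res$stage2$note, file.path(dir, "stage2_skipped.txt"))
  } else {
    utils::write.table(res$stage2$motifs, file.path(dir, "stage2_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$stage2$matches,
                       file.path(dir, "stage2_matches.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$stage2$exclusions,
                       file.path(dir, "stage2_exclusions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(res$stage3))
      write_enrichment_report(res$stage3, file.path(dir, "stage3.tsv"))
  }
  for (k in seq_along(res$controls)) {
    write_enrichment_report(res$controls[[k]]$stage1,
                            file.path(dir, sprintf("control%d_stage1.tsv",
                                                   k)))
    if (!is.null(res$controls[[k]]$stage3))
      write_enrichment_report(res$controls[[k]]$stage3,
                              file.path(dir,
                                        sprintf("control%d_stage3.tsv",
                                                k)))
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
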