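#' Run the full LD-based Ne pipeline on one population
#'
#' Orchestrates read -> QC -> windowed pairwise r2 -> genetic-distance
#' conversion -> distance binning -> stage-1 smooth -> Ne, writing every
#' stage's table under `out_dir` so each reported number is traceable to a
#' file:
#' \describe{
#'   \item{qc_report.tsv (+ .summary.tsv)}{per-variant QC stats and attrition}
#'   \item{ld_pairs.tsv}{pairwise r2 with genetic distances}
#'   \item{decay_genome.tsv, decay_by_chrom.tsv}{LD-decay curves}
#'   \item{ld_scores.tsv, ld_scores.bed}{windowed mean LD scores}
#'   \item{distance_bins.tsv}{grouped mean r2 per genetic distance}
#'   \item{ne_estimate.json}{the Ne estimate with diagnostics}
#'   \item{run.log}{thresholds and per-stage attrition counts}
#' }
#' Populations are analysed one VCF at a time and never pooled; run the
#' pipeline once per population. A stage failure is re-raised with the
#' stage name; tables written before the failure are kept and a
#' `FAILED.<stage>` marker is left in `out_dir`.
#'
#' @param vcf Path to the input VCF.
#' @param out_dir Output directory (created if needed).
#' @param map A [genetic_map()], or path to a map config for [load_map()].
#' @param maf_min,missing_max,het_max QC thresholds; see [apply_filters()].
#' @param max_bp Maximum pair distance for LD (default 750 kb).
#' @param decay_bin_bp Decay-curve bin width (default 50 kb).
#' @param ldscore_window_bp,ldscore_r2_cutoff LD-score settings (defaults
#'   1000 kb and 0).
#' @param mode Ne estimator mode, `"paper"` or `"direct"`.
#' @param c_round_digits Rounding for genetic-distance grouping.
#' @param sample_n Optional finite-sample r2 correction for
#'   [estimate_ne()].
#' @return Invisibly, a list with all stage objects: `genotypes`, `qc`,
#'   `pairs`, `decay`, `decay_by_chrom`, `scores`, `bins`, `ne`, `log`.
#' @export
run_pipeline <- function(vcf, out_dir, map = genetic_map(default_ratio = 1),
                         maf_min = 0.05, missing_max = 0.20, het_max = 0.20,
                         max_bp = 750000, decay_bin_bp = 50000,
                         ldscore_window_bp = 1000000, ldscore_r2_cutoff = 0,
                         mode = c("paper", "direct"), c_round_digits = 6,
                         sample_n = NULL) {
  mode <- match.arg(mode)
  if (is.character(map)) map <- load_map(map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(out_dir, paste0("FAILED.", name)))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  note("input vcf: %s", vcf)
  note("settings: maf_min=%g missing_max=%g het_max=%g max_bp=%d",
       maf_min, missing_max, het_max, as.integer(max_bp))
  note("settings: ldscore_window_bp=%d r2_cutoff=%g mode=%s c_round_digits=%d",
       as.integer(ldscore_window_bp), ldscore_r2_cutoff, mode,
       as.integer(c_round_digits))

  G <- stage("read", suppressMessages(read_vcf(vcf)))
  note("read: %d samples, %d variants (%d records dropped)",
       n_samples(G), n_variants(G), attr(G, "n_dropped"))

  qc <- stage("qc", apply_filters(G, maf_min, missing_max, het_max))
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  note("qc: retained %d / %d (maf %d, missing %d, het %d failures)",
       qc$report$n_retained, qc$report$n_input, qc$report$n_failed_maf,
       qc$report$n_failed_missing, qc$report$n_failed_het)
  Gf <- qc$genotypes

  pairs <- stage("ld", {
    if (n_variants(Gf) < 2L)
      stop("fewer than 2 variants after QC; no LD can be computed")
    p <- pairwise_r2(Gf, max_bp = max_bp)
    add_genetic_distance(p, map)
  })
  note("ld: %d pairs within %d bp (%d monomorphic pairs skipped)",
       nrow(pairs), as.integer(max_bp), attr(pairs, "n_skipped"))
  write_pair_table(pairs, file.path(out_dir, "ld_pairs.tsv"))

  decay <- stage("decay", decay_curve(pairs, decay_bin_bp, scope = "genome"))
  utils::write.table(as.data.frame(decay),
                     file.path(out_dir, "decay_genome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  decay_by_chrom <- stage("decay", {
    per <- lapply(unique(pairs$chrom), function(ch)
      cbind(chrom = ch, as.data.frame(decay_curve(pairs, decay_bin_bp,
                                                  scope = ch))))
    do.call(rbind, per)
  })
  utils::write.table(decay_by_chrom,
                     file.path(out_dir, "decay_by_chrom.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scores <- stage("ldscore",
                  ld_scores(Gf, window_bp = ldscore_window_bp,
                            r2_cutoff = ldscore_r2_cutoff))
  write_score_track(scores, file.path(out_dir, "ld_scores.tsv"), "tsv")
  write_score_track(scores, file.path(out_dir, "ld_scores.bed"), "bed")
  note("ldscore: %d variants scored, %d without neighbours",
       sum(!is.na(scores$mean_r2)), sum(is.na(scores$mean_r2)))

  bins <- stage("bin", bin_mean_r2(pairs, c_round_digits = c_round_digits))
  utils::write.table(as.data.frame(bins),
                     file.path(out_dir, "distance_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("bin: %d distinct genetic distances (%d zero-c pairs dropped)",
       nrow(bins), attr(bins, "n_dropped_zero"))

  ne <- stage("ne", estimate_ne(bins, mode = mode, sample_n = sample_n))
  write_ne_estimate(ne, file.path(out_dir, "ne_estimate.json"))
  note("ne: %.4f (%s mode, %d points, %d mu<=0 dropped)",
       ne$ne, ne$mode, ne$n_points, ne$dropped_nonpositive)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(genotypes = G, qc = qc, pairs = pairs, decay = decay,
                 decay_by_chrom = decay_by_chrom, scores = scores,
                 bins = bins, ne = ne, log = log_lines))
}
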