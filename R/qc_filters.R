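#' Per-variant quality-control statistics
#'
#' Computes, for every variant, the minor allele frequency (from allele
#' counts over non-missing genotypes), the genotype missing rate, and the
#' heterozygosity rate (fraction of dosage-1 calls among non-missing
#' genotypes). Variants with all genotypes missing get `NA` for MAF and
#' heterozygosity — undefined, which is distinct from 0.
#'
#' @param G A [genotype_matrix()].
#' @return data.frame with columns `chrom`, `pos`, `id`, `maf`,
#'   `missing_rate`, `het_rate`, one row per variant in matrix order.
#' @export
variant_stats <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  D <- G$dosage
  n <- nrow(D)
  n_obs <- colSums(!is.na(D))
  alt_count <- colSums(D, na.rm = TRUE)
  p <- ifelse(n_obs > 0L, alt_count / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  het <- ifelse(n_obs > 0L, colSums(D == 1L, na.rm = TRUE) / n_obs, NA_real_)
  data.frame(chrom = G$variants$chrom, pos = G$variants$pos,
             id = G$variants$id,
             maf = maf,
             missing_rate = 1 - n_obs / n,
             het_rate = het,
             stringsAsFactors = FALSE)
}

#' Marker-level QC filtering
#'
#' Applies the three marker filters jointly in one pass on the input
#' statistics: a variant is retained iff `maf >= maf_min` AND
#' `missing_rate <= missing_max` AND `het_rate <= het_max`. The boundary
#' semantics follow the usual reading of "MAF below 5\%", "more than 20\%
#' missing" and "heterozygosity above 20\%": the MAF cut is strict below the
#' threshold, the other two strict above. Variants whose MAF/heterozygosity
#' are undefined (all genotypes missing) are always removed.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency retained (default 0.05).
#' @param missing_max Maximum genotype missing rate retained (default 0.20).
#' @param het_max Maximum heterozygosity rate retained (default 0.20).
#' @return A list of class `qc_result` with elements `genotypes` (the
#'   filtered [genotype_matrix()]) and `report` (class `qc_report`: counts
#'   `n_input`, `n_failed_maf`, `n_failed_missing`, `n_failed_het`,
#'   `n_undefined`, `n_retained`, plus `per_variant_stats`).
#' @export
apply_filters <- function(G, maf_min = 0.05, missing_max = 0.20,
                          het_max = 0.20) {
  thr <- c(maf_min = maf_min, missing_max = missing_max, het_max = het_max)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1))
    stop("QC thresholds must lie in [0, 1]")
  st <- variant_stats(G)
  undefined <- is.na(st$maf) | is.na(st$het_rate)
  fail_maf <- !undefined & st$maf < maf_min
  fail_mis <- st$missing_rate > missing_max
  fail_het <- !undefined & st$het_rate > het_max
  keep <- !undefined & !fail_maf & !fail_mis & !fail_het
  st$retained <- keep
  report <- structure(list(
    n_input = nrow(st),
    n_failed_maf = sum(fail_maf),
    n_failed_missing = sum(fail_mis),
    n_failed_het = sum(fail_het),
    n_undefined = sum(undefined),
    n_retained = sum(keep),
    thresholds = thr,
    per_variant_stats = st), class = "qc_report")
  if (!any(keep))
    warning("no variants pass QC")
  structure(list(genotypes = subset_variants(G, keep), report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat(sprintf("  input variants : %d\n", x$n_input))
  cat(sprintf("  failed MAF < %.3g       : %d\n",
              x$thresholds["maf_min"], x$n_failed_maf))
  cat(sprintf("  failed missing > %.3g   : %d\n",
              x$thresholds["missing_max"], x$n_failed_missing))
  cat(sprintf("  failed het > %.3g       : %d\n",
              x$thresholds["het_max"], x$n_failed_het))
  if (x$n_undefined > 0)
    cat(sprintf("  undefined (all-missing) : %d\n", x$n_undefined))
  cat(sprintf("  retained       : %d\n", x$n_retained))
  invisible(x)
}

#' Write a QC report to TSV
#'
#' Writes the per-variant statistics table (with a `retained` flag); the
#' attrition counts go to a small companion `<path>.summary.tsv`.
#'
#' @param report A `qc_report` from [apply_filters()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.table(report$per_variant_stats, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- data.frame(metric = c("n_input", "n_failed_maf", "n_failed_missing",
                             "n_failed_het", "n_undefined", "n_retained"),
                  value = c(report$n_input, report$n_failed_maf,
                            report$n_failed_missing, report$n_failed_het,
                            report$n_undefined, report$n_retained))
  utils::write.table(s, paste0(path, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
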