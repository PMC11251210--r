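#' Pairwise r-squared within a physical window
#'
#' For every intra-chromosomal variant pair at most `max_bp` apart, computes
#' genotypic r2: the squared Pearson correlation of allele-dosage vectors
#' over the samples non-missing at both sites (complete-pairs deletion).
#' Pairs where either site is monomorphic among the shared non-missing
#' samples are skipped; their count is kept in `attr(, "n_skipped")`.
#' Chromosomes are processed independently in position-sorted blocks.
#'
#' @param G A [genotype_matrix()].
#' @param max_bp Maximum pair distance in bp (default 750000, i.e. 750 kb).
#' @return An `ld_pair_table`: a data.frame with columns `chrom`, `idx_i`,
#'   `idx_j` (variant indices into `G$variants`, i before j in position
#'   order), `pos_i`, `pos_j`, `bp_dist`, `r2`, and attributes `max_bp`,
#'   `n_skipped`. Empty (with a warning) if no pair qualifies.
#' @export
pairwise_r2 <- function(G, max_bp = 750000) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (max_bp <= 0) stop("max_bp must be positive")
  out <- vector("list", 0L)
  n_skipped <- 0L
  for (ch in unique(G$variants$chrom)) {
    idx <- which(G$variants$chrom == ch)
    if (length(idx) < 2L) next
    pos <- G$variants$pos[idx]
    D <- G$dosage[, idx, drop = FALSE]
    storage.mode(D) <- "double"
    R2 <- suppressWarnings(
      stats::cor(D, use = "pairwise.complete.obs"))^2
    ut <- which(upper.tri(R2), arr.ind = TRUE)
    d <- pos[ut[, 2L]] - pos[ut[, 1L]]
    inwin <- d >= 1L & d <= max_bp
    ut <- ut[inwin, , drop = FALSE]
    d <- d[inwin]
    r2 <- R2[ut]
    ok <- !is.na(r2)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      idx_i = idx[ut[ok, 1L]], idx_j = idx[ut[ok, 2L]],
      pos_i = pos[ut[ok, 1L]], pos_j = pos[ut[ok, 2L]],
      bp_dist = d[ok], r2 = r2[ok],
      stringsAsFactors = FALSE)
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), idx_i = integer(0), idx_j = integer(0),
               pos_i = integer(0), pos_j = integer(0),
               bp_dist = integer(0), r2 = numeric(0))
  rownames(tab) <- NULL
  if (nrow(tab) == 0L)
    warning("no variant pairs within ", max_bp, " bp")
  structure(tab, class = c("ld_pair_table", "data.frame"),
            max_bp = max_bp, n_skipped = n_skipped)
}

#' Attach genetic distances to an LD pair table
#'
#' Fills the `c_morgan` column from each pair's physical distance via the
#' chromosome's cM/Mb ratio.
#'
#' @param pairs An `ld_pair_table` from [pairwise_r2()].
#' @param map A [genetic_map()].
#' @return The table with a `c_morgan` column (Morgans).
#' @export
add_genetic_distance <- function(pairs, map) {
  stopifnot(inherits(pairs, "ld_pair_table"))
  pairs$c_morgan <- bp_to_morgans(map, pairs$chrom, pairs$bp_dist)
  pairs
}

#' LD-decay curve: mean r2 in physical-distance bins
#'
#' Groups pairs into half-open distance bins `[k*w, (k+1)*w)` and reports
#' the mean r2 and pair count per bin. Bins with no pairs carry `NA` means.
#'
#' @param pairs An `ld_pair_table`.
#' @param bin_width_bp Bin width in bp (> 0).
#' @param scope `"genome"` for all chromosomes pooled, or one chromosome
#'   label.
#' @return A `decay_curve` data.frame with columns `bin_start`, `bin_end`,
#'   `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
decay_curve <- function(pairs, bin_width_bp = 50000, scope = "genome") {
  stopifnot(inherits(pairs, "ld_pair_table"))
  if (!is.numeric(bin_width_bp) || bin_width_bp <= 0)
    stop("bin_width_bp must be positive")
  if (!identical(scope, "genome"))
    pairs <- pairs[pairs$chrom == scope, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no pairs in scope '", scope, "'")
  k <- floor(pairs$bp_dist / bin_width_bp)
  mean_by_bin <- tapply(pairs$r2, k, mean)
  n_by_bin <- tapply(pairs$r2, k, length)
  kk <- seq(0L, max(k))
  m <- mean_by_bin[as.character(kk)]
  n <- n_by_bin[as.character(kk)]
  n[is.na(n)] <- 0L
  curve <- data.frame(bin_start = kk * bin_width_bp,
                      bin_end = (kk + 1) * bin_width_bp,
                      bin_mid = (kk + 0.5) * bin_width_bp,
                      mean_r2 = as.numeric(m),
                      n_pairs = as.integer(n))
  structure(curve, class = c("decay_curve", "data.frame"),
            scope = scope, bin_width_bp = bin_width_bp)
}

#' Per-SNP mean LD scores from a pair table
#'
#' For each variant, the mean r2 over its pairs within `window_bp` whose
#' r2 is at least `r2_cutoff`; variants without a qualifying neighbour get
#' `NA`. The input table must have been computed with a maximum pair
#' distance of at least `window_bp`.
#'
#' @param pairs An `ld_pair_table` whose `max_bp` is >= `window_bp`.
#' @param G The [genotype_matrix()] the table came from (supplies the full
#'   variant list, so isolated variants appear with missing scores).
#' @param window_bp Window half-width in bp (neighbours at most this far).
#' @param r2_cutoff Minimum r2 for a pair to contribute (default 0).
#' @return An `ld_score_track` data.frame: `chrom`, `pos`, `id`,
#'   `mean_r2`, `n_neighbors`.
#' @export
ld_scores_from_pairs <- function(pairs, G, window_bp = 1000000,
                                 r2_cutoff = 0) {
  stopifnot(inherits(pairs, "ld_pair_table"),
            inherits(G, "genotype_matrix"))
  if (attr(pairs, "max_bp") < window_bp)
    stop("pair table max_bp (", attr(pairs, "max_bp"),
         ") is smaller than window_bp (", window_bp, ")")
  use <- pairs$bp_dist <= window_bp & pairs$r2 >= r2_cutoff
  p <- pairs[use, , drop = FALSE]
  nv <- n_variants(G)
  sums <- numeric(nv)
  counts <- integer(nv)
  if (nrow(p)) {
    for (side in c("idx_i", "idx_j")) {
      agg_s <- tapply(p$r2, p[[side]], sum)
      agg_n <- tapply(p$r2, p[[side]], length)
      at <- as.integer(names(agg_s))
      sums[at] <- sums[at] + agg_s
      counts[at] <- counts[at] + agg_n
    }
  }
  track <- data.frame(chrom = G$variants$chrom, pos = G$variants$pos,
                      id = G$variants$id,
                      mean_r2 = ifelse(counts > 0L, sums / counts, NA_real_),
                      n_neighbors = counts,
                      stringsAsFactors = FALSE)
  structure(track, class = c("ld_score_track", "data.frame"),
            window_bp = window_bp, r2_cutoff = r2_cutoff)
}

#' Windowed mean LD scores per SNP
#'
#' For each variant, the mean r2 against all other variants on the same
#' chromosome within `window_bp`, keeping only pairs with
#' r2 >= `r2_cutoff`; the variant itself is excluded. Variants with no
#' qualifying neighbour are reported with a missing score.
#'
#' @inheritParams pairwise_r2
#' @param window_bp Window half-width in bp (default 1000000, i.e. 1000 kb).
#' @param r2_cutoff Minimum r2 for a neighbour to contribute (default 0).
#' @return An `ld_score_track`; see [ld_scores_from_pairs()].
#' @export
ld_scores <- function(G, window_bp = 1000000, r2_cutoff = 0) {
  pairs <- suppressWarnings(pairwise_r2(G, max_bp = window_bp))
  ld_scores_from_pairs(pairs, G, window_bp = window_bp,
                       r2_cutoff = r2_cutoff)
}

#' Export an LD pair table as TSV
#'
#' Plink-like layout with columns CHR, POS_A, POS_B, BP_DIST, C_MORGAN, R2
#' (C_MORGAN is `NA` unless [add_genetic_distance()] was applied).
#'
#' @param pairs An `ld_pair_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  stopifnot(inherits(pairs, "ld_pair_table"))
  out <- data.frame(CHR = pairs$chrom, POS_A = pairs$pos_i,
                    POS_B = pairs$pos_j, BP_DIST = pairs$bp_dist,
                    C_MORGAN = if (is.null(pairs$c_morgan)) NA_real_
                               else pairs$c_morgan,
                    R2 = pairs$r2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an LD score track as TSV or BED
#'
#' BED output uses 0-based half-open single-base intervals
#' `(pos - 1, pos]` with the mean r2 in the score column.
#'
#' @param track An `ld_score_track`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path, format = c("tsv", "bed")) {
  stopifnot(inherits(track, "ld_score_track"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(track), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    keep <- !is.na(track$mean_r2)
    bed <- data.frame(track$chrom[keep], track$pos[keep] - 1L,
                      track$pos[keep],
                      ifelse(is.na(track$id[keep]), ".", track$id[keep]),
                      track$mean_r2[keep])
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
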