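# Independent oracles and small fixture builders used across tests.

# Brute-force squared Pearson correlation from raw sums over samples
# complete at both sites. Deliberately avoids stats::cor, which the
# implementation uses.
brute_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  if (vx == 0 || vy == 0) return(NA_real_)
  (sxy - sx * sy / n)^2 / (vx * vy)
}

# Double-loop pair enumeration against which pairwise_r2 is checked.
brute_pair_table <- function(G, max_bp) {
  rows <- list()
  v <- G$variants
  for (i in seq_len(nrow(v) - 1L)) for (j in seq(i + 1L, nrow(v))) {
    if (v$chrom[i] != v$chrom[j]) next
    d <- abs(v$pos[j] - v$pos[i])
    if (d < 1L || d > max_bp) next
    r2 <- brute_r2(G$dosage[, i], G$dosage[, j])
    if (is.na(r2)) next
    rows[[length(rows) + 1L]] <-
      data.frame(idx_i = i, idx_j = j, bp_dist = d, r2 = r2)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(idx_i = integer(0), idx_j = integer(0),
               bp_dist = integer(0), r2 = numeric(0))
}

# Random small dosage panel, optionally with missing genotypes.
random_panel <- function(n_samples, n_variants, missing_prob = 0.1,
                         n_chrom = 1L, span_bp = 1e6) {
  D <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE),
              nrow = n_samples)
  if (missing_prob > 0)
    D[matrix(runif(length(D)) < missing_prob, nrow = n_samples)] <- NA
  chrom <- paste0("chr", sample.int(n_chrom, n_variants, replace = TRUE))
  pos <- integer(n_variants)
  for (ch in unique(chrom)) {
    k <- chrom == ch
    pos[k] <- sort(sample.int(span_bp, sum(k)))
  }
  genotype_matrix(D, chrom = chrom, pos = pos,
                  ref = rep("A", n_variants), alt = rep("C", n_variants))
}

# Minimal VCF writer for hand-made test inputs (independent of write_vcf).
write_test_vcf <- function(path, samples, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
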