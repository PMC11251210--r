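#' Construct a genotype dosage matrix
#'
#' The central container of the package: a samples x variants matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for missing) together with
#' variant coordinates. Variants are stored sorted by (chromosome, position);
#' input order does not matter.
#'
#' @param dosage Numeric or integer matrix, samples in rows and variants in
#'   columns. Allowed values are 0, 1, 2 and `NA`.
#' @param chrom Character vector of chromosome labels, one per variant.
#' @param pos Integer vector of 1-based physical positions (bp).
#' @param ref,alt Single-nucleotide reference and alternate alleles.
#' @param id Optional variant labels (`NA` where absent).
#' @param samples Optional sample labels; defaults to the row names of
#'   `dosage` or `S1..Sn`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (samples x variants matrix), `variants` (data.frame with
#'   columns `chrom`, `pos`, `id`, `ref`, `alt`) and `samples`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL,
                            id = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  n_var <- ncol(dosage)
  if (nrow(dosage) < 2L)
    stop("a genotype matrix needs at least 2 samples")
  if (length(chrom) != n_var || length(pos) != n_var)
    stop("chrom/pos length must equal the number of dosage columns")
  if (any(pos < 1L, na.rm = TRUE))
    stop("positions must be >= 1 (1-based bp coordinates)")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  if (is.null(ref)) ref <- rep(NA_character_, n_var)
  if (is.null(alt)) alt <- rep(NA_character_, n_var)
  if (is.null(id))  id  <- rep(NA_character_, n_var)
  if (!is.null(ref) && !is.null(alt)) {
    same <- !is.na(ref) & !is.na(alt) & ref == alt
    if (any(same)) stop("ref and alt alleles must differ")
  }
  if (is.null(samples)) {
    samples <- rownames(dosage)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  }
  variants <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                         id = as.character(id), ref = as.character(ref),
                         alt = as.character(alt), stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- list(samples, NULL)
  storage.mode(dosage) <- "integer"
  structure(list(dosage = dosage, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of variants / samples in a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Integer count.
#' @export
n_variants <- function(G) nrow(G$variants)

#' @rdname n_variants
#' @export
n_samples <- function(G) length(G$samples)

# keep: logical or integer index over variants
subset_variants <- function(G, keep) {
  genotype_matrix(G$dosage[, keep, drop = FALSE],
                  chrom = G$variants$chrom[keep],
                  pos = G$variants$pos[keep],
                  ref = G$variants$ref[keep],
                  alt = G$variants$alt[keep],
                  id = G$variants$id[keep],
                  samples = G$samples)
}

#' Read a VCF into a genotype dosage matrix
#'
#' Reads diploid GT calls from a VCF (4.x) and converts them to alternate
#' allele dosages: `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> `NA`.
#' Phased separators (`|`) are accepted and phase is ignored; half-calls such
#' as `./1` are treated as missing. Multiallelic records and non-SNP records
#' (indels, symbolic alleles) are dropped; the number dropped is available as
#' `attr(, "n_dropped")` and reported via `message()`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_matrix()] sorted by (chrom, pos), with attribute
#'   `n_dropped` giving the count of excluded records.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path))
    stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, "FORMAT"]
  if (length(fmt) == 0L || !all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF has no GT field; genotypes are required")
  if (ncol(v@gt) - 1L < 2L)
    stop("VCF has fewer than 2 samples")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!is_snp)
  if (n_dropped > 0L)
    message(n_dropped, " multiallelic/non-SNP record(s) dropped")
  if (!any(is_snp))
    stop("no biallelic SNP records in VCF")

  gt <- gt[is_snp, , drop = FALSE]
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[gt %in% c("0/0", "0")] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt %in% c("1/1", "1")] <- 2L

  id <- fix[is_snp, "ID"]
  id[!is.na(id) & id == "."] <- NA_character_
  G <- genotype_matrix(t(dos),
                       chrom = fix[is_snp, "CHROM"],
                       pos = as.integer(fix[is_snp, "POS"]),
                       ref = ref[is_snp], alt = alt[is_snp],
                       id = id, samples = samples)
  attr(G, "n_dropped") <- n_dropped
  G
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits one GT-only record per variant; missing dosages become `./.`.
#' Round-trips with [read_vcf()] on (variants, samples, dosage).
#'
#' @param G A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  ref <- ifelse(is.na(v$ref), "A", v$ref)
  alt <- ifelse(is.na(v$alt), "C", v$alt)
  id <- ifelse(is.na(v$id), ".", v$id)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(v), ncol = length(G$samples))
  ok <- !is.na(G$dosage)
  gt[t(ok)] <- gt_code[as.character(t(G$dosage)[t(ok)])]
  body <- paste(v$chrom, v$pos, id, ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldne",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
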