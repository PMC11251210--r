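pair_lookup <- function(tab, i, j) {
  tab$r2[tab$idx_i == i & tab$idx_j == j]
}

test_that("pairwise r2 on worked examples", {
  # identical columns -> r2 = 1; complementary coding -> also 1
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)),
                       chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  tab <- pairwise_r2(G)
  expect_equal(pair_lookup(tab, 1, 2), 1)
  # orthogonal columns
  G <- genotype_matrix(cbind(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L)),
                       chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  expect_equal(pair_lookup(pairwise_r2(G), 1, 2), 0)
  # 6-sample pair: centered sums give (3/4)^2
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                             c(0L, 1L, 1L, 0L, 2L, 2L)),
                       chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  r2 <- pair_lookup(pairwise_r2(G), 1, 2)
  expect_equal(r2, 0.5625)
  expect_equal(r2, brute_r2(G$dosage[, 1], G$dosage[, 2]))
})

test_that("pairs beyond the window or across chromosomes are not emitted", {
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L),
                             c(0L, 1L, 2L, 0L)),
                       chrom = c("chr1", "chr1", "chr2"),
                       pos = c(1L, 800001L, 1000L))
  tab <- suppressWarnings(pairwise_r2(G, max_bp = 750000))
  expect_equal(nrow(tab), 0L)
  tab2 <- pairwise_r2(G, max_bp = 800000)
  expect_equal(nrow(tab2), 1L)  # chr1 pair only; chr2 has one variant
  expect_equal(tab2$chrom, "chr1")
})

test_that("monomorphic-in-overlap pairs are skipped and counted", {
  # second site varies overall but is constant among samples where the
  # first site is non-missing
  G <- genotype_matrix(cbind(c(0L, 2L, NA, NA), c(1L, 1L, 0L, 2L)),
                       chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  tab <- suppressWarnings(pairwise_r2(G))
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "n_skipped"), 1L)
})

test_that("pairwise r2 matches the brute-force oracle with missing data", {
  set.seed(101)
  for (rep in 1:20) {
    G <- random_panel(sample(3:8, 1), sample(2:6, 1), missing_prob = 0.2,
                      n_chrom = 2L, span_bp = 1e6)
    tab <- suppressWarnings(pairwise_r2(G, max_bp = 750000))
    ref <- brute_pair_table(G, max_bp = 750000)
    expect_equal(nrow(tab), nrow(ref))
    if (nrow(ref)) {
      ord <- order(tab$idx_i, tab$idx_j)
      ord_ref <- order(ref$idx_i, ref$idx_j)
      expect_equal(tab$r2[ord], ref$r2[ord_ref], tolerance = 1e-12)
      expect_equal(tab$bp_dist[ord], ref$bp_dist[ord_ref])
    }
  }
})

test_that("r2 is invariant under allele-label swap of either column", {
  set.seed(7)
  for (rep in 1:10) {
    G <- random_panel(8, 4, missing_prob = 0.1)
    tab <- suppressWarnings(pairwise_r2(G))
    Gs <- G
    Gs$dosage[, 1] <- 2L - Gs$dosage[, 1]   # swap labels at first site
    tabs <- suppressWarnings(pairwise_r2(Gs))
    expect_equal(tabs$r2, tab$r2, tolerance = 1e-12)
  }
})

test_that("decay curve bins pairs and averages r2 per bin", {
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)),
                       chrom = c("chr1", "chr1"), pos = c(100L, 30100L))
  one <- decay_curve(pairwise_r2(G), bin_width_bp = 50000)
  expect_equal(sum(one$n_pairs), 1L)
  expect_equal(one$mean_r2[one$n_pairs > 0], 1)

  # hand-made table: two pairs in one bin, means average
  tab <- structure(data.frame(chrom = "chr1", idx_i = c(1L, 1L),
                              idx_j = c(2L, 3L), pos_i = c(100L, 100L),
                              pos_j = c(10100L, 20100L),
                              bp_dist = c(10000L, 20000L),
                              r2 = c(0.2, 0.4)),
                   class = c("ld_pair_table", "data.frame"),
                   max_bp = 750000, n_skipped = 0L)
  d <- decay_curve(tab, bin_width_bp = 50000)
  expect_equal(d$mean_r2[1], 0.3)
  expect_equal(d$n_pairs[1], 2L)
  expect_equal(sum(d$n_pairs), 2L)
  expect_error(decay_curve(tab, bin_width_bp = 0), "positive")
})

test_that("ld_scores follows the windowed-mean contract", {
  # two identical SNPs 1 kb apart -> each scores 1
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)),
                       chrom = c("chr1", "chr1"), pos = c(1000L, 2000L))
  s <- ld_scores(G)
  expect_equal(s$mean_r2, c(1, 1))
  expect_equal(s$n_neighbors, c(1L, 1L))

  # isolated SNP beyond the window gets a missing score
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L),
                             c(0L, 2L, 1L, 0L)),
                       chrom = rep("chr1", 3),
                       pos = c(1000L, 2000L, 5000000L))
  s <- ld_scores(G, window_bp = 1000000)
  expect_true(is.na(s$mean_r2[3]))
  expect_equal(s$n_neighbors[3], 0L)

  # with a single neighbour and cutoff 0 the score is that pair's r2
  G2 <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                              c(0L, 1L, 1L, 0L, 2L, 2L)),
                        chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  expect_equal(ld_scores(G2)$mean_r2, c(0.5625, 0.5625))
})

test_that("ld_scores agrees with a brute-force window average", {
  set.seed(55)
  for (rep in 1:5) {
    G <- random_panel(8, 6, missing_prob = 0.1, span_bp = 2e6)
    s <- suppressWarnings(ld_scores(G, window_bp = 1e6, r2_cutoff = 0.1))
    v <- G$variants
    for (i in seq_len(n_variants(G))) {
      vals <- c()
      for (j in seq_len(n_variants(G))) {
        if (i == j || v$chrom[i] != v$chrom[j]) next
        if (abs(v$pos[i] - v$pos[j]) > 1e6) next
        r2 <- brute_r2(G$dosage[, i], G$dosage[, j])
        if (!is.na(r2) && r2 >= 0.1) vals <- c(vals, r2)
      }
      if (length(vals)) expect_equal(s$mean_r2[i], mean(vals))
      else expect_true(is.na(s$mean_r2[i]))
    }
  }
})

test_that("score and pair tables export in the documented layouts", {
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)),
                       chrom = c("chr1", "chr1"), pos = c(1000L, 2000L))
  tab <- add_genetic_distance(pairwise_r2(G), genetic_map(default_ratio = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(tab, f)
  got <- read.delim(f)
  expect_equal(names(got),
               c("CHR", "POS_A", "POS_B", "BP_DIST", "C_MORGAN", "R2"))
  expect_equal(got$C_MORGAN, 1e-5)

  s <- ld_scores(G)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_score_track(s, fb, format = "bed")
  bed <- read.delim(fb, header = FALSE)
  expect_equal(bed$V2, c(999, 1999))  # 0-based half-open starts
  expect_equal(bed$V3, c(1000, 2000))
})
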