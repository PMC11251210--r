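#' Configuration for the Wright-Fisher forward simulator
#'
#' Describes a closed diploid population evolving by drift alone: no
#' mutation, selection or migration. Generation 0 carries standing
#' variation at `n_loci` sites per chromosome with allele frequencies
#' drawn from `init_freq_range`; each later generation is produced by
#' sampling parents (with self-fertilization at rate `selfing_rate`) and
#' recombining gametes at a uniform `cm_per_mb` rate. After the burn-in
#' the sampled panel is corrupted with missing genotypes and spurious
#' heterozygote calls so that downstream QC has work to do.
#'
#' @param n_diploid Census size N (default 100).
#' @param selfing_rate Probability an offspring is selfed, in `[0, 1]`
#'   (default 0: random mating).
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_len_bp Chromosome length in bp (default 10 Mb).
#' @param cm_per_mb Uniform recombination ratio (default 1 cM/Mb).
#' @param n_loci Segregating sites per chromosome at generation 0
#'   (default 300).
#' @param init_freq_range Range of initial allele frequencies, drawn
#'   uniformly (default `c(0.1, 0.9)`).
#' @param n_generations Drift generations before sampling; default `2 * N`,
#'   enough burn-in for LD to approach the drift-recombination
#'   quasi-equilibrium `E(r2) = 1/(1 + 4*Ne*c)` the estimator assumes.
#' @param n_sample Individuals sampled for output (default 50).
#' @param missing_rate Per-genotype missing probability after sampling
#'   (default 0.05).
#' @param het_error_rate Per-genotype probability of a spurious
#'   heterozygote call (default 0.02).
#' @param seed RNG seed (required; the simulation is deterministic given
#'   the seed).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_diploid = 100, selfing_rate = 0, n_chrom = 2,
                       chrom_len_bp = 10e6, cm_per_mb = 1, n_loci = 300,
                       init_freq_range = c(0.1, 0.9),
                       n_generations = 2 * n_diploid, n_sample = 50,
                       missing_rate = 0.05, het_error_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_diploid = as.integer(n_diploid),
              selfing_rate = selfing_rate,
              n_chrom = as.integer(n_chrom),
              chrom_len_bp = as.integer(chrom_len_bp),
              cm_per_mb = cm_per_mb,
              n_loci = as.integer(n_loci),
              init_freq_range = init_freq_range,
              n_generations = as.integer(n_generations),
              n_sample = as.integer(n_sample),
              missing_rate = missing_rate,
              het_error_rate = het_error_rate,
              seed = as.integer(seed))
  rates <- c(cfg$selfing_rate, cfg$missing_rate, cfg$het_error_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("selfing_rate, missing_rate, het_error_rate must lie in [0, 1]")
  if (cfg$n_diploid < 2L) stop("n_diploid must be >= 2")
  if (cfg$n_sample < 2L || cfg$n_sample > cfg$n_diploid)
    stop("need 2 <= n_sample <= n_diploid")
  if (cfg$n_generations < 1L) stop("n_generations must be >= 1")
  if (cfg$n_chrom < 1L || cfg$n_loci < 1L || cfg$chrom_len_bp < 2L)
    stop("invalid genome configuration")
  if (cfg$cm_per_mb <= 0) stop("cm_per_mb must be positive")
  fr <- cfg$init_freq_range
  if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    stop("init_freq_range must be within (0, 1)")
  structure(cfg, class = "sim_config")
}

# One gamete pool for a chromosome: for each of the 2N gametes, start on a
# random parental haplotype and switch at Poisson(lambda) uniform crossover
# points. The common zero-crossover case is a plain row copy.
recombine_gametes <- function(H, parent, pos, len_bp, lambda) {
  n_g <- length(parent)
  ncross <- stats::rpois(n_g, lambda)
  start <- sample.int(2L, n_g, replace = TRUE) - 1L
  newH <- H[2L * (parent - 1L) + 1L + start, , drop = FALSE]
  for (j in which(ncross > 0L)) {
    breaks <- sort(stats::runif(ncross[j], 0, len_bp))
    seg <- findInterval(pos, breaks)
    choice <- (start[j] + seg) %% 2L
    a <- H[2L * parent[j] - 1L, ]
    b <- H[2L * parent[j], ]
    newH[j, ] <- ifelse(choice == 0L, a, b)
  }
  newH
}

#' Run the Wright-Fisher forward simulation
#'
#' Evolves the configured population and returns the sampled, corrupted
#' SNP panel together with its ground truth. Monomorphic sites in the
#' sample are dropped (as a SNP panel would), then missingness and
#' spurious-het corruption are applied independently per genotype.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (class `sim_truth`: the config echo, `realized_ne_nominal`
#'   `= N / (1 + F)` with the equilibrium selfing inbreeding coefficient
#'   `F = s / (2 - s)`, and `n_segregating_out`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  N <- cfg$n_diploid
  lambda <- cfg$chrom_len_bp / 1e6 * cfg$cm_per_mb / 100
  chroms <- vector("list", cfg$n_chrom)
  positions <- vector("list", cfg$n_chrom)
  for (k in seq_len(cfg$n_chrom)) {
    positions[[k]] <- sort(sample.int(cfg$chrom_len_bp, cfg$n_loci))
    f0 <- stats::runif(cfg$n_loci, cfg$init_freq_range[1],
                       cfg$init_freq_range[2])
    chroms[[k]] <- matrix(stats::rbinom(2L * N * cfg$n_loci, 1L,
                                        rep(f0, each = 2L * N)),
                          nrow = 2L * N)
  }
  for (g in seq_len(cfg$n_generations)) {
    p1 <- sample.int(N, N, replace = TRUE)
    selfed <- stats::runif(N) < cfg$selfing_rate
    p2 <- sample.int(N, N, replace = TRUE)
    clash <- !selfed & p2 == p1
    while (any(clash)) {   # outcrossed offspring need two distinct parents
      p2[clash] <- sample.int(N, sum(clash), replace = TRUE)
      clash <- !selfed & p2 == p1
    }
    p2[selfed] <- p1[selfed]
    parent <- as.integer(rbind(p1, p2))  # gametes 2k-1, 2k per offspring
    for (k in seq_len(cfg$n_chrom))
      chroms[[k]] <- recombine_gametes(chroms[[k]], parent,
                                       positions[[k]], cfg$chrom_len_bp,
                                       lambda)
  }
  take <- sample.int(N, cfg$n_sample)
  dos_list <- lapply(chroms, function(H)
    H[2L * take - 1L, , drop = FALSE] + H[2L * take, , drop = FALSE])
  dosage <- do.call(cbind, dos_list)
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), each = cfg$n_loci)
  pos <- unlist(positions)

  ac <- colSums(dosage)
  seg <- ac > 0L & ac < 2L * cfg$n_sample
  dosage <- dosage[, seg, drop = FALSE]
  chrom <- chrom[seg]
  pos <- pos[seg]

  nv <- ncol(dosage)
  if (nv > 0L) {
    if (cfg$het_error_rate > 0) {
      flip <- matrix(stats::runif(length(dosage)) < cfg$het_error_rate,
                     nrow = nrow(dosage))
      dosage[flip] <- 1L
    }
    if (cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(length(dosage)) < cfg$missing_rate,
                     nrow = nrow(dosage))
      dosage[drop] <- NA_integer_
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  G <- genotype_matrix(dosage, chrom = chrom, pos = pos, ref = ref,
                       alt = alt,
                       id = paste0(chrom, "_", pos),
                       samples = paste0("S", seq_len(cfg$n_sample)))
  f_self <- cfg$selfing_rate / (2 - cfg$selfing_rate)
  truth <- structure(list(config = cfg,
                          realized_ne_nominal = N / (1 + f_self),
                          n_segregating_out = nv),
                     class = "sim_truth")
  list(genotypes = G, truth = truth)
}

#' Write a simulated VCF fixture with its ground truth
#'
#' Runs [simulate_population()] and writes the panel as a plain-text VCF
#' plus a JSON truth sidecar (`<path>.truth.json`) carrying the config and
#' the nominal Ne.
#'
#' @param cfg A [sim_config()].
#' @param path Output VCF path.
#' @return The simulation result (list of `genotypes`, `truth`), invisibly.
#' @export
make_fixture <- function(cfg, path) {
  sim <- simulate_population(cfg)
  write_vcf(sim$genotypes, path)
  truth <- sim$truth
  jsonlite::write_json(
    list(config = unclass(truth$config),
         realized_ne_nominal = truth$realized_ne_nominal,
         n_segregating_out = truth$n_segregating_out),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
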