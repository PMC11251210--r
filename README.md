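# ldne

Effective population size (Ne) from linkage disequilibrium in diploid SNP
panels.

Ne is the size of the idealized Wright–Fisher population drifting at the
same rate as a real one, and is the quantity plant breeders watch to judge
how fast inbreeding erodes a germplasm pool. For predominantly selfing
crops such as field pea, a single contemporary SNP panel is often all that
exists — no pedigrees, no temporal samples. `ldne` estimates Ne from that
one panel by exploiting the drift–recombination equilibrium between
linkage disequilibrium and genetic distance (Sved's relation):

```
E(r²) = 1 / (1 + 4 · Ne · c)
```

where r² is the squared correlation of allele dosages at two loci and c is
their genetic distance in Morgans. Rearranged, `1/E(r²) − 1 = 4c · Ne`, so
Ne is the slope of a no-intercept least-squares regression of
`Y = 1/μ̂ − 1` on `X = 4c`. The package implements this as a two-stage
scheme: mean r² is grouped by genetic distance, a stage-1 OLS fit
`μ̂ = β₀ + β₁·c` smooths the decay profile, and the transformed fitted
values feed the no-intercept regression whose coefficient is Ne
(`mode = "paper"`). A `mode = "direct"` variant transforms the binned
means themselves and inverts an exact Sved curve to machine precision,
which is the validation route.

Around the estimator sits the full pipeline a pea (or other crop) panel
needs:

- **VCF I/O** — biallelic SNPs to a samples × variants dosage matrix
  (`read_vcf`, `write_vcf`);
- **marker QC** — MAF ≥ 5%, missingness ≤ 20%, heterozygosity ≤ 20%
  (`apply_filters`), with per-filter attrition accounting;
- **LD engine** — pairwise dosage r² within a 750 kb window
  (`pairwise_r2`), LD-decay curves (`decay_curve`), and per-SNP mean LD
  scores in 1000 kb windows at r² cutoff 0 (`ld_scores`);
- **genetic map** — physical→genetic distance via per-chromosome cM/Mb
  ratios (`genetic_map`, `load_map`, `bp_to_morgans`);
- **simulator** — a forward-time Wright–Fisher model with recombination,
  selfing, missingness and genotyping error (`simulate_population`,
  `make_fixture`) whose known census size grounds parameter-recovery
  tests;
- **driver** — `run_pipeline()` runs everything on one population and
  exports every intermediate table (TSV/BED/JSON); a thin CLI lives in
  `inst/scripts/ldne-cli.R`.

## Worked example

Simulate a random-mating population of census size 100 (2 chromosomes ×
10 Mb at 1 cM/Mb, 300 initial loci each, 200 burn-in generations, 50
individuals sampled), then estimate Ne back from the panel:

```r
library(ldne)

cfg <- sim_config(n_diploid = 100, selfing_rate = 0, seed = 7)
sim <- simulate_population(cfg)
sim$genotypes
#> genotype_matrix: 50 samples x 316 variants on 2 chromosome(s)
#>   missing genotypes: 5.05%

qc <- apply_filters(sim$genotypes, het_max = 1)  # outcrossing panel:
qc$report                                        # het filter off
#> Marker QC report
#>   input variants : 316
#>   failed MAF < 0.05       : 12
#>   retained       : 304

pairs <- add_genetic_distance(pairwise_r2(qc$genotypes, max_bp = 750000),
                              genetic_map(default_ratio = 1))
bins <- bin_mean_r2(pairs, c_round_digits = 4)
estimate_ne(bins, mode = "paper")
#> Ne estimate (paper mode): 155.54
#>   regression points: 75 (dropped mu<=0: 0)
#>   stage 1: mean r2 = 0.4806 + -43.2505 c
```

A single replicate is noisy (drift is one realization); the median over 20
such replicates lands within ±35% of the true census size — that recovery
is asserted by the test suite. Short-range LD in this panel (mean r² ≈ 0.50
within 100 kb, decaying to 0.32 over the 750 kb window) is what the
estimate is read from: stronger short-range LD ⇒ smaller Ne.

On a real panel, start from `run_pipeline("panel.vcf", "outdir",
map = "map.cfg")` with a map config listing cM/Mb ratios (one
`chromosome ratio` pair per line, plus `default`). Keep the 20% het filter
for selfing germplasm — residual heterozygosity there indicates genotyping
artifacts, whereas in outcrossing panels it is real signal.

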