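---
title: "Estimating effective population size from LD decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effective population size from LD decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldne)
```

## The model

At drift–recombination equilibrium in a closed Wright–Fisher population,
the expected squared correlation between alleles at two loci a genetic
distance $c$ (Morgans) apart is

$$E(r^2) = \frac{1}{1 + 4 N_e c},$$

Sved's relation. Drift builds associations between loci; recombination
breaks them down at rate $c$; the balance point depends only on their
product $N_e c$. Rearranged, $1/E(r^2) - 1 = 4c \cdot N_e$: if mean $r^2$
is tabulated against $c$, $N_e$ is the slope of a regression through the
origin of $Y = 1/\hat\mu - 1$ on $X = 4c$.

`ldne` implements this as a two-stage least-squares scheme:

1. **Grouping.** Every intra-chromosomal marker pair within a physical
   window (default 750 kb) gets a dosage $r^2$ and a genetic distance $c$;
   pairs are grouped by $c$ rounded to `c_round_digits` decimals and the
   group mean $r^2$ taken. Rounding makes "group by distance" well defined
   on floating-point values; groups at $c = 0$ carry no recombination
   information and are dropped (counted, never silently).
2. **Stage 1.** Ordinary least squares of mean $r^2$ on $c$ with an
   intercept, solved literally via the normal equations
   $\hat\beta = (X'X)^{-1}X'Y$ with design $X = [1\ c]$. The fitted values
   $\hat\mu$ are the smoothed expected $r^2$.
3. **Stage 2.** $Y = 1/\hat\mu - 1$, $X = 4c$, and
   $\hat N_e = \sum XY / \sum X^2$ — the closed form of a single-column
   no-intercept least-squares fit.

The stage-1 *linear* smooth of a hyperbolic decay curve is an
approximation; it stabilizes noisy bin means but bends the profile. The
package therefore carries two modes. `mode = "paper"` is the two-stage
scheme above; `mode = "direct"` skips the smooth and transforms the binned
means themselves. On data lying exactly on a Sved curve, direct mode
recovers $N_e$ to $10^{-9}$ relative error (a test asserts this for
$N_e \in \{10, 64, 174, 1000\}$); on noisy bins with few pairs each, the
reciprocal transform amplifies sampling error, which is why bin resolution
matters (below). Fitted $\hat\mu \le 0$ — possible at long distances under
a negative stage-1 slope — would make $1/\hat\mu$ undefined; such rows are
excluded and counted rather than clamped, since clamping would bias the
slope. $\hat\mu \ge 1$ is retained (it just yields $Y \le 0$). A profile
with no decay at all yields $\hat N_e \le 0$ and is returned with a
`degenerate` flag and a warning rather than an error.

No finite-sample correction is applied by default: the relation above has
no such term. Because $r^2$ estimated from $n$ individuals is inflated by
roughly $1/n$, an optional `sample_n` argument subtracts $1/n$ from
$\hat\mu$ before the transform for users who want the correction; leaving
it off biases $\hat N_e$ slightly downward at small $n$, which is visible
but tolerable at the panel sizes the package targets.

## From a VCF to the estimator

**QC.** Three marker filters run jointly in one pass on the input
statistics (no sequential recomputation, so the result is
order-independent): minor allele frequency $\ge$ 5% (allele-count
definition: rare alleles inflate $r^2$), missingness $\le$ 20%, and
heterozygosity $\le$ 20%. The het filter encodes an expectation specific
to predominantly selfing species: inbred lines should be nearly
homozygous, so excess hets flag genotyping artifacts (paralogs, sample
mixing). For an outcrossing population heterozygosity is real signal —
set `het_max = 1` there, as the package's own recovery analyses do.
Boundary semantics are exact: MAF exactly at the threshold is kept,
missingness/het exactly at theirs are kept.

**Pairwise r².** Genotypic $r^2$: the squared Pearson correlation of
dosage vectors over samples non-missing at both sites. This is
deterministic and phase-free, unlike haplotype-EM $r^2$; in highly selfed
material the two converge (with near-zero heterozygosity, dosages are
haplotypes). Monomorphic-in-overlap pairs have no defined correlation and
are skipped with a count. No $r^2$ reporting floor is applied anywhere: a
nonzero floor would inflate mean $r^2$ and bias $N_e$ downward. Pairs are
enumerated per chromosome in position-sorted blocks, so memory scales with
the largest chromosome's marker count.

**Distances.** Physical distance converts to genetic distance by a
constant per-chromosome cM/Mb ratio (`c = bp/10^6 × ratio / 100`
Morgans), supplied as user configuration — a deliberate simplification: a
single ratio is what a linkage-map summary provides, and piecewise Marey
maps are an extension point, not a default. Whether one genome-wide ratio
or per-chromosome ratios are used is the user's call; the estimator is
fitted genome-wide by default.

**LD scores.** As a complementary windowed view of local LD, each SNP gets
the *mean* $r^2$ against neighbours within ±1000 kb at cutoff 0 (self
excluded; mean, not sum, so the score is a local LD level, not a density;
SNPs with no qualifying neighbour are reported missing rather than 0).

## The simulator and what passing tests mean

`simulate_population()` is a forward-time Wright–Fisher model on standing
variation: generation 0 draws haplotypes from uniform([0.1, 0.9]) allele
frequencies at uniformly placed loci; each generation, offspring pick one
parent (selfing, probability `selfing_rate`) or two distinct parents, and
each gamete recombines its parent's haplotypes with a Poisson number of
crossovers (rate = map length in Morgans) at uniform positions. There is
no mutation, selection, migration or structure; sites fixed by drift are
dropped at sampling, exactly as a SNP panel would drop them. After
sampling, genotypes are corrupted independently: 5% missing calls and 2%
spurious heterozygotes by default, realistic for reduced-representation
(GBS-like) genotyping and enough to exercise every QC filter. The default
burn-in of $2N$ generations lets LD approach the Sved quasi-equilibrium;
the nominal target for recovery is $N/(1+F)$ with $F = s/(2-s)$ the
equilibrium selfing inbreeding coefficient.

The recovery analyses (test suite and `scripts/acceptance.R`) use census
$N = 100$, random mating, 2 chromosomes × 10 Mb at 1 cM/Mb, 300 initial
loci per chromosome, 50 sampled individuals — a desk-scale panel of a few
hundred markers and a few thousand pairs that runs in seconds per
replicate. At this scale the default distance rounding of $10^{-6}$
Morgans (100 bp at 1 cM/Mb) would leave ~1 pair per group, and the
reciprocal transform of single-pair means is numerically wild; the
recovery protocol therefore groups at $10^{-4}$ Morgans (10 kb), giving
~75 groups of tens of pairs. On dense real panels (thousands of markers,
millions of pairs) the finer default is appropriate. The asserted property
is that the *median* direct-mode estimate over 20 replicate populations
falls within ±35% of 100: a deliberately wide band, because each replicate
is one drift realization and LD-based estimators have heavy-tailed
sampling error. Passing it shows the chain inverts the
drift–recombination signal it models; it does *not* show robustness to
what the simulator omits — population structure, selection, migration,
non-equilibrium demography — all of which confound LD-based $N_e$ in real
germplasm (under high selfing, structure and reduced effective
recombination can bias estimates substantially; the nominal selfing target
is recorded in the simulator's truth output rather than asserted as exact
recovery, for precisely that reason).

## Numerical and design choices

- **Grouping resolution** (`c_round_digits`, default 6): see above; it is
  the one knob that trades group occupancy against distance resolution.
- **Ties and ordering**: variants sort by (chromosome label, position);
  pair tables store each pair once with $i$ before $j$ in position order;
  re-running the pipeline on identical input is byte-identical (no hidden
  randomness anywhere outside the simulator's seed).
- **Missing data**: per-pair complete-case deletion in $r^2$; undefined
  markers (all genotypes missing) are reported as undefined, distinct
  from 0, and always removed by QC.
- **Half-calls** (`./1`) are treated as missing — conservative, since a
  half-call carries one allele but no genotype.
- **Degenerate inputs**: a single distinct distance is a rank-deficiency
  error in stage 1; an empty pair table is a warning (empty result), but
  a pipeline run fails loudly at the LD stage if fewer than 2 markers
  survive QC, with the stage name in the error and a failure marker file.
- **Estimator default** is `mode = "paper"` (the two-stage scheme), with
  `"direct"` as the validation mode; both are exposed everywhere.

## Limitations

Constant recombination ratios per chromosome; genotypic (not haplotypic)
$r^2$; no confidence intervals (jackknife over chromosomes is a natural
extension); a single contemporary $N_e$, not a trajectory; and the
equilibrium assumption itself — recent bottlenecks or admixture violate
it in ways no single-panel LD method can detect from within.
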