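---
title: "Models and methods behind ldrscan"
author: "ldrscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ldrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldrscan)
```

## The scientific problem

A domesticated genome carries two kinds of history. Most of it descends from
the wild progenitor through whatever demographic path domestication took --
bottlenecks, selfing, expansion. But the targets of human selection can
follow a different genealogy: an allele favoured in one cultivated lineage
may have been carried into another by deliberate crossing, so that a genomic
segment is *shared* between cultivars that are otherwise of independent
origin. `ldrscan` implements a pipeline for finding such segments in a
three-taxon design -- a wild outcrossing progenitor (labelled **R**
throughout) and two selfing domesticated taxa (**I** and **J**) -- from
pooled-sequencing allele counts, and for testing whether candidate segments
really follow a different genealogy than the genomic background. The design
is modelled on domesticated Asian rice (two cultivated subspecies plus the
wild progenitor, roughly 21--23 accessions pooled per taxon at about 30X on
each of two sequencing platforms), but every stage is parameterised and runs
on synthetic data at desk scale.

The pipeline has five stages:

1. **Diversity estimation.** Watterson's estimator
   $\hat\theta = S / (a_n L)$, with $a_n = \sum_{i=1}^{n-1} 1/i$ and
   $L$ the callable length, applied to segregating-site counts from
   dual-platform pooled read counts.
2. **Low-diversity regions (LDRs).** A sliding-window scan (100 kb windows,
   10 kb steps) with a genome-shuffle-calibrated cutoff; maximal runs of low
   10 kb tiles become LDR contigs; LDRs shared by both cultivars
   ("overlapping LDRs") are the candidate set.
3. **Genealogy contrast.** Per-site genetic distance $p_1 q_2 + p_2 q_1$ and
   haploid Weir--Cockerham $F_{st}$, summarised by a conditional
   Kolmogorov--Smirnov $D$ statistic comparing overlapping LDRs to the
   genomic background, with significance from coalescent-simulation nulls.
4. **Candidate genes.** Within significant regions, genes carrying at least
   one nonsynonymous site with $F_{st}(I,R) > 0.8$, $F_{st}(J,R) > 0.8$ and
   $F_{st}(I,J) < 0.1$.
5. **Synthetic data.** A two-phase coalescent simulator plus pooled-read
   emulator that generates every input the other stages consume.

## The two-phase coalescent

Both cultivars are presumed selfers after domestication, which suppresses
effective recombination by a factor $(1-s)$ for selfing rate $s$. The
simulator therefore partitions each locus's history at the domestication
time $T_d$:

* **Phase 1 (present $\to T_d$).** Each cultivar sample coalesces inside its
  own bottlenecked population ($N_I$, $N_J$) with *no* recombination at the
  default $s = 1$: one genealogy fragment is shared by the entire locus.
* **Phase 2 (older than $T_d$).** The wild phase recombines freely, so the
  locus is partitioned into sub-segments with geometric breakpoints; given
  the cultivar lineages surviving at $T_d$, each sub-segment's wild-phase
  genealogy is drawn independently. The wild sample itself (R) coalesces
  per sub-segment from the present, since R recombines throughout.

Times are in units of $4 N_R$ generations and the scaled mutation rate is
$\theta = 4 N_R \mu$ per site (the ms convention); a haploid lineage pair in
a population of relative size $c$ coalesces at rate $2/c$, so
$E[T_2] = 0.5$ for $c = 1$. Mutations are laid down under the infinite-sites
model, Poisson along branches, giving $E[S] = a_n \theta L$ in the
single-population limit -- both properties are verified by Monte-Carlo tests
against closed forms.

Two topologies are supported. Under **independent domestication**, I and J
each split from R at $T_d$ (a trifurcation; with symmetric sizes the two
wild--cultivar distances are equal in expectation). Under **sequential
domestication**, a single domesticated stem splits from R at $T_d'$ and I
and J separate at `T_split` $< T_d'$, making the cultivars sisters. The
interface exposes `T_split` explicitly (default $T_d'/2$) and a stem size
`N_D` (default $N_I + N_J$), because a single shared-domestication time
underdetermines the model.

For partial selfing ($0 < s < 1$) a sub-segment re-draws its cultivar
genealogy with probability $1 - \exp(-(1-s)\,\rho\,\ell)$ for sub-segment
length $\ell$ and breakpoint rate $\rho$. This Bernoulli refresh is an
approximation (exact at $s \in \{0, 1\}$); the package's analyses all use
the fully selfing default, which matches the phase-1 construction above.

`T`, the nominal age of the deepest split, only validates that
$T_d < T$: under both topologies the pre-domestication history is a single
wild population, so the sample's MRCA time is an outcome of the simulation
rather than an input.

### Introgression events

`inject_sweep_introgression()` models the event of interest: a segment
selected in a donor cultivar and then introgressed into the other. Within
the region, every recipient haplotype -- and, with `sweep_donor = TRUE`
(default), every donor haplotype -- is replaced by one randomly chosen donor
haplotype, so the region is monomorphic within and identical between the two
cultivars while the wild taxon keeps its variation. Optional post-transfer
mutations (rate $\theta \cdot t$ per lineage for transfer age $t$) let the
region re-diverge.

### Pooled-read emulation

`simulate_pooled_platform_reads()` draws, per site, per platform, a Poisson
read depth, reads from the pool's haplotype frequencies, and independent
symmetric substitution errors per read base (uniform over the three other
alleles). Independence of errors *between* platforms is the property the
combined-platform filter exploits. The emulator does not model: mapping
bias, indels, base-quality structure, correlated (systematic) platform
errors, or unequal pooling of accessions. Passing tests therefore show that
the estimators behave correctly under the stated error model, not that real
platform artefacts are fully captured.

## Site calling and diversity estimation

A site is *callable* when both platforms cover it with at least
`min_coverage` reads (6 for taxon-level estimates, 4 for the window scan).
The majority allele is taken from the combined counts; the focal variant is
the most frequent non-majority allele (other alleles are ignored). The
schemes are `S` (variant seen on both platforms), `S_>1` (variant count
$\ge 2$ on both -- the default for all scans), and `S_>2` ($\ge 3$ on
both). A variant-read threshold is not the same thing as an allele-class
threshold: at high coverage a single carrier contributes many reads, so
read-level `S_>1` removes *read* singletons, while the analytic expectation
$E[\hat\theta_{>1}] = \theta\,(a_n - 1 - 1/(n-1))/a_n$ refers to removing
sample allele classes 1 and $n-1$. The estimator-recovery experiment
reports both flavours and checks the analytic value on sample classes.

Haploid sample sizes follow the pooling design: selfing cultivar accessions
contribute one lineage each, the outcrossing wild accessions two (e.g.
$n = 21, 22, 46$ for 21 J / 22 I / 23 R accessions).

Windows slide 100 kb / 10 kb and are emitted only with $\ge$ 10,000
callable sites; $\hat\theta$ uses the window's own callable length, so
coverage gaps do not bias it. Each 10 kb tile takes the median of its
covering emitted windows ($\ge 4$ required; even counts use the mean of the
central pair), and a tile is *low* iff its median is strictly below the
cutoff. Windows never extend past a chromosome end, and dropped tiles break
contig runs.

## The shuffle-calibrated cutoff

The cutoff asks: how low can a window go by chance alone, if local structure
is destroyed? The genome is cut into 1 kb units, the units are permuted
genome-wide (200 times), each permutation is re-cut into the original
chromosome lengths, and the minimum window $\hat\theta$ (over non-overlapping
100 kb windows obeying the callable rule) is recorded. The cutoff is the
10th smallest of the 200 minima, i.e. an empirical significance of
$10/200 = 0.05$: about 95% of fresh shuffled genomes show no window at or
below it, and the offenders show only one or two. Non-overlapping windows
are used inside the shuffle (the real scan slides): a single low stretch
under a sliding scan would be counted ~10 times, and tiling makes
"number of offending windows" a meaningful small count. A per-chromosome
shuffle variant is available behind a flag.

## Differentiation statistics

Per-site allele frequencies for the three-taxon analysis combine both
platforms, require $\ge 10$ reads in *all three* taxa, and drop sites whose
pooled minor-allele count is exactly 1 (combined singletons, mostly
sequencing errors). Genetic distance between populations at a SNP is
$p_1 q_2 + p_2 q_1 \in [0, 1]$, averaged unweighted over SNPs in a segment.

$F_{st}$ uses the Weir--Cockerham moment estimator adapted to haploid
allele-frequency data (the classical estimator is defined for diploid
genotype data; the haploid adaptation is ours, cross-checked in the tests against two
independent implementations, one of them `stats::aov` mean squares on
indicator data). Negative estimates are clamped to 0, values above 1 to 1.
At sites monomorphic within a pooled pair the estimator itself refuses
(0/0); the pipeline-level record builder assigns $F_{st} = 0$ there, because
"both populations fixed for the same allele" is exactly the
no-differentiation signal that introgression-shared sites carry.

The **conditional D statistic** compares the empirical CDF of
$F_{st}(I, J)$ at sites inside overlapping LDRs against the genomic
background, restricted to sites with $F_{st}(R, I) \ge 0.5$ -- where the two
most polymorphic taxa are differentiated enough for the genealogy to be
resolvable ($\ge$ keeps the boundary; threshold 0 reproduces the all-sites
analysis). $D$ is the maximum vertical ECDF distance (a two-sample KS
statistic), computed over sites, not windows. Its null distribution comes
from full simulated replicates: each replicate simulates a complete
multi-locus dataset under one history, designates LDR analogues by the same
lowest-5%-diversity rule (ranked by the I taxon's per-locus
$\hat\theta$, as in the single-cultivar bottom-5% analysis), applies the
same conditioning, and computes the same $D$. The empirical p-value is
$(1 + \#\{D_{null} \ge D_{obs}\}) / (1 + \#null)$. How LDR analogues are
designated inside null replicates has no canonical definition; the
bottom-fraction rule is our documented choice, and
`simulate_null_D()` accepts a list of models so the null can span several
parameter combinations.

Per-region significance uses two one-sided two-sample KS tests
($F_{st}(I,J)$ stochastically smaller than $F_{st}(R,J)$, and than
$F_{st}(R,I)$), both at a nominal uncorrected 5% (asymptotic p-values;
exact small-sample computation behind a flag). Regions with fewer than
`min_sites` (default 10) records are untestable, never significant. No
multiple-testing correction is applied by default, so the screen keeps its
nominal per-region level.

## Candidate genes

Within KS-significant regions, a gene is a candidate iff it contains a
nonsynonymous site with $F_{st}(I,R) > 0.8$, $F_{st}(J,R) > 0.8$ and
$F_{st}(I,J) < 0.1$, all strict. Coding effects are classified by
strand-aware codon translation under the standard nuclear code; a site is
nonsynonymous if the amino acid changes in *any* overlapping transcript.
GFF3 coordinates (1-based inclusive) are converted to 0-based half-open at
the reader boundary. We require the qualifying site to lie inside the gene
body and the gene to overlap the significant region; whether the site must
also lie inside the LDR proper is a genuinely open design point; we take
the laxer reading.

## Chosen defaults and problem sizes

The generator's default demography was calibrated once so that the
synthetic taxa reproduce the diversity ratios characteristic of the rice
system
($\hat\theta_I/\hat\theta_R \approx 0.92$,
$\hat\theta_J/\hat\theta_R \approx 0.22$, $\hat\theta_R \approx 4$/kb):
$N_I = 0.6\,N_R$, $N_J = 0.04\,N_R$, $T_d = 0.025$, $\theta = 0.004$/site,
full selfing, wild breakpoint spacing $\approx 500$ bp (consistent with
linkage disequilibrium extending only a few kb in the wild taxon). No
established parameter set exists for these domestication histories, so
these values are plausible calibrated choices, not measurements.

Experiments run at deliberately scaled-down sizes chosen once:

* *Estimator recovery*: 500 error-free loci of 10 kb, $n = 22$,
  $\theta = 4$/kb, at 100X per platform so that site-calling completeness is
  ~1 and the experiment isolates the estimators; the error-robustness
  experiment instead uses the pooled-sequencing design being emulated (30X,
  0.5% per-platform errors,
  100 loci).
* *Genealogy contrast*: datasets of 200 independent 10 kb loci; 10 injected
  introgression loci = the bottom-5% designation size; 200 null replicates;
  50 calibration datasets. The demography for this experiment uses a more
  pronounced cultivar bottleneck ($N_I = 0.2\,N_R$, $N_J = 0.1\,N_R$) than
  the diversity-calibrated default: at 1/1000 of a real genome the
  $F_{st}(R,I) \ge 0.5$ conditioning would otherwise retain too few
  background sites per dataset for the ECDFs to be estimable. This is a
  statement about desk-scale resolution, chosen at design time and fixed.
* *Distance pattern*: 30 replicate genomes of 80 × 2 kb loci with 4
  injections, under a symmetric independent model ($N_I = N_J = 0.15 N_R$),
  which is the setting in which the two wild--cultivar background distances
  are predicted equal.
* *Candidate screen*: 20 replicates of 12 × 5 kb regions (one gene each),
  3 planted introgressions with one nonsynonymous divergent site each,
  overlapping-LDR designation by the bottom 30% per cultivar.

```{r, eval = FALSE}
# the worked pipeline at these sizes, end to end
scan <- demographic_model("independent", N_I = 2e4, N_J = 1e4)
cfg <- d_pipeline_config()
set.seed(1)
obs <- conditional_fst_D(make_two_history_genome(scan, cfg, 10)$genome, cfg)
simulate_null_D(scan, 200, cfg, observed_D = obs$D)
```

## Numerical and degenerate-input choices

* Median of an even window count = mean of the two central values; ties at
  the cutoff are *not* low (strict inequality).
* Bottom-fraction designation keeps `ceiling(fraction * n)` tiles; ties at
  the boundary break by (chromosome, start).
* LDR size bins are left-closed in bp ($[200\,000, 300\,000)$ etc.), so
  every size maps to exactly one bin and a 200 kb contig is "200--300".
* Infinite-sites positions are continuous; the read emulator floors them to
  integer bp and shifts the rare collisions to the nearest free base.
* Fst at pair-monomorphic sites: 0 by convention at the record level,
  an error at the `weir_fst()` level (see above).
* Empty inputs return typed empty tables; invalid model/region parameters
  error at construction.

## Known limitations

* The partial-selfing refresh approximation ignores linkage between
  neighbouring sub-segments' cultivar genealogies.
* The error model is site- and platform-independent; systematic errors
  shared by both platforms defeat the combined filter by construction.
* The null-replicate LDR designation rule and the haploid Weir--Cockerham
  adaptation are interpretations, as flagged above.
* Direction of introgression (I to J versus J to I) is out of scope; the
  injected events are symmetric in the statistics used here.
* The simulator book-keeps haploid lineages only: no diploid genotypes,
  phasing, or indels.
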