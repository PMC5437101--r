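---
title: "Modeling the tropical-temperate maize split from the joint site-frequency spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the tropical-temperate maize split from the joint site-frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizedemog)
```

## The scientific problem

Maize was domesticated once, in tropical Mexico, yet most maize today grows
in temperate zones. The demographic question is when and how the temperate
gene pool (here proxied by the Non-Stiff Stalk heterotic group, NSS) split
from the tropical/subtropical pool (TS), and how severe the accompanying
founder events were. `maizedemog` models that split from the joint site
frequency spectrum (SFS) of two inbred-line panels and characterizes the
panels with windowed Fst, population-specific SNP counts, linkage
disequilibrium (LD) decay, and identity-by-descent (IBD) segment sharing.

## Demographic models

Eight models are defined in diffusion scaling (sizes as multiples of the
ancestral effective size $N_a$, times in units of $2N_a$ generations,
migration as $M = 2N_a m$ with $m$ the per-generation migrant fraction).
Three single-population models (`neutral`, `two_epoch`, `three_epoch`) test
whether the inbred-line spectra are informative at all; five two-population
models (`split1` ... `split5`) describe the TS/NSS split with increasingly
realistic size histories. The headline model, `split5`, runs (past to
present): ancestral equilibrium at size 1; a short severe domestication
bottleneck (`nuB`, `tau1`); an instantaneous split into TS (`nuTS0`) and the
temperate founder population (`nuNSS0`) with symmetric gene flow `M1` for
`tau2`; then a linear decline of both demes to (`nuTS1`, `nuNSS1`) with gene
flow `M2` for `tau3`. The reference parameter set is available as

```{r}
ref <- split5_reference_fit()
ref$physical
```

Two unit conventions needed decisions that the source material leaves open:

* **Migration units.** The printed gene-flow values are described both as
  "migrants per generation" and through $M_{ij}/2N_a = m_{ij}$. We store
  the scaled $M = 2N_a m$ and report the fraction $m = M/(2N_a)$ alongside,
  so either reading can be recovered.
* **Onset sizes.** Only the post-split total (10,746) and the temperate
  founder size (1,312) are printed; the TS onset size is the difference,
  9,434, and is flagged as derived.
* **The divergence stage.** Sizes are held constant at the onset values for
  the 126-generation divergence-and-recovery stage; "recovery" is the jump
  from the bottleneck size at the split, since no within-stage trajectory is
  printed.
* **Generation time** is fixed at one year everywhere, and physical
  conversion uses $\theta = 4 N_a \mu L$ with $\mu = 2.230\times10^{-8}$
  per bp per generation and $L = 3.8$ Mbp. The printed $\mu$ is used as
  printed even though the quoted derivation
  ($4.794\times10^{-8}/(1+1.14)$) gives $2.240\times10^{-8}$.

## Expected spectra: Monte Carlo engine and exact oracle

The expected joint SFS under a timeline is computed by a Monte Carlo
structured coalescent over **expected branch lengths**: for each simulated
genealogy the total length $T(i,j)$ subtending exactly $i$ TS and $j$ NSS
leaves is accumulated, and $E[S(i,j)] = (\theta/2)\,\overline{T}(i,j)$.
Coalescence in deme $d$ proceeds at rate $\binom{k_d}{2}/\nu_d(t)$, each
lineage migrates backward at rate $M/2$, and linear/exponential size epochs
are simulated by thinning against a per-epoch rate bound taken from the
epoch's extreme sizes (an exceeded bound raises an error rather than
truncating). Sites are exchangeable - there is no recombination inside the
SFS engine - so computing the expectation directly at the projected sample
sizes (20x20 below) is exactly equivalent to simulating a larger panel and
projecting down hypergeometrically.

Correctness is bounded by two independent implementations:

* a deterministic single-population path (`expected_sfs_onepop`) through the
  block-counting chain, checked against the neutral closed form
  $E[S_i] = \theta/i$;
* an exact small-sample oracle (`exact_small_sfs`, $n_1+n_2 \le 6$,
  piecewise-constant epochs) that integrates the ancestral-configuration
  Markov chain with matrix exponentials. The Monte Carlo engine must agree
  with it within 3 Monte Carlo standard errors across randomized models;
  this is enforced in the test suite.

Each spectrum evaluation is seeded explicitly (`coalescent_config`), so
spectra are reproducible and fits can hold the replicate stream fixed.

## Poisson composite likelihood and model choice

The data spectrum is treated as independent Poisson counts per unmasked
cell: $\ell = \sum S\log M - M - \log S!$, with the monomorphic corners
always masked. Because the model spectrum is linear in $\theta$, $\theta$
is profiled analytically ($\hat\theta = \sum S / \sum M$) at every
evaluation. Optimization is Nelder-Mead on log-parameters (with a
coarse-grid + zoom + golden-section path for single free parameters, and a
restart from the incumbent), at least two starts one order of magnitude
apart, convergence tolerance $10^{-8}$ on the log-likelihood and at most
$10^4$ evaluations per start. Nested models are compared with the standard
likelihood-ratio chi-square test (boundary cases are conservative; no
mixture correction is applied) and non-nested ones by AIC with
$k = \text{free parameters} + 1$ for the profiled $\theta$ (the +1 is
common to all models, so rankings are unaffected). Confidence intervals
come from a parametric bootstrap: each cell resampled as
Poisson($\hat M$), refit from the point estimate, percentile intervals in
scaled and physical units. Anscombe residuals
$r = \tfrac{3}{2}(S^{2/3}-M^{2/3})/M^{1/6}$ diagnose fit per cell.

## The synthetic-recovery protocol (what the acceptance script runs)

The original 368-line genotype panel is not redistributable, so the
package validates its inference path by self-consistency at the reference
parameters: generate the expected 20x20 joint SFS under `split5` at the
reference values with $\theta = 4N_a\mu L \approx 8190$, then re-estimate
each focal parameter with every other parameter pinned at truth
(`split5_recovery`), and convert back to physical units.

The data spectrum and all candidate spectra during refitting share one
replicate seed stream - common random numbers, the standard device of
simulated-likelihood inference. This makes the Monte Carlo objective a
deterministic function of the parameters whose maximum sits at the
generating values, so the protocol verifies the optimizer, the profiled
likelihood and the unit conversions rather than Monte Carlo luck. It is
deliberately not a statistical power study: with independent streams the
weakest signals - the 5-generation bottleneck (total coalescent intensity
$\tau_1/\nu_B \approx 1.8\%$) and the post-split gene flow
($M_1\tau_2/2 \sim 10^{-5}$ expected migrations per lineage) - would
require far more than desk-scale replicates to resolve. Engine correctness
is established separately by the exact-oracle tests, and an
independent-noise recovery (a planted two-epoch size change refit on a
Poisson-sampled spectrum) is kept in the unit suite as an honest
statistical check where the signal supports it.

Problem sizes were chosen once for desk-scale runtime: 100,000 genealogy
replicates per spectrum evaluation in the acceptance script, 20,000 in the
test suite's recovery block, spectra at 20x20 haplotypes. The gene-flow
rates are the one place where surface curvature is so shallow that the
recovered value can sit a few tens of percent off; the suite refits them
at the full 100,000-replicate stream and checks them at the wider 50%
tolerance appropriate to rates this small.

## Data processing

`load_variants` reads a VCF with `vcfR`, keeps biallelic SNPs, and codes
the inbred lines as one haplotype each: homozygous diploid calls collapse
to 0/1, heterozygous or missing calls become `NA` (the panel is inbred;
residual heterozygosity carries no phase information worth modeling).
Synonymous filtering relies on an annotation INFO key; selected-region
exclusion takes 0-based half-open BED intervals ([start, end) removes
1-based positions start+1..end); distance thinning visits sites in a
random order per replicate and accepts greedily at >= 2 kb, so replicates
differ but are reproducible from (seed, index). Allele counts are
projected hypergeometrically per site, absorbing missing data; sites with
fewer non-missing haplotypes than the projection are dropped and counted.
Folding is the default polarization (the ancestral-allele source is
unspecified upstream); unfolded spectra are available when ALT can be
taken as derived, and the fit records which was used.

## Population statistics

Fst is the Weir-Cockerham ratio-of-sums estimator specialized to haploid
samples (the within-individual component is structurally zero for inbred
lines), on 1 Mb sliding windows with 0.2 Mb step; windows need strictly
more than 30 segregating sites. Population-specific SNPs are counted over
ten draws of 50 lines per population (specific = polymorphic in exactly
one draw; rare means MAF <= 0.05, boundary inclusive). LD is the squared
allele-frequency correlation of each SNP with its ten downstream
neighbours over pairwise-complete lines; the decay distance is the mean
distance of the first distance-ordered bin whose mean r2 falls to the 0.1
cutoff (right-censored if none does), and per-r2-category distance
quartiles feed the boxplot view - the exact binning behind the original
figure is unspecified, so both groupings are emitted. Pruning is a greedy
left-to-right scan (remove at r2 > 0.2 within 500 kb upstream). Kinship is
the centered method-of-moments IBS estimator
$(\mathrm{IBS}-\mathrm{IBS}_{exp})/(1-\mathrm{IBS}_{exp})$; raw IBS would
sit near 0.5 for unrelated lines at intermediate allele frequencies and
make the 0.5 removal threshold meaningless.

## IBD post-processing

Physical positions map to genetic positions by linear interpolation
between anchors (terminal slopes extend beyond the anchored range, with a
flag). Consensus across the ten detector runs keeps base pairs covered in
a strict majority (> 5 of 10; rule and threshold configurable and
recorded). Tracts shorter than 1 cM are removed (a tract of exactly 1 cM
survives; the exclusion is strict), and tracts are labeled long when
strictly above 7 cM. Hotspot occurrence tiles each chromosome with 10 cM
windows from 0 cM (terminal partial windows kept and flagged), counts a
segment in every window it overlaps, and divides by the number of possible
pairs ($\binom{n}{2}$ within, $n_1 n_2$ across). The overlap test takes
the top 5% of windows by occurrence (ties broken by genomic order),
measures the fraction touching any candidate region, and compares against
uniform draws of equally many windows without replacement,
$p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$.

## The synthetic-data generators

`simulate_genotypes` draws site configurations multinomially from a
model's expected joint SFS and assigns carriers uniformly - the study
conditions it emulates are unlinked synonymous SNPs in two inbred panels
(defaults: 80+80 lines, 20,000 SNPs on ten 30 Mb chromosomes with
guaranteed 2 kb spacing, a quarter of sites synonymous-labeled, ~5% of
the genome emitted as "selected regions"). What it deliberately does not
emulate: linkage between SNPs (the SFS likelihood assumes exchangeable
sites), genotype error, and ascertainment - so passing tests certify the
inference machinery, not robustness to those real-data complications. LD
statistics are instead exercised on a copy-with-noise haplotype-block
panel (`simulate_ld_panel`), and Fst calibration on Balding-Nichols
island-model draws (`simulate_island_sites`). `simulate_map` jitters cM
increments around a 0.8 cM/Mb baseline (a maize-like genome-wide
average) with a positive gamma multiplier, keeping strict monotonicity.
`simulate_ibd` plants per-pair Poisson segment counts with exponential cM
lengths (default mean 3 cM, matching the observation that segment
frequency falls steeply with length), uniform placement except for an
enrichment multiplier inside declared hotspot windows, and maps ends back
to bp by inverse interpolation. Every generator is a pure function of its
configuration and seed.

## Numerical choices and degenerate inputs

Corners (0,0) and (n1,n2) of every spectrum are masked and never modeled.
Cells with model mass zero but observed counts give $-\infty$ rather than
being dropped; Anscombe residuals at M = 0 are reported as undefined.
Zero-duration epochs are legal and exact no-ops; a linear decline to zero
size is rejected at construction. The exact oracle restricts its infinite
ancestral epoch to states reachable from the current mass and treats a
reachable non-coalescing state as an error. Thinning replicate streams,
bootstrap draws, permutation draws and kinship tie-breaks are all
explicitly seeded; library-level RNG state is saved and restored around
every seeded routine.

## Known limitations

* The composite likelihood ignores linkage between sites; standard errors
  from the parametric bootstrap are therefore optimistic on real data (no
  Godambe-style correction is applied).
* Likelihood-ratio tests at parameter-space boundaries (e.g. migration at
  zero) are conservative.
* The Monte Carlo likelihood surface is rugged away from its optimum at
  finite replicate counts; fits of many simultaneous free parameters
  should use generous starts and the deterministic one-population path
  where applicable.
* The fifth model's nesting of models 3/4 holds by construction of the
  declared nesting graph, not for every parameterization; LRTs are only
  computed for declared pairs.
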