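---
title: "Shared polymorphism, drift persistence and gene flow: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared polymorphism, drift persistence and gene flow: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suprapop)
```

This vignette documents the models behind `suprapop`, the assumptions they
make, the parameters that matter, and the numerical and design choices a
user should know before trusting the output.

## 1. The scientific question

When two species that diverged millions of years ago still segregate the
same biallelic SNPs, there are two candidate explanations: retained
ancestral polymorphism (incomplete lineage sorting) or ongoing gene flow
through hybridisation. Neutral drift purges polymorphism at a rate set by
the effective population size, so the first explanation has a quantitative
budget — and when observed sharing exceeds it, gene flow is implicated.
`suprapop` implements that budget (the persistence-time calculus), the
machinery to measure sharing in genotype panels, and a simulator to explore
the gene-flow alternative.

## 2. The persistence-time calculus

### Model

For a neutral biallelic locus at initial minor-allele frequency $p$ in an
ideal Wright-Fisher population of diploid effective size $N_e$, the
diffusion approximation gives the expected time until absorption (loss or
fixation, whichever comes first):

$$t(p) = -4 N_e \left[(1-p)\ln(1-p) + p \ln p\right].$$

`mean_persistence_time()` evaluates this directly. Properties the test
suite verifies: symmetry in $p \leftrightarrow 1-p$, strict increase on
$(0, 0.5]$ with maximum $4 N_e \ln 2$ at $p = 0.5$, exact linearity in
$N_e$, and $t \to 0$ at the boundaries (boundary inputs return 0 with a
warning — the allele is already absorbed).

### Parameters

* **`census_size`** ($N_c$, individuals): taken from census estimates
  (upper bounds where a range is published). The built-in
  `anas_population_params()` carries the six duck taxa of the study system.
* **`ne_ratio`** (default **0.1**, dimensionless): $N_e = 0.1\,N_c$ is a
  deliberately conservative (high) choice for r-selected waterfowl whose
  censuses are winter counts and whose sizes fluctuate strongly; measured
  waterfowl ratios run roughly 0.05–0.09. A higher ratio lengthens every
  persistence time, making "sharing exceeds the neutral budget" harder to
  conclude — i.e. the conservative direction.
* **`generation_time`** (default **1 year**): ducks breed in their first
  year. The threshold and year-scale outputs depend on $N_e$ and generation
  time only through their product, which is why `scenario_analysis()`
  implements "three times higher $N_e$ *or* generation time" as a single
  multiplier.
* **`retention multiplier`** (default **3.8** generations per $N_e$): the
  horizon beyond which only a small tail of initially balanced
  polymorphisms still segregates. Section 4 shows what "small" means
  precisely.

### The published table and one misprint

`species_persistence_table()` reproduces the published six-species
persistence table cell-for-cell at $p \in \{0.5, 0.1\}$ — except one cell.
The published *Anas strepera* $p=0.1$ value (702,179) equals the *Anas
acuta* $p=0.1$ value exactly, while the closed form with $N_e = 380{,}000$
gives 494,126. We treat the published cell as a typesetting duplication:
the package always reports the formula value, and `render_report()` prints
an explicit note (`anas_published_persistence()` carries the flag).

### Rounding conventions

Generation counts are rounded half-up to integers (`round_half_up()`;
base R's half-to-even would disagree with conventionally rounded published
values on exact .5 boundaries). Year-scale horizons are reported in
millions of years to one decimal (7.2, 6.2, 7.9, 3.8, 4.3 under the
default and triple scenarios).

## 3. Genotype QC and sharing

Genotypes are coded 0/1/2 (copies of the alternate allele) with `NA` for
missing; the TSV dialect (`individual_id`, `species`, `locality`, then one
column per locus) is hand-editable, and biallelic VCF input is supported
through `vcfR` with multi-allelic records skipped and a warning. Per-group
statistics (`summarize_locus()`) use only called genotypes: MAF is the
rarer allele's count over $2 n_{called}$, observed heterozygosity the
heterozygote fraction of called individuals.

**Hardy-Weinberg testing.** `hwe_exact_test()` is the exact conditional
test: given the sample's allele counts, every attainable heterozygote count
$h$ (they share the parity of the rare-allele count) is enumerated with

$$P(h) = \frac{n!\,2^h}{n_{AA}!\,h!\,n_{aa}!}\Big/\binom{2n}{n_A},$$

and the two-sided p-value sums configurations no more probable than the
observed one (probability-ordering convention, stated here because other
orderings exist). Full enumeration is cheap for biallelic loci and, unlike
a Markov-chain exact test, deterministic. Two consequences worth knowing:
p-values are discrete and therefore *conservative* — their null
distribution is approximately uniform but satisfies
$P(p \le \alpha) \le \alpha$; the tests assert exactly that, not exact
uniformity, which no discrete test can deliver.

**"Polymorphic in species"** is a sample-level property: both alleles
observed among called genotypes, no frequency floor. This matches what a
genotyped panel can actually assess; population-level polymorphism at
unobserved frequencies is out of reach by design. Loci with all calls
missing in a group are excluded from that group's sharing set (with a
message). `sharing_venn()` computes all $2^k - 1$ exclusive regions for
2–6 species sets; region keys use alphabetical set-name order so results
are invariant to input order, and region counts provably sum to the union
size.

**LD bookkeeping.** Only the multiple-testing arithmetic is implemented:
`pairwise_test_count(n)` $= n(n-1)/2$ (364 loci give 66,066 pairwise
tests) and `bonferroni_alpha()`. Haplotype-based LD estimation itself is
deliberately out of scope. We read the published "each SNP is involved in
66066 pairwise tests" as the *total* pair count, which is what
$\binom{364}{2}$ supports (each individual SNP sits in 363 pairs).

## 4. The Wright-Fisher simulator and its oracle

`simulate_absorption()` iterates the binomial resampling chain
$X_{t+1} \mid X_t \sim \mathrm{Binomial}(2N, X_t/2N)$ for many replicate
loci in one vectorised stream (results are replicate-order independent and
fully determined by the seed). Unabsorbed replicates at `max_generations`
(default $40N$) are reported separately, never silently counted as
absorbed.

`markov_absorption_oracle()` is the validation anchor: the exact
$(2N{+}1)$-state transition matrix, expected absorption times from
$(I-Q)\,t = \mathbf{1}$, fixation probabilities from a linear solve
(checked against the martingale value $i/2N$), and exact segregation
probabilities at any generation by matrix powering
(`oracle_segregating_prob()`). It is dense linear algebra, so it is capped
at $2N \le 400$ — which is ample, because the bridge to realistic
population sizes ($N_e \sim 10^6$) is the calculus of Section 2: $t(p)$ is
linear in $N_e$, and the tests verify the oracle/diffusion ratio converges
to 1 as $N$ grows (0.985 at $N = 50$).

**What "5% retained after 3.8 N generations" means.** The exact oracle
puts the single-population probability that a $p_0 = 0.5$ polymorphism
still segregates at $3.8N$ generations at $\approx 0.22$ (Kimura's
large-$t$ expansion $6p(1-p)e^{-t/2N} = 1.5\,e^{-1.9} \approx 0.224$). The
*square* of that — joint retention in **two** lineages drifting
independently, which is what shared polymorphism between two isolated
species requires — is $\approx 0.047 \approx 5\%$. The simulator reports
both readings; the joint one is the scientifically relevant interpretation
of the 3.8 $N_e$ threshold for *shared* SNPs, and the one this package
documents.

**Gene flow.** `simulate_divergence_with_geneflow()` couples two
populations by symmetric gametic migration: each generation population
$i$'s gamete pool is $(1-m)f_i + m f_j$ before resampling. $m$ is a free
parameter (no hybridisation rate is quantified for the study system);
$m = 0.5$ makes both pools identical, and the combined allele count then
follows exactly a single Wright-Fisher population of the summed size —
the test suite exploits this for validation. Note one definitional
subtlety: "jointly segregating" (both demes polymorphic *within their own
$2N$ copies*) sits slightly below "segregating in the merged pool", since
a locus can be momentarily monomorphic in one deme; at desk scale the gap
is about one percentage point and the binomial intervals of the two
quantities overlap.

## 5. The synthetic-panel generator

`simulate_panel()` emulates the study design: candidate loci receive
ancestral MAFs uniform on $[0.05, 0.5]$ (the true ancestral spectrum of
the panel is unknown; uniform is a documented default, not a claim, and
the minor allele is assigned to the alternate allele with probability
1/2); the focal lineage drifts from the root to the present; every other
species branches off the stored focal trajectory at its divergence time
and then drifts with one-way migration from the contemporary focal
frequency (star topology — the focal species is by far the most abundant,
so focal-to-other introgression dominates; a topology-faithful multi-species
tree is deliberately not modelled). Ascertainment draws a finite focal
discovery sample (default 24 individuals) and retains only loci
polymorphic in it — the mechanism that produces real panels' upward MAF
bias, which the tests confirm. Genotypes are then drawn under
Hardy-Weinberg proportions within species (panmixia per species — this is
also what keeps the HWE test calibrated on null data), missing calls are
injected independently per species, and F1 hybrids receive one allele from
each parent species' frequency.

**Default conditions.** The defaults mirror the study shape: a 364-locus
panel, six species at sample sizes 197/7/9/14/10/17, missingness 0.04
(focal) and 0.14–0.24 (others), one F1 hybrid. Drift runs at a desk scale
obtained by dividing both effective sizes and divergence times by $10^4$
($N$ = 190/54/69/33/38/29; divergence 640 or 800 generations), which
preserves each species' drift intensity (divergence measured in units of
$N$) while keeping generation costs trivial. Hybridisation rates
(0.002/0.002/0.0005/0.0005/0.0001 toward acuta/crecca/penelope/strepera/
fuligula) were fixed once so that per-species sharing falls in the
qualitative gradient the study observed; they are not estimates. The
candidate pool (8,000) is large because focal drift absorbs most
candidates before ascertainment (~13% survive the discovery sample).

**What the generator does *not* emulate**, hence what passing tests do not
show about real data: no linkage or recombination structure (the panel's
SNPs are treated as unlinked, as in the study); no mutation after
divergence; no population substructure or assortative mating within
species; no genotyping-error model (missingness is independent, whereas
real missingness from cross-species probe failure is locus- and
divergence-correlated); and a star topology rather than the true species
tree. One visible consequence: under these near-neutral defaults the
four-species *core* of shared loci is essentially empty (0–1 of 364),
because migration-regenerated sharing is nearly independent across
species. An observed core of many loci therefore indicates strongly
correlated connectivity — which is precisely the argument the persistence
analysis is built to support, but it means the generator should not be
used as a null model for the core count without raising the hybridisation
rates.

## 6. Pipeline and reproducibility

`run_pipeline()` executes input → QC → sharing → persistence → scenarios →
simulation from a single declarative (YAML-loadable) configuration, writes
every stage as plain TSV/JSON plus a manifest (seed, package version,
stage list, config echo), aborts with a stage-named error on failure, and
is byte-identical across runs under a fixed seed (verified in the tests).
All randomness flows from the single configured seed; the synthetic
module's stages use fixed small offsets of it so each stage is
independently reproducible.

## 7. Numerical choices and degenerate inputs

* HWE enumeration works in log-space (`lfactorial`) and normalises within
  the attainable set; ties at the observed probability are included with a
  $1 + 10^{-12}$ relative guard, so equal-probability configurations are
  not dropped to floating-point noise. Monomorphic samples have a single
  attainable configuration and return $p = 1$ exactly.
* `mean_persistence_time()` uses `log1p(-p)` for accuracy at small $p$.
* Loci with zero called genotypes in a group report `NA` statistics and a
  missing-fraction of 1; they are excluded from sharing sets with a
  message rather than silently.
* The Markov oracle refuses $2N > 400$ rather than returning a slow or
  ill-conditioned answer.
* Problem sizes used by the validation suite — $N \le 100$ for oracle
  comparisons, $2N$-generation horizons, $10^3$–$3\times10^3$ loci,
  20-seed averages for trend checks, 20,000 replicates for absorption-time
  comparisons — were chosen to keep Monte-Carlo error well below the
  effect sizes being asserted.

## 8. Known limitations

The calculus assumes a constant $N_e$ and strict neutrality — selection,
bottlenecks and population growth all shift persistence times and are out
of scope. The $N_e\!:\!N_c$ ratio is a single scalar; uncertainty in it
propagates linearly into every horizon. Divergence times are consumed as
fixed constants, not estimated. The gene-flow model is a symmetric
two-island model; asymmetric or time-varying hybridisation is not
implemented. The sharing analysis is sample-level and inherits
ascertainment bias by design — cross-species sharing *percentages* are
panel-relative quantities, not genome-wide rates.
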