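---
title: "How similarity thresholds bias de novo RAD-Seq inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How similarity thresholds bias de novo RAD-Seq inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo assembly of fixed-length short reads (RAD-Seq, GBS and kin) has no
reference genome to say which reads come from the same place in the genome.
The standard workaround is a percent-similarity threshold: reads within the
threshold are clustered into one locus, reads outside it are kept apart. The
threshold is a blunt instrument. Set it stringently (98–99%) and the two
alleles of a genuinely polymorphic locus can exceed the allowed mismatch
count and be split into two apparent loci ("over-splitting"), silently
deleting the most divergent — most informative — variation. Set it liberally
and reads from paralogous loci can collapse into one ("under-splitting"),
manufacturing variation that is not allelic at all. Because different
species carry different amounts of variation, one threshold biases each
dataset differently, which corrupts exactly the cross-species comparisons
these datasets are collected for.

`radsweep` makes this bias measurable. It simulates two-population RAD-Seq
data with complete knowledge of the truth, assembles the simulated reads
under a sweep of thresholds with a deterministic re-implementation of the
standard clustering workflow, and tracks what happens to allele counts,
genetic distances, Fst, gene-tree depths and demographic parameter
estimates.

## The generative model

Each locus is an independent realisation of a two-population isolation
model. Backwards in time, the `2n` sampled gene copies in each population
coalesce as a Kingman coalescent with pairwise rate `2/theta_i` until the
divergence time `tau`; the survivors then enter a single ancestral
population with rate `2/theta_A`. All times are in mutation units (expected
substitutions per site), so `theta = 4*Ne*mu` per site and `tau` is in
substitutions per site per lineage. Two useful identities follow and are
tested against the simulator: the expected within-population pairwise
diversity is `theta`, and the expected between-population separation is
`2*tau + theta_A` (the `theta_A` term is the expected extra coalescence time
inside the ancestor, exponentially distributed with mean `theta_A/2` and
doubled because two lineages hang from the common ancestor).

Sequences evolve by finite-sites Jukes–Cantor: each branch receives a
Poisson(branch length × L) number of substitutions, each at a uniform site
to a uniform different base. Multiple hits are therefore possible, which is
deliberate — the downstream distances apply the JC correction, and an
infinite-sites simulator would make that correction a systematic
overestimate.

A fraction of loci optionally carry a duplicated copy: the duplicate's root
is the original ancestral sequence mutated by Poisson(`paralog_divergence`
× L) substitutions, and the copy then evolves on its own independent
genealogy. Both copies emit reads for every individual, which is what makes
under-splitting visible as individuals with more than two alleles.

Reads are emitted per haplotype with Poisson(`depth_mean`) counts and
independent per-base errors at `error_rate`. Reads are full-length and
forward-oriented only — RAD loci are anchored at a restriction site, so
strand and offset handling would model nothing real here.

### Defaults and what they emulate

The study design defaults — 2 populations × 4 diploids, 100-bp reads,
~10 reads per allele — mirror a typical single-lane GBS experiment on a
vertebrate lineage. Divergence defaults are artifact choices, not empirical
values: `theta = 0.005` and `tau = 0.005` sit mid-range between the
"shallow" (`theta ~ 0.001`) and "deep" (`tau ~ 0.02`) ends that the
package's experiments span, and `error_rate = 0.005`/base is a conservative
short-read figure. `paralog_fraction` defaults to 0 (duplication is opt-in);
when enabled, `paralog_divergence = 0.04` puts duplicate copies near the
93%-identity boundary, the interesting regime where the threshold decides
whether they merge.

What the generator does *not* emulate: PCR duplicates, allele dropout from
restriction-site polymorphism, indels, quality-score structure, gene flow
after divergence, or more than two populations. Passing tests therefore
demonstrate correctness of the assembly-and-inference chain under a clean
mutational model, not robustness to library-preparation artifacts.

## The assembler

Reads are dereplicated per individual into *stacks* (sets of identical
reads); stacks below `min_depth` (default 10) are discarded outright —
there is no rescue of shallow secondary reads, so sequencing-error reads,
which are almost always singletons, die here. Surviving stacks are
clustered into within-individual loci, and individual loci are merged
across individuals into catalog loci whenever the minimum Hamming distance
between their allele sets is within the budget. The percent threshold `s`
maps onto fixed-length reads as an integer mismatch budget
`M = floor(L*(100 - s)/100)`: at L = 100, 93% allows 7 mismatches and 99%
allows 1.

Two deliberate departures from the workflow this emulates:

* **Clustering is single-linkage** — connected components of the ≤ M
  mismatch graph — rather than depth-ordered greedy seeding. Components are
  order-independent, reproducible to the byte, and checkable against a
  brute-force oracle, which the test suite does exhaustively on random
  instances. The cost is that long mismatch chains can connect sequence
  pairs farther than M apart; at RAD-scale divergences this is rare, and
  the refinement property it buys (the partition at a stringent threshold
  is always a refinement of the partition at a liberal one) is what makes
  the threshold sweep internally comparable.
* **The across-individual budget is the allele-set minimum distance.**
  Whether catalog merging should compare consensus to consensus or allele
  set to allele set is underdetermined in the workflows this mirrors; the
  minimum over allele pairs is the choice here because it makes the
  within- and across-individual stages use the same geometry.

Each individual keeps at most `max_alleles = 3` alleles per locus (ranked
by depth, ties broken lexicographically) — one above diploid ploidy, so a
locus contaminated by a paralog still shows a third allele and can be
flagged. Every tie anywhere (allele ranking, consensus choice, component
ordering) breaks lexicographically; assemblies are byte-reproducible.

## Splitting diagnostics

*Under-splitting* is flagged per catalog locus when any individual carries
more than two distinct alleles. Flagged loci are removed before every
downstream statistic, mirroring standard paralog filtering practice.

*Over-splitting* has no direct observable without a genome, so two measures
are kept side by side:

* the **proxy**, available on real data: map each locus assembled at a
  stringent threshold onto the loci from the most liberal threshold (93%)
  by best ungapped Hamming hit at ≥ 93% identity, and count collisions
  (`sum(max(0, k - 1))` over reference loci hit by `k` queries; a
  `mode = "all"` variant counts all `k` involved loci). The number of 93%
  loci that map to a *different* 93% locus is subtracted as a baseline —
  loci that live within 93% identity of each other collide in the mapping
  whether or not anything was over-split — and the difference is floored
  at zero so a perfect one-to-one mapping scores zero.
* the **truth rates**, available in simulation: the fraction of true loci
  whose depth-surviving reads occupy two or more catalog loci
  (over-splitting), and the fraction of catalog loci containing reads from
  two or more true loci (under-splitting). Paralog copies count as
  distinct true loci. Denominators are the true loci with at least one
  retained read and the catalog loci, respectively.

## Population-genetic statistics

All statistics run on an *allele table* — two allele copies per genotyped
individual per locus (homozygotes contribute their allele twice) — which
both the assembler and the simulator's truth emit, so every estimate can be
computed on assembled data and on ground truth in the same code path.

* **Distances.** Between two individuals at a locus: the mean p-distance
  over the 2 × 2 allele-copy pairs; per pair of individuals, the mean over
  loci genotyped in both. Jukes–Cantor correction
  `d = -(3/4) log(1 - 4p/3)` is applied per locus; saturated loci
  (p ≥ 3/4) are excluded from JC means and counted, not clamped.
* **Hudson Fst.** Per polymorphic locus, `1 - Hw/Hb` with `Hw` the mean
  number of pairwise differences over distinct within-population copy
  pairs (both populations pooled by default; per-population averaging and
  an exclude-identical-pairs variant are flags) and `Hb` the mean over
  between-population pairs. Loci with `Hb = 0` are excluded. The summary
  is the mean of per-locus ratios (a ratio-of-sums option exists). Note
  the small-sample property of this estimator: with identical allele
  compositions in both populations it is slightly negative, not zero.
* **Diversity.** Watterson's `theta_W` from segregating sites with the
  per-locus harmonic correction, and `pi` as mean pairwise p-distance.
* **Ancestral parameters.** The two-population sampling configuration
  supports a closed-form moment estimator: with one allele copy per
  population per locus, the between-population difference count `K`
  satisfies `E[K] = L(2 tau + theta_A)` and
  `Var[K] = L(2 tau + theta_A) + L^2 theta_A^2` (Poisson mutation noise
  plus exponential ancestral coalescence), giving
  `theta_A = sqrt(max(0, var(K) - mean(K)))/L` and
  `tau = max(0, (mean(K)/L - theta_A)/2)`. One copy per population is
  sampled (seeded) precisely so the variance identity stays exact;
  within-locus pairs share a genealogy and would correlate. Negative
  moment solutions are floored at zero and flagged. Contemporary thetas
  are within-population `pi`.
* **Gene-tree depth.** Per locus, distinct alleles → JC distance matrix →
  neighbor-joining (negative branches clamped to zero) → midpoint rooting
  (loci have no outgroup) → depth = longest root-to-tip path. This
  replaces Bayesian tree inference deliberately: for ≤ 16 alleles of
  100 bp, NJ on JC distances is deterministic and fast, and the *relative*
  response of depth to the threshold is the quantity of interest —
  absolute depths from a posterior would differ. Monomorphic loci count
  at depth 0; the sweep averages depths over a seeded subsample of 1,000
  loci per threshold.

## The sweep

`run_sweep()` dereplicates and depth-filters once, then re-clusters at each
threshold, removes flagged loci, and computes every statistic per
threshold, plus the over-split proxy against the 93% reference with its
baseline. One row per threshold; the TSV on disk is the contract, plots
are conveniences. `compare_lineages()` overlays several sweeps (e.g.
parameter sets standing in for species of different diversity) as ratios
to a baseline lineage and across-lineage variances per statistic.

## Numerical and design notes

* All randomness descends from one integer seed; each locus gets a
  deterministic substream, so enlarging `n_loci` extends a dataset without
  reshuffling existing loci. Identical parameters + seed give
  byte-identical FASTQ output.
* Hamming distances at scale are computed by one-hot encoding and BLAS
  `crossprod` in column blocks (memory-bounded), then thresholded; tests
  verify equality with character-by-character counting.
* The over-split proxy's exact arithmetic (what "subtracting the baseline"
  means operationally) is underdetermined in the practice it mirrors; the
  package's definition — best-hit mapping, `k - 1` collisions per
  reference, one dataset-wide 93%-self-map baseline, floored at zero — is
  fixed by three requirements: a one-to-one mapping scores zero, the score
  is non-negative, and the baseline does not depend on the stringent
  threshold under test.
* `min_depth` defaults to 10 throughout. Experiments that isolate
  clustering behaviour (truth-recovery tests) simulate at 40× so that
  allele recovery is not confounded by Poisson depth dropout: at 10×
  mean depth, an allele fails a depth-10 filter roughly half the time,
  which is a property of the filter, not of the clustering under study.
* Problem sizes in the shipped experiments were chosen to make
  Monte-Carlo error small relative to the assertions: 2,000 loci for
  simulator calibration and bias curves, 5,000 single-pair loci for
  moment-estimator recovery, 1,000 loci for the paralog-flag experiment.

## Known limitations

Single-linkage differs from the greedy seeded clustering of the tools it
emulates, so locus counts are not expected to match any specific tool
run; directions of threshold response are the comparable quantity. The
moment estimator assumes no post-divergence gene flow and free
recombination between loci, and its variance-based `theta_A` degrades
gracefully but noticeably when between-population difference counts are
truncated by over-splitting — which is, in fact, the bias the package
exists to demonstrate. The truncation has a hard edge worth knowing: any
threshold assembler only keeps within-locus divergence up to roughly the
mismatch budget, so once `E[K] = L(2 tau + theta_A)` approaches `M` —
e.g. `tau = 0.02` against the 7-mismatch budget of 93% at L = 100 — even
the most liberal assembly clips the upper tail of `K`, `var(K)` falls
below `mean(K)`, and the ancestral-theta estimate floors to zero at
*every* threshold. The threshold-dependence of `theta_A` is therefore
demonstrable only at moderate divergence (`E[K]` well below the liberal
budget); at deeper divergence the informative signal moves into
`tau`-hat, which is mean- rather than variance-based and declines with
stringency as expected. Fst stability across thresholds is reported as a
diagnostic, not asserted, because both its numerator and denominator lose
alleles together and the residual movement is empirically small but not
provably bounded.
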