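# radsweep

**Similarity-threshold sensitivity of de novo RAD-Seq assembly.**

Reduced-representation datasets (RAD-Seq, GBS) are assembled de novo by
clustering fixed-length reads under a percent-similarity threshold. The
threshold is a bias dial: stringent settings split divergent alleles of one
locus into several ("over-splitting", deleting the most informative
variation), liberal settings merge paralogous loci into one
("under-splitting", manufacturing false variation). Because species differ
in diversity, a single threshold biases each dataset differently — which is
fatal for comparative population genetics. `radsweep` is for researchers
who want to *measure* that bias: it simulates two-population RAD-Seq data
with known truth, assembles it across a sweep of thresholds, and tracks
what happens to every downstream statistic.

## What it computes

* **Simulator** — per locus, a two-population isolation-model coalescent
  (mutation-scaled sizes `theta = 4*Ne*mu`, divergence time `tau` in
  substitutions/site), finite-sites Jukes–Cantor mutation, optional
  paralogous locus copies, Poisson read depth and per-base errors. Every
  read carries its source locus, so splitting can be scored against truth.
* **Assembler** — dereplication into stacks, a minimum-depth filter,
  single-linkage clustering under the mismatch budget
  `M = floor(L(100-s)/100)` (93% → 7 mismatches, 99% → 1 at L = 100),
  and an across-individual catalog; deterministic to the byte.
* **Diagnostics** — under-splitting flagged as individuals with >2 alleles;
  over-splitting via best-hit mapping of stringent-threshold loci onto the
  93% catalog (baseline-subtracted), plus truth-based rates in simulation.
* **Statistics** — p / Jukes–Cantor distances between individuals, Hudson
  Fst (`1 - Hw/Hb` over allele-copy pairs), segregating sites, Watterson's
  theta, nucleotide diversity, neighbor-joining gene-tree depths, and a
  closed-form moment estimator of ancestral theta and tau from
  between-population difference counts
  (`E[K] = L(2 tau + thetaA)`, `Var[K] = E[K] + L^2 thetaA^2`).
* **Sweep** — `run_sweep()` ties it together: one report row per
  threshold, plus `compare_lineages()` for cross-parameter-set contrasts.

## Worked example

```r
library(radsweep)

p   <- sim_params(n_loci = 300, tau = 0.01, theta1 = 0.005, theta2 = 0.005,
                  thetaA = 0.005, seed = 42)
sim <- simulate_rad(p)
sim
#> Synthetic RAD-Seq dataset: 300 loci x 100 bp, 8 individuals, 47680 reads
#>   paralogous loci: 0; seed 42

rep <- run_sweep(sim, thresholds = c(93, 95, 97, 99), tree_sample = 300,
                 seed = 1)
rep
#> Similarity-threshold sweep over 4 thresholds
#>  threshold n_loci undersplit_prop oversplit_prop mean_alleles mean_jc_dist
#>         93    300               0             NA        2.130     0.012271
#>         95    303               0       0.009901        2.109     0.012085
#>         97    332               0       0.096386        1.925     0.010490
#>         99    480               0       0.375000        1.331     0.004782
#>  mean_fst mean_tree_depth thetaA      tau
#>    0.8885        0.010683      0 0.010429
#>    0.8871        0.010267      0 0.010264
#>    0.8753        0.007530      0 0.008559
#>    0.8388        0.001749      0 0.004000
```

Reading the table: the 300 simulated loci are recovered exactly at the
liberal 93% threshold, but at 99% the same reads shatter into 480 loci —
37.5% of them flagged as putative over-splits by the mapping proxy — and
every diversity-sensitive statistic deflates with stringency: mean alleles
per locus (2.13 → 1.33), mean Jukes–Cantor distance between individuals
(0.0123 → 0.0048, versus a true between-population separation of
`2*tau + thetaA = 0.025` diluted by within-population pairs), mean
gene-tree depth (0.0107 → 0.0017), and the divergence-time signal
(`tau`-hat 0.0104 → 0.0040). Fst moves far less (0.89 → 0.84) because
allele loss hits its numerator and denominator together. Under-splitting
stays at zero — no paralogs were simulated. The ancestral-theta column
shows the estimator's variance signal floored at zero: at 300 loci the
sampling noise of `var(K)` exceeds the `L^2 thetaA^2` excess (the fit
prints a note when this happens); thousands of loci are needed for a
stable ancestral theta, as in the full-scale runs below.

## Caveats worth knowing

Clustering is single-linkage over the mismatch graph, not the seeded
greedy matching of the tools it emulates — deterministic and
oracle-checkable, but locus counts will not match any specific external
tool run. Gene trees are neighbor-joining on JC distances, so absolute
depths are not comparable to Bayesian posteriors; threshold *response* is
the comparable quantity. See `vignettes/threshold-bias.Rmd` for the full
model, parameter meanings, and known limitations.
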