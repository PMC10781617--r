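# paleoturnover

Multiproxy inference of prehistoric population turnovers from ancient-DNA
cohorts.

## The problem

Ancient-genomics transect studies ask *when* one ancestry replaced another in
a region, and what else changed with it.  Answering that requires chaining
several independent lines of evidence for the same skeletons:

- **Who is related to whom?**  Pairwise identity-by-descent (IBD) sharing —
  total centimorgans of genome two individuals co-inherit — defines a
  weighted network whose communities are genetic clusters, and whose
  covariance structure yields a PCA of relatedness.
- **What are they a mixture of?**  A target's *relative IBD-sharing rate
  vector* over reference clusters is decomposed as a non-negative mixture of
  source profiles (NNLS); the weights are read as ancestry proportions.
  ABBA-BABA D-statistics with a block jackknife test treeness between
  cluster-defined populations, and a least-squares projection places
  low-coverage samples into a reference PCA.
- **When did each ancestry arrive?**  Radiocarbon dates are calibrated
  against a curve, marine-diet individuals are reservoir-corrected from
  their collagen δ¹³C/δ¹⁵N (flagged when δ¹³C ≥ −18.0‰ *and* δ¹⁵N ≥
  +12.0‰), and a Bayesian two-phase model with trapezoidal phase priors
  yields the posterior of the inter-onset duration Δ between the two
  arrivals.
- **What did they eat, look like, and where did they grow up?**  Marine diet
  fraction and trophic level from collagen isotopes (collagen QC via atomic
  C:N in [2.9, 3.6]), HIrisPlex-style multinomial-logistic pigmentation
  probabilities and a height polygenic score from imputed dosages, and
  ⁸⁷Sr/⁸⁶Sr mobility outliers by a robust MAD rule.

The package implements all of these stages plus a seeded synthetic-cohort
generator that emulates the statistical structure of such a dataset (three
temporally ordered ancestry strata with abrupt turnovers, cluster-structured
IBD sharing, period-dependent isotope distributions, radiocarbon noise), so
the whole pipeline is testable end to end without restricted accession data.

## Core statistics

With `p_k` the non-missing alternate-allele frequency of population `k` at a
site, the D-statistic is

    D = sum_s (p2 - p1)(p3 - p4) / sum_s (p1 + p2 - 2 p1 p2)(p3 + p4 - 2 p3 p4)

(equal to `(ABBA − BABA)/(ABBA + BABA)` for fixed haploid frequencies), with
Z from a leave-one-block-out jackknife.  The NNLS mixture solves
`min ||Σ_k w_k s_k − y||²` with `w ≥ 0` over sum-normalized sharing vectors,
then renormalizes `Σ w = 1`.  The trapezoidal phase prior on an event date
`t` (cal BP, `a ≥ b ≥ c ≥ d`) rises linearly `a → b`, is flat `b → c` and
falls `c → d`; phase onset is the ramp midpoint `(a+b)/2`, and
`Δ = onset(farmer) − onset(steppe)`.

## Worked example

```r
library(paleoturnover)
coh <- generate_cohort(synthetic_scenario(n_individuals = 30,
                                          n_sites = 1000, seed = 42))
res <- run_pipeline(coh, list(seed = 42))
print(res)
```

```
pipeline result: 30 individuals, 3 level-1 clusters
first appearances:
  ancestry first_id date    weight   tie
1   farmer   SYN012 5930 1.0000000 FALSE
2       hg   SYN002 7315 0.9436939 FALSE
3   steppe   SYN023 4820 0.9861694 FALSE
```

The synthetic scenario plants turnovers at 5,900 and 4,850 cal BP; the
detected first appearance of farmer ancestry (SYN012, calibrated median
5,930 cal BP, NNLS weight 1.0) and of steppe ancestry (SYN023, 4,820 cal BP)
recover those boundaries to within radiocarbon noise.  The head of the
chronologically sorted multiproxy table:

```
      id date_mid cluster  w_hg w_farmer w_steppe     marine_class reservoir_flag
1 SYN002     7315       1 0.944  0.00358   0.0527 marine-dominated          FALSE
2 SYN007     7285       1 0.976  0.00000   0.0242 marine-dominated          FALSE
3 SYN009     6795       1 0.954  0.04626   0.0000 marine-dominated           TRUE
4 SYN003     6770       1 0.883  0.08108   0.0362 marine-dominated           TRUE
5 SYN001     6735       1 1.000  0.00000   0.0000            mixed           TRUE
```

Early (hunter-gatherer stratum) individuals cluster together, carry ~1 NNLS
weight on the hunter-gatherer source, and show the marine-shifted collagen
values that trigger the reservoir flag — the structure the real multiproxy
transect exhibits.

## Command line

```sh
Rscript inst/scripts/paleoturnover simulate --out cohort_dir --seed 7
Rscript inst/scripts/paleoturnover run --cohort cohort_dir --out results --seed 7
Rscript inst/scripts/paleoturnover phase-model --dates dates.csv --curve curve.14c --seed 1 --iters 6000
```

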