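---
title: "Models and methods behind paleoturnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoturnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoturnover)
```

This vignette is the package's own account of its science: what each model
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. Quality control

Sample-level QC (`qc_samples()`) excludes samples with coverage < 0.1×,
mean genotype probability < 0.98, or contamination > 5%, then resolves
first/second-degree kin pairs by removing the lower-coverage member,
iterating until no pair remains. All thresholds are strict inequalities, so
boundary values are retained. Coverage ties are broken by removing the
lexicographically larger id — an arbitrary but deterministic rule, logged in
the exclusion reason. The operation is idempotent and does not mutate its
input.

Site-level QC (`filter_sites()`) retains sites with minor allele frequency
> 1% and imputation info score > 0.5 (again strict), and can restrict to
transversion SNPs, which are immune to post-mortem C→T deamination and are
the conventional substrate for ancient-DNA D-statistics.

## 2. IBD sharing, clustering and PCA

`sharing_matrix()` sums segment lengths per unordered pair, ignoring
segments below `min_segment_cM` (default 1 cM: shorter segments are
dominated by detection noise), and normalizes by the analyzable map length
to a dimensionless rate. The raw rate is the one canonical matrix; any
further normalization ("relative" rates for mixture modelling) happens at
the point of use. The edge weight of the similarity network is the rate;
using total cM instead would only rescale every edge by a constant and leave
the partition unchanged, which is why we do not expose it as an option.

`detect_communities()` is a deterministic greedy modularity agglomeration on
the weighted network: merge the community pair with the largest modularity
gain, stop when the best gain falls below `gain_tol`, recurse within
communities of at least `min_size` members. A deterministic algorithm with a
lexicographic tie-break was chosen over stochastic Louvain-style methods so
that partitions are exactly reproducible under permutation of the input —
a property the tests assert. On planted-block inputs it agrees with
igraph's fast-greedy reference implementation (tested), and disconnected
blocks separate exactly.

`ibd_pca()` eigendecomposes the covariance of the rows of the rate matrix.
The structural zero diagonal (no self-sharing) would otherwise inject a
spurious "self" axis, so it is replaced by each row's off-diagonal mean
before computing covariances; this choice is recorded in the result object.
Coordinates are eigenvectors scaled by the square root of their eigenvalue,
with each component's sign fixed so its largest-magnitude loading is
positive.

## 3. Supervised ancestry mixtures

`nnls_mixture()` expresses a target's sharing profile over reference
clusters as a non-negative combination of source profiles. All vectors are
first normalized to sum to one — this is what makes the rates "relative"
and removes overall sharing intensity (a function of coverage and
relatedness depth) from the problem, leaving only profile shape. The
Lawson–Hanson active-set solver is implemented in-package (no NNLS solver
ships with the pre-installed stack) and is verified against a simplex
grid-search oracle. Weights are renormalized to sum to one; the residual
norm and the source condition number are reported, with a warning when
sources are nearly collinear. The feature space (`sharing_features()`) is
the mean sharing rate with each reference cluster's members, excluding self;
cluster-mean source vectors are the default, per-individual references can
be passed directly.

## 4. D-statistics

`d_statistic()` uses the frequency estimator

$$D = \frac{\sum_s (p_2 - p_1)(p_3 - p_4)}{\sum_s (p_1 + p_2 - 2p_1p_2)(p_3 + p_4 - 2p_3p_4)}$$

so diploid and pseudo-haploid inputs share one code path; for fixed haploid
frequencies it reduces to the classic pattern-count form
$(\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+\mathrm{BABA})$, which the
tests verify by enumeration. The sign convention ($D>0$ = excess ABBA =
excess P2–P3 sharing) follows the pattern-count definition. The Z score
comes from a leave-one-block-out jackknife over contiguous physical blocks
(default 5 Mb, the conventional scale for human LD); with `weighted = TRUE`
the Busing delete-$m_j$ variant accounts for unequal block sizes. Null
calibration (|Z| ≥ 3 in < 5% of symmetric replicates, empirical SD of Z in
[0.8, 1.25]) is asserted in the acceptance suite.

## 5. Least-squares projection and admixture dating

`lsq_project()` solves the least-squares placement of a possibly incomplete,
frequency-normalized dosage vector on reference PCA loadings restricted to
the sample's non-missing sites — the standard treatment for low-coverage
ancient samples ("lsqproject"). A complete reference sample recovers its
coordinates exactly; the masking experiment in the tests shows the error
shrinking monotonically as missingness drops.

`admixture_date()` is a deliberately simplified admixture-LD dating method:
the covariance of allele pairs across admixed haplotypes, weighted by source
allele-frequency differences, decays as $e^{-\lambda d}$ with genetic
distance $d$; $\lambda$ is the admixture age in generations. We bin pairs,
fit $A_0 e^{-\lambda d} + c$ by nonlinear least squares (grid-profiled
fallback), and flag "no date" when the decay is absent, inverted, or the
amplitude is indistinguishable from the bin noise floor. This is an
approximation to full admixture-LD machinery (no rotation tricks, no
affine-correction against reference panels); its acceptance surface is
parameter recovery on simulated tract data (±20% at 20 generations).
Generation time defaults to 29 years and is configurable; it multiplies
generations into years and nothing else.

## 6. Radiocarbon chronology

`calibrate()` evaluates $p(t) \propto N(\text{age};\ \mu(t),\ \sigma^2 +
\sigma_{\mathrm{curve}}(t)^2)$ on a cal BP grid and normalizes. Highest
posterior density regions are built by descending-density accumulation, so
they may be disjoint on wiggly curves (verified against a hand-constructed
two-crossing curve with closed-form crossing points). The reported HPD mass
overshoots the requested mass by at most one grid cell; the default 1-yr
grid keeps that overshoot near 1% for typical AMS errors.

`reservoir_correct()` flags a date when both collagen isotopes are elevated
(δ¹³C ≥ −18.00‰ AND δ¹⁵N ≥ +12.00‰). The conjunction is a design choice the
underlying threshold rule leaves open; we require both because marine
protein raises carbon and trophic nitrogen together, and an OR rule would
flag high-trophic freshwater diets for a *marine* correction. The reservoir
age is the marine diet fraction — linear two-endmember mixing of δ¹³C
between a terrestrial endmember (−21‰) and a marine endmember (−12.5‰),
clipped to [0, 1] — times a full-marine offset of 400 ± 50 ¹⁴C yr; offset
uncertainty scales with the fraction and combines in quadrature. The
endmembers and offset are conventional values, configurable, and not claims
about any particular study. `combine_dates()` is the standard
inverse-variance combination with the χ² consistency test at the 5% level.

`fit_phase_model()` is the centerpiece: each ancestry class has a
trapezoidal prior on its event dates — parameters $(a, b, c, d)$ in cal BP
with $a \ge b \ge c \ge d$, rising $a \to b$, flat $b \to c$, falling
$c \to d$, normalized height $2/((a-d)+(b-c))$ — and each event's
likelihood is its calibrated, reservoir-corrected density, so calibration
and phase structure inform each other. Sampling is Metropolis-within-Gibbs:
event dates update in a vectorized elementwise step (they are conditionally
independent given the trapezoid), trapezoid parameters update
componentwise under the ordering and window constraints. Proposal scales
adapt toward 20–40% acceptance during burn-in and are frozen afterwards, so
post-burn-in draws are from a fixed kernel; chains are seeded and
reproducible. Convergence is monitored by split-R̂ (flagged above 1.1).

The phase *onset* is defined as the ramp midpoint $(a+b)/2$. The convention
is genuinely open ("first appearance" could map to $a$, to $b$, or to the
first event posterior); we chose the midpoint as the least extreme reading
and return the $a$ and $b$ draws so either alternative can be read off
without refitting. The inter-onset duration is
$\Delta = \text{onset(farmer)} - \text{onset(steppe)}$, positive when the
farmer onset is older; 95% central and shortest (HPD) intervals are
reported.

## 7. Phenotype and isotope proxies

Pigmentation prediction is multinomial-logistic with a reference category
receiving the residual mass; variants with missing dosage are dropped and
the prediction flagged low-confidence, which keeps the probabilities valid
(they always sum to one). The bundled panel fixture is **synthetic** — it
has the structure of an 18-variant eye/hair panel but none of the published
coefficients, which are not printed in the main text of any source we ship;
real panels drop in through the same TSV + JSON format.

The polygenic score is $\sum \beta \cdot \text{dosage}$ over non-missing
loci, rescaled by panel size over non-missing count (so missingness does not
deflate the score), requiring ≥ 50% coverage; standardization is against a
user-supplied reference population, and the cm-per-SD conversion defaults
to 1 (SD units) because no mapping to centimetres is assumed.

Collagen C:N bounds [2.9, 3.6] are closed (a stated "range" is read
inclusively). Diet classes cut the marine fraction at 0.2 and 0.5. Sr
outliers use the scaled MAD (consistency constant 1.4826, k = 3) relative
to the assemblage itself — deliberately no geological baseline — with an
IQR fallback when the MAD degenerates to zero.

## 8. The synthetic cohort: what it is and is not

`generate_cohort()` draws, per individual: a stratum (equal thirds across
strata, remainder to the oldest — the simplest allocation that guarantees
every stratum is represented), a true date uniform within the stratum's
occupancy interval (matching the uniform-within-phase likelihood the
chronology module assumes), genotypes binomial from Balding–Nichols stratum
frequencies (drift F = 0.1 by default, giving Hudson FST ≈ F, which the
tests verify against a brute-force oracle), IBD segments as Poisson counts
with exponential lengths at the stratum-pair rate, isotopes from stratum
normals (Mesolithic stratum marine-shifted at δ¹³C −15‰/δ¹⁵N 13.5‰;
Neolithic terrestrial at −20‰/10‰), and a ¹⁴C age from pushing the true
date through the curve, adding the marine-fraction × 400 yr reservoir
offset, plus Gaussian noise (σ = 30 yr, typical AMS precision). Four RNG
streams (genotype/IBD/isotope/¹⁴C) derive from the master seed so
perturbing one domain leaves the others byte-identical. Default turnovers
sit at 5,900 and 4,850 cal BP, the first appearances of farmer- and
steppe-related ancestry in the southern Scandinavian record.

What it does **not** emulate: coalescent or recombination realism (IBD
segments are independent of the genotypes), sequence reads, post-mortem
damage, or spatial structure. A green end-to-end test therefore
establishes that the pipeline's statistical machinery recovers planted
structure of the assumed form — not that it is robust to every failure mode
of real ancient data. The IBD rate/stratum link is a free parameter of the
scenario, not an empirical claim.

## 9. Numerical choices and degenerate inputs

- NNLS tolerance 1e-10 on the dual; rank-deficient passive sets fall back to
  zero coefficients.
- Calibration grids are uniform; HPD masses overshoot by at most one cell.
- All-zero sharing matrices yield a single community with a warning rather
  than an error; all-zero mixture targets are an error ("no sharing
  signal").
- Coverage ties in kin resolution, modularity-gain ties, and date ties in
  turnover detection all break lexicographically and are flagged.
- The phase model requires at least 3 dates per class and a prior window
  covering every density; degenerate trapezoid ramps (a = b) are handled as
  instantaneous boundaries.

## 10. Known limitations

- The admixture-LD dating is a single-panel simplification; cross-panel
  affine corrections are out of scope.
- The D-statistic block jackknife assumes blocks ≫ LD range; with few
  blocks the Z is conservative at best (fewer than 3 blocks errors out).
- The two-phase model treats the calibrated densities as fixed likelihood
  surfaces (no joint recalibration of curve error), matching desk-scale
  practice but not a full hierarchical treatment.
- EIGENSTRAT round trips cannot carry info scores (the format has no such
  column); the VCF route carries them via INFO tags.
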