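---
title: "Inferring mutation-burst and stem-cell division parameters from single-gland data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mutation-burst and stem-cell division parameters from single-gland data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandabc)
```

## The scientific problem

Colorectal tumors are built from glands (crypts) of roughly 10,000
cells, each a nearly pure cell population.  Mutations that arise before
the first gland forms end up in every cell of the glands that inherit
them ("fixed" mutations, diploid allele frequency exactly 0.5), while
later mutations segregate at lower frequencies.  The balance between
fixed and non-fixed mutations across several sequenced glands therefore
carries information about two things that cannot be observed directly:

* whether the point-mutation rate was elevated during the first few
  divisions (an early *mutation burst*): the rate before first-gland
  formation ($\alpha$) versus after it ($\beta$), both in expected
  mutations per daughter cell per division at exome scale;
* how cancer stem cells (CSCs) divide: the probability $r$ of
  asymmetric division (one CSC daughter, one differentiating daughter)
  versus symmetric division (two CSCs or two non-CSCs, with equal
  probability), which controls how long new mutations persist.

`glandabc` implements a generative simulator for this process and a
rejection Approximate Bayesian Computation (ABC) layer that estimates
$\alpha$, $\beta$ and $r$ from per-gland variant tables.

## The growth model

A tumor is simulated in three phases:

1. **First-gland formation.**  A single transformed cell divides
   repeatedly (balanced binary expansion) until the gland holds
   `n_csc` CSCs (default 32).  Every daughter cell receives an
   independent Poisson($\alpha$) number of new mutations under an
   infinite-sites assumption.
2. **Exponential gland fission.**  Glands double in number each
   generation for `n_fission_gens` generations (default 19, giving
   $2^{19} \approx 5\times10^5$ glands, about $4\times10^9$ cells at
   10,000 cells per gland).  The two daughters of the very first
   fission seed the tumor halves A and B.  At each fission, each
   daughter gland is founded by one CSC drawn without replacement from
   the parent pool and regrown clonally to `n_csc` cells, each regrowth
   division adding Poisson($\beta$) mutations per daughter cell
   (*bottleneck* mode).
3. **Constant-size phase.**  For `t3` generations (default 100) each
   gland is maintained by CSC division: asymmetric with probability
   $r$; two CSC daughters with probability $(1-r)/2$; two
   differentiating daughters with probability $(1-r)/2$.  Offspring
   mean is exactly 1, so gland size is maintained in expectation.

Allele frequencies are computed over the CSC pool
(`carriers / pool size / 2`), treating the differentiated compartment
as mirroring CSC composition because differentiated cells are
short-lived.  The nominal 10,000 cells per gland is reporting metadata
only.

### Design choices the model text leaves open

* **CSC apportionment at fission** is not fixed by the biology above.
  The default bottleneck mode (single founder per daughter, regrown to
  `n_csc`) is chosen because it reproduces the observed property that
  every pre-gland mutation detected in a sampled gland sits at exactly
  0.5: any mutation carried by a gland founder is fixed in that gland
  and in all its descendants until lost by a later founder draw.  A
  `"split"` mode (every CSC divides once, the $2 n_{csc}$ daughters are
  partitioned at random) is available for sensitivity analysis; under
  it pre-gland mutations segregate within glands.
* **Constant-size tension.**  The stated division probabilities make
  the CSC count a critical branching process (offspring variance
  $1-r$), which can drift and go extinct.  Sampled glands are
  conditioned on survival: a gland whose pool dies during the constant
  phase has that phase resimulated from its start, and the number of
  restarts is recorded on the returned sample.
* **Rate switch.**  Mutations arising during first-gland expansion use
  $\alpha$ up to the moment the gland reaches `n_csc` cells and $\beta$
  thereafter (including fission regrowth).
* **Pruning.**  Only lineages ancestral to sampled glands are
  simulated.  Glands evolve independently after a fission, so pruning
  unsampled branches does not change the joint distribution of the
  sampled glands; a test compares pruned against exhaustive simulation
  on a small tree.
* **Non-CSC daughters** never contribute offspring, so their Poisson
  mutation draws are not generated; this is distributionally
  equivalent and saves half the draws.

## Sequencing model

`seq_model("perfect")` observes true frequencies (a record is fixed iff
its frequency is exactly 0.5); `seq_model("reads", m, v)` draws a
per-locus depth $k$ from a negative binomial parameterised by its mean
$m$ and variance $v$ via $p = 1 - m/v$, $t = mv/(v-m) - m$ (the
default $v = 1.1m$ is mildly overdispersed), then
$n_a \sim \mathrm{Binomial}(k, q)$ alternative reads at true frequency
$q$.  A record is called fixed when a two-sided *exact* binomial test
of $H_0\!: q = 0.5$ fails to reject at `test_level` (default 0.05; the
level is a package choice, exposed as a parameter).  Loci with
$n_a = 0$ are undetectable and dropped; the minimum-detectable-
frequency filter `f_min` is applied to the observed frequency
$n_a / k$ in reads mode and to the true frequency in perfect mode, and
filtering precedes the fixation test.  Frequencies near 0.5 are often
called fixed (type II errors); the identical calling procedure is
applied to reference-table simulations and to observed data, so this
costs precision but not bias.

## Summary statistics

Nine statistics summarise a multi-gland sample: the mean (s1) and
variance (s2) of allele frequencies over all records of non-fixed
mutations; counts of distinct gland-specific/shared ×
non-fixed/fixed mutations (s3–s6); variances across glands of the
per-gland counts of non-fixed (s7) and fixed (s8) mutations; and the
between-half variance of non-fixed allele frequencies (s9).  Choices
made where the definitions admit several readings:

* a mutation's sample-level status is *fixed* only if it is called
  fixed in every gland where it is present — any segregating
  observation contradicts fixation;
* s1/s2 pool per-(gland, mutation) records rather than collapsing to
  one value per mutation, preserving between-gland heterogeneity;
* s9 is the sample variance (denominator 1) of the two half-level
  means of non-fixed records; pooled-within-half and
  variance-component readings exist, and whichever is used must be
  identical between reference table and observed data — the package
  has a single implementation to make that automatic;
* empty categories give mean/variance 0, and the variance of a single
  value is 0.

A structural consequence of bottleneck fission worth knowing: with
perfect data, any mutation present in two glands must have been
carried by both fission founders at the glands' divergence, hence is
fixed in both — so shared non-fixed mutations (s5) are exactly 0 in
perfect-data bottleneck simulations.  s5 becomes informative under
read noise (discordant test calls) and under split-mode fission.

## ABC layer

Priors are independent uniforms, $\alpha \sim U(0,5)$,
$\beta \sim U(0,1)$, $r \sim U(0.5,1)$, covering reported tumor
mutation rates with room to spare.  A reference table of $N$ prior
draws is paired with simulated summary vectors, and rejection keeps
the `accept_fraction` smallest weighted distances

$$ d(S', S) = \sqrt{\sum_m \left( w_m \frac{s'_m - s_m}{c_m} \right)^2 } $$

where $c_m$ is a robust per-statistic scale (reference-table MAD,
falling back to the SD and then to 1).  Standardisation is needed
because count-valued statistics (hundreds) and frequency-valued
statistics (≤ 0.5) otherwise contribute on wildly different scales;
the $R^2$-based weights are scale-free, so without it the distance
would be count-dominated.  Three weighting schemes:

* **equal** — $w_m = 1/M$;
* **global** — $w_m \propto R^2$ of the simple regression of the
  target parameter on statistic $m$ over the whole table;
* **local** — as global, but each statistic's regression uses only the
  $\lceil \eta N \rceil$ rows whose value of that statistic is nearest
  the observed value (1-D absolute distance, ties broken by row
  index); $\eta = 0.1$ by default, and $\eta = 1$ recovers the global
  weights exactly.

Weights are normalised to sum to one *across statistics for each
parameter*; the alternative reading (normalising across parameters for
a fixed statistic) does not yield a usable per-parameter weighting for
the distance above.  An all-zero $R^2$ row falls back to equal
weights.  The acceptance threshold $\varepsilon$ is specified as a
quantile of the realised distances (default: accept the smallest 1–2%)
rather than an absolute number.  Posterior draws are summarised by
mean, SD, and a mode taken as the argmax of a Gaussian KDE (Silverman
bandwidth, 512-point grid over the prior support).

## What the simulation studies show — and what they do not

`recovery_study()` simulates test tumors with known parameters drawn
from the priors and tabulates posterior mean/SD against the truth
under different observation conditions (detection thresholds 0.001 vs
0.05; 1 vs 6 glands per half; read depths 20 vs 80 with $v = 1.1m$).
All conditions share one pool of simulated tumors — conditions differ
only in the observation layer, so this is statistically valid and
keeps the study tractable.  The package's desk-scale defaults are a
5,000-row reference table, 50 test tumors, 6 glands per half, and
acceptance fraction 0.02; these sizes were chosen once as the smallest
at which rank correlations and paired contrasts are stable, and the
test suite states all comparisons as paired per-tumor contrasts with
3-standard-error Monte-Carlo bands.

The generator emulates: gland-structured growth, Poisson mutation
accumulation, drift through fission bottlenecks and CSC division,
depth-dependent detection and miscalled fixation status.  It does not
emulate: spatial structure, selection, copy-number evolution,
sequencing error or mapping artifacts, or cell-cycle asynchrony.
Passing recovery tests therefore show that the inference machinery
recovers parameters *of this generative model* from data shaped like
single-gland variant tables — not that real tumors satisfy the model's
assumptions.

Identifiability is uneven across parameters.  $\beta$ and $r$ act on
thousands of segregating records and are estimated tightly.  The
$\alpha$ signal is carried almost entirely by shared fixed-mutation
counts (≈ $10\alpha$ mutations survive the founder draws per tumor,
against a $\beta$-driven background of comparable size: each fission
bottleneck fixes ≈ $5\beta$ new mutations along a sampled lineage), so
$\alpha$ posteriors are markedly wider at any study scale.

Two further limitations follow from the CSC-pool frequency convention.
First, allele frequencies are quantised to multiples of $1/(2\,n_{csc})$
(1/64 by default), so a detection threshold of 0.001 removes nothing
and a threshold of 0.05 only removes records with three or fewer
carrier CSCs; the information loss a fine-grained (per-cell) frequency
scale would suffer at a 5% threshold cannot materialise here, and the
thresholded count statistics can even end up slightly less noisy.
Second, paired per-tumor contrasts across observation conditions are
extremely sensitive (standard errors of a few thousandths on posterior
sds), so small real effects — such as the slight dependence of
fixation-call error on sequencing depth — are statistically detectable
even where they are practically negligible.  The test suite states
both facts as measured outcomes rather than hiding them.

## Real data

`read_mutect_callstats()` ingests MuTect call-stats files by column
name (KEEP records only).  Copy-number context enters through a
user-supplied integer segment table: a mutation carried on one copy in
every cell of a copy-number-$c$ region has expected allele frequency
$1/c$, so the fixation test becomes an exact binomial test of
$q = 1/c$ (the 0.33-at-copy-number-3 case is the canonical example),
and frequencies are rescaled to diploid equivalents
($\min(0.5,\, \hat q\, c/2)$) so that real records and simulated
records live on the same scale.  Multi-copy mutant configurations
($q = j/c$, $j \ge 2$) are testable behind an option, off by default.
Records outside all segments fall back to diploid with a warning.
With one gland per half — the realistic minimal design — s9 degrades
to the variance of two single-gland means; inference still runs, with
wider posteriors.

## Numerical conventions

* Mutation ids are sequential integers; the phase of origin
  (pre-gland / fission / constant) is stored run-length encoded.
* All simulation randomness flows through R's RNG: a master seed plus
  deterministic per-tumor substreams makes every table and study
  reproducible bit-for-bit.
* The exact binomial p-value at $q_0 = 0.5$ uses the two-equal-tails
  form (identical to the minimum-likelihood convention for a symmetric
  null, and asserted against `binom.test` in the tests); general
  $q_0 = 1/c$ nulls call `binom.test` directly.
* Degenerate inputs: extinction is a reported outcome (resimulated for
  sampled glands, never an exception); a zero-variance statistic gets
  $R^2 = 0$; an empty acceptance set is a parameter error.

## Worked example

```{r example, eval = FALSE}
p <- growth_params(alpha = 2, beta = 0.1, r = 0.8)
sim <- simulate_tumor(p, glands_per_half = 6, seed = 1)
obs <- sequence_sample(sim, seq_model("reads", m = 20), seed = 2)
summarize_sample(obs)

tab <- build_reference_table(prior_spec(), n = 2000, glands_per_half = 6,
                             model = seq_model("reads", m = 20), seed = 3)
w <- global_regression_weights(tab, "alpha")
post <- abc_reject(tab, summarize_sample(obs), w, accept_fraction = 0.02)
posterior_summary(post, "alpha")
```
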