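---
title: "Comparing synonymous gene variants: codon usage, mRNA structure, and translation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing synonymous gene variants: codon usage, mRNA structure, and translation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonkinetics)
```

## The problem

Codon optimization rewrites a coding sequence with synonymous codons to
raise expression. The protein is unchanged on paper, but the mRNA is not:
codon-usage indices rise, GC content rises, secondary structure strengthens,
and — critically — the local speed of translation can change. Ribosome
profiling reads that speed out at single-codon resolution: the number of
ribosome-protected fragments (RPFs) whose A-site sits on a codon is a proxy
for how long ribosomes dwell there. If a recoded variant is translated with
different regional kinetics than its wild-type source, co-translational
folding can differ too, which matters for any recombinant or gene-therapy
product.

This package implements the full comparative analysis for one wild-type /
optimized pair (coagulation factor IX being the motivating case), in five
layers:

1. **seqfeat** — codon-usage statistics (RSCU, RSCPU, CAI), composition,
   divergence, and per-codon feature tracks;
2. **rnastruct** — minimum-free-energy structures and equilibrium
   base-pairing probabilities, with per-codon structure tracks;
3. **ribocov** — per-codon A-site coverage, QC, RPKM and translation
   efficiency from aligned fragments;
4. **kinstats** — Box-Cox transformation, a lagged stepwise-AIC regression
   explaining occupancy, and a cumulative-sum / Kolmogorov–Smirnov procedure
   for regional divergence;
5. **synth** — a generator of usage-biased gene pairs and autocorrelated
   coverage profiles with known ground truth, so that every other layer is
   testable without access to raw sequencing data.

## Sequence statistics

For codon $c$ in a synonymous family $F$, relative synonymous codon usage is
$\mathrm{RSCU}(c) = x_c / \bar x_F$, the observed count over the family
mean; the codon-pair analogue (RSCPU) normalizes an ordered pair's count by
the mean over all synonymous pairs encoding the same amino-acid pair. The
codon adaptation index is the geometric mean of relative adaptiveness
$w(c) = x_c / \max_{c' \in F} x_{c'}$ over a gene's codons. Following the
original definition, ATG, TGG and stops are excluded (they carry no choice),
and zero-count codons receive $w = 0.5/\max_F x$ rather than 0 so one rare
codon cannot annihilate the product. All indices are derived from a
user-supplied usage table (TSV: `codon`, `count`); which snapshot of usage
statistics you supply materially affects CAI at the second decimal, so the
table is always an explicit input rather than a built-in constant.

Divergence between two variants is computed position-by-position on the
colinear sequences (synonymous recoding preserves length, so no alignment is
performed), as percent mismatched nucleotides and percent mismatched codons,
together with a check that both translate to the same protein.

Feature tracks are long-format tibbles (`gene_id`, `codon_index`, `feature`,
`value`) with `NA` marking positions where a feature is undefined — for
pair-keyed features the last codon, for usage-derived features any codon
whose family has no counts. The 7-codon centered sliding mean used for
plotting masks `floor(w/2)` positions at each end: only full windows are
averaged.

## The folding engines

Published structure numbers for genes of this size come from thermodynamic
folders (NUPACK, RNAfold). Those parameter sets are not something a
reusable analysis should silently re-implement, so the package has two
engines behind one interface:

* the **external** engine shells out to any folder implementing the RNAfold
  command-line contract and returns free energies in kcal/mol and ensemble
  pairing probabilities;
* the **built-in** engine is a self-contained pseudoknot-free model: score
  $-1$ per canonical pair (AU, UA, GC, CG, GU, UG), an additional $-1$ per
  stacked pair, hairpin loops of at least 3 nt. Its minimum-energy structure
  comes from exact dynamic programming, and its pairing probabilities from
  the exact partition function of the same ensemble at a fixed dimensionless
  inverse temperature $\beta = 1$, computed by an unambiguous inside–outside
  recursion with per-nucleotide rescaling (the rescaling exponent is set
  from the MFE and refined automatically, so kilobase sequences neither
  overflow nor underflow).

The built-in model is deliberately small enough that brute force can check
it: the test suite enumerates *every* structure of *every* sequence up to
length 6 (and seeded random sequences to length 12) and verifies that the
dynamic programs reproduce the enumerated optimum exactly and the Boltzmann
pairing frequencies to $10^{-9}$. Its energies are scores, not kcal/mol;
whenever the physical scale matters, use the external engine. One
consequence worth knowing: the model is exactly symmetric under sequence
reversal (the pair rule is orientation-free), but *not* under
reverse-complementation once GU wobble pairs are available, so only the
former is asserted as an invariant.

Per-codon structure tracks follow the conventions of the motivating
analysis: `MFE_151` folds the 151-nt window centered on each codon's middle
nucleotide ("150 nt centered" is not realizable symmetrically; 151 = ±75 nt
resolves it, truncating at the sequence ends), and `pair_prob` averages the
three nucleotide pairing probabilities of each codon. Two variants'
pairing-probability vectors are compared positionwise with the Wilcoxon
signed-rank test (zero differences dropped; exact null up to 25 informative
positions, normal approximation with continuity and tie correction beyond).
Whether to compare per nucleotide or per codon is configurable; per
nucleotide is the default since the variants are colinear.

## From fragments to per-codon occupancy

Input fragments live in transcript coordinates (TSV: `transcript_id`,
`start` 0-based, `length`, `sample`; a SAM reader is provided), keeping the
module downstream of any aligner. Defaults implement the standard filters:
RPFs of 20–22 and 27–29 nt are kept, total-mRNA fragments below 25 nt are
discarded, and the decoded codon sits 15 nt downstream of a footprint's 5′
end (one offset for all kept lengths; a per-length table can be supplied).
Coverage is the count of A-sites per CDS codon; normalized coverage divides
by the replicate's mean over the CDS so a profile has mean exactly 1;
replicates are averaged positionwise. Translation efficiency is
RPF RPKM / mRNA RPKM per gene. QC mirrors the usual plots: fragment-length
histogram, A-site region fractions (5′UTR/CDS/3′UTR), reading-frame
fractions, and pairwise Pearson correlations of log10 RPKM over genes with
RPKM ≥ 10 in both replicates (the log scale is chosen as standard for RPKM
reproducibility; region assignment uses the A-site nucleotide, consistent
with the coverage definition).

## The statistical layer

**Box-Cox.** Raw coverage is skewed; the transform
$y = ((x + c)^\lambda - 1)/\lambda$ (with $y = \ln(x+c)$ at $\lambda = 0$)
is applied with pseudocount $c = 0.5$ guarding zeros (configurable; the
choice only matters at very low coverage). In automatic mode $\lambda$
maximizes the Gaussian profile log-likelihood on $[-2, 2]$ by grid search
refined with golden-section; the implementation is cross-checked against
MASS's profile in the tests.

**Lagged regression.** The design matrix joins the transformed per-codon
response with any feature tracks plus downstream lags: $\mathrm{Lag}_k$ at
codon $i$ is the response at codon $i + k$ (the A+k site), $k = 1..3$. Rows
with any undefined predictor or lag are dropped and counted. Fitting is
ordinary least squares with intercept; the Gaussian AIC includes the
log-likelihood constant so values are comparable with mainstream software.
Stepwise selection starts from the full model and greedily applies the
single add or drop that most decreases AIC until no move improves, with a
deterministic tie-break (drops before adds, then name order); perfectly
collinear columns are resolved before the search by dropping the
later-named duplicate. The selected model reports the classic columns
(estimate, standard error, t, p) via `tidy()`.

**Cumulative sums.** Per-codon occupancy is strongly autocorrelated, so
codonwise two-group tests are inappropriate. Instead the transformed values
are standardized and cumulatively summed; the curve is pinned to 0 at its
end by construction, and a sustained regional slowdown bends it away from 0.
Two procedures consume the curve:

* `white_noise_test()` simulates standard-Gaussian sequences of the same
  length, builds their curves, and reports the fraction whose maximum
  |curve| reaches the observed one — an exact Monte-Carlo p-value for the
  null "this profile is white noise";
* `cumsum_compare()` compares two variants' curves with the two-sample KS
  test on the curves' value sets. The choice of operands (curve values, not
  increments) is a convention this package fixes and documents, since it is
  not uniquely determined by the description it follows; with strongly
  autocorrelated curves its p-value should be read as a descriptive index,
  and the white-noise test is the calibrated instrument.

## What the generator emulates, and what it does not

`synthetic_usage_table()` draws a biased usage table (Gamma weights raised
to a skew exponent); its `gc3_bias` tilts preferences toward G/C-ending
codons, mirroring the empirical tendency of mammalian "optimal" codons, so
that `optimize_codons()` — which recodes every codon to its family maximum —
produces a variant that is more GC-rich and more structured than a
wild-type sampled from an AT-leaning table. This captures the defining
sequence-level signatures of real optimizers (common-codon enrichment, GC
gain, MFE decrease) but none of their multiparametric constraints (splice
sites, repeats, motif avoidance), so divergence percentages are of realistic
magnitude rather than matched to any particular optimizer.

`simulate_profiles()` generates the data-generating process the regression
assumes, and nothing more: a log-scale field with downstream-lag dependence
built recursively from the 3′ end ($\mu_i = \beta_0 + \sum_f \beta_f f_i +
\sum_k \beta_{\mathrm{lag}k} z_{i+k}$, optionally shifted by
$\log m$ inside a region), $z_i = \mu_i + N(0, \sigma)$, and counts
$\mathrm{Poisson}(d\, e^{z_i} / \overline{e^z})$ — a log-normal mixed
Poisson, the simplest process with both the lag structure and the
overdispersion the analysis must face. Defaults are one realistic operating
point for a strongly expressed transgene: depth 100 expected RPFs/codon,
$\sigma = 0.3$, $\beta_{\mathrm{lag}1} = 0.4$, three replicates, and a 2×
regional slowdown spanning codons 45–130 of a 461-codon gene when a shifted
variant is requested (the span mimics the Gla–EGF region of factor IX).
`simulate_fragments()` inverts coverage into fragments whose A-sites land in
the right codons, which makes profile → fragments → coverage an exact
round trip and the generator the fixture factory for all tests. No 5′ ramp,
dwell-time biophysics, sequencing error or multimapping is simulated —
passing tests say the *statistics* behave as designed, not that real
libraries look like this.

Two experimental-design choices deserve their rationale:

* **Recovery experiments run at depth 500.** The lag regressors are
  measured log-counts, so Poisson counting noise attenuates the lag
  coefficient by the reliability factor
  $\mathrm{var}(z) / (\mathrm{var}(z) + 1/d)$. At the recovery settings
  ($\beta_{\mathrm{lag}1} = 0.5$, $\sigma = 0.2$) the attenuation bias is
  ≈0.08 at depth 100 — comparable to three standard errors — but ≈0.02 at
  depth 500, so deep coverage makes the check about the estimator rather
  than about counting noise. The transform is fixed at $\lambda = 0$
  (natural log) there, matching the generator's log-scale truth.
* **Calibration experiments switch the lag effects off.** The white-noise
  test is calibrated against iid Gaussians; data with built-in lag
  dependence is *correctly* rejected by it at elevated rates. Null
  calibration therefore uses intercept-only profiles, where the full
  pipeline (Poisson counts, normalization, replicate averaging, log) holds
  the 5% level; the power experiment adds only the regional shift.

## Numerical choices and degenerate inputs

Zero-variance input to `cumsum_profile()` yields a flagged all-zero curve
(and a white-noise p of 1). An all-zero coverage profile is a normalization
error, not a silent NaN. Internal stop codons warn but are kept. The
stepwise tie-break and the aliased-column rule are deterministic so reruns
are bit-identical. Every stochastic routine takes an explicit seed;
simulation replicates use fixed seed offsets. The built-in partition
function refuses sequences beyond 4 kb (quadratic memory); the windowed
MFE track batches all windows through one external-engine call when RNAfold
is used.

Problem sizes in the shipped checks are chosen to make their statistical
claims decidable at conventional Monte-Carlo error: 1000 repetitions for
type-I-error bands, 100 seeded runs for recovery rates, exhaustive
enumeration only where the structure space is small (n ≤ 12).

## Known limitations

* The built-in energy model ranks structures by pair/stack counts only; its
  probabilities are exact for its own ensemble but are not thermodynamic
  predictions.
* CAI values depend on the usage-table snapshot; second-decimal agreement
  between sources should not be expected.
* The variant-vs-variant KS comparison inherits the autocorrelation of
  cumulative-sum curves; treat it as descriptive (the package therefore
  also ships the calibrated white-noise test).
* One transcript space per gene: multi-isoform mapping, soft-clipping and
  spliced alignments are out of scope, as are adapter trimming, contaminant
  removal and alignment itself.

## A compact worked example

```{r example, eval = FALSE}
usage <- synthetic_usage_table(bias = 1.5, gc3_bias = 0.5, seed = 1)
ref <- synthetic_usage_table(bias = 1, gc3_bias = 2, seed = 51)
wt <- sample_gene(usage, 461, seed = 2, id = "WT")
co <- optimize_codons(wt, ref, id = "CO")
sequence_divergence(wt, co)

truth <- simulation_truth(beta = c(intercept = 0, lag1 = 0.4), sigma = 0.3,
                          depth = 100,
                          region_shift = list(start = 45, end = 130,
                                              multiplier = 2), seed = 7)
prof <- simulate_profiles(co, truth)
avg <- average_replicates(normalize_profile(prof))
wn <- white_noise_test(log(avg$mean_value + 0.005), seed = 8)
wn$p_empirical
```

The README shows this pipeline end to end with the numbers it prints.
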