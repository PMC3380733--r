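---
title: "Unsupervised consensus assessment of MS/MS spectral quality: models and methods"
author: "ms2quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised consensus assessment of MS/MS spectral quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2quality)
```

## The problem

A single proteomics run produces tens of thousands of tandem mass (MS/MS)
spectra, the large majority of which are noise — chemical background, poorly
fragmented precursors, co-isolated mixtures. Searching them all against a
protein database wastes most of the search time and inflates false
identifications. `ms2quality` scores every spectrum with a probability of
being high quality *before* the search, using no training labels, so that the
poor-quality bulk can be set aside.

The method has two stages:

1. **Per-feature assessments.** Ten real-valued quality features are computed
   per spectrum, each designed so that larger values indicate higher quality.
   Each feature alone is a weak assessor: the top `p`% of spectra by that
   feature (default `p = 50`) are called high quality, the rest poor.
2. **Consensus integration.** The ten weak binary assessments are integrated
   into per-spectrum probabilities by a constrained quadratic optimization on
   a bipartite spectrum–group graph, solved by an alternating algorithm with
   provable properties (row-stochastic iterates, non-increasing cost).

## Stage 1: the ten features

For a spectrum with peaks at m/z values $M(x)$ and intensities $I(x)$, let
$\mathrm{NormI}(x) = I(x) / \sum_y I(y)$. All pair comparisons use a tolerance
$\tau$ (default 0.5 Da, appropriate for low-resolution ion-trap data) and
treat every peak as singly charged.

| | feature | unit | rationale |
|---|---|---|---|
| f1 | total NormI of peaks in complementary pairs | fraction | b/y ions from one backbone bond sum to a precursor-determined target |
| f2 | uncharged precursor mass $m/z \cdot z - z\,m_p$ | Da | poor spectra tend to come from small precursors |
| f3 | pairs differing by a residue mass | count | consecutive same-series ions differ by one residue |
| f4 | mean gap between adjacent peaks | Da | overly dense spectra are poor |
| f5 | Good-Diff fraction: $\sum\{\mathrm{NormI}(x)+\mathrm{NormI}(y)\,:\, M(x)-M(y)\approx M_i\}$ | fraction | intensity-weighted version of f3 |
| f6 | complementary pair count | count | as f1, unweighted |
| f7 | pairs differing by water/ammonia | count | neutral-loss satellites mark real fragments |
| f8 | share of peaks above 1% of total intensity | fraction | signal peaks are intense |
| f9 | standard deviation of adjacent gaps | Da | as f4 |
| f10 | pairs differing by CO/NH | count | a-/z-ion support |

Numerical conventions the definitions leave open, fixed here once:

* **NormI** is intensity over total intensity (not rank-based).
* **Pair-sum target for f1/f6.** "Two peaks whose m/z values sum to the mass
  of the precursor ion" needs a proton-bookkeeping convention. The default
  target is the *uncharged* precursor mass $m/z \cdot z - z\,m_p$ (which also
  equals f2); `mass_constants(pair_sum_convention =)` exposes the singly
  protonated mass (`"protonated"`) and the physical sum of singly protonated
  b/y ions, $M + 2m_p$ (`"by"`), for users who prefer those readings. At the
  0.5 Da default tolerance the three targets differ by 1–2 proton masses, so
  the choice matters and must be consistent between data and configuration;
  the synthetic generator plants its complementary pairs against whichever
  convention is configured.
* **f1 counts each peak once.** A peak participating in several complementary
  pairs contributes its NormI once, so f1 is the total normalized intensity
  *in* complementary pairs and stays in $[0,1]$. f5, by contrast, is the
  literal per-pair sum: two disjoint matching pairs of equal-intensity peaks
  give 2.0. The two readings are both defensible for f1; the bounded one was
  chosen because the feature is described as a *total normalized intensity*.
* **f3 counts pairs, not peaks.** "The number of peaks whose mass difference
  equals a residue mass" is ambiguous between peaks and pairs;
  unordered-pair counting is used (a peak-counting variant would differ only
  when one peak matches several partners).
* **f9** uses the sample (n−1) standard deviation.
* **Residue masses** are monoisotopic. Leu/Ile coincide and Gln/Lys nearly
  coincide; both are retained in the 20-entry table and a pair matching
  several residues counts once (the matching windows are merged into disjoint
  intervals before counting).
* **Degenerate spectra** (fewer than 2 peaks; fewer than 3 for f9) get 0 for
  the affected features with a warning rather than an error, so a batch run
  never aborts on a junk scan.

The pair searches are implemented as window scans over the sorted peak list
(`findInterval` on merged tolerance intervals), with equality to a naive
$O(p^2)$ double loop asserted in the test suite.

## Stage 2: consensus on the bipartite graph

With $n$ spectra and $m = 10$ features, each feature splits the dataset in
two, giving $v = 2m$ *groups*; group $2(f-1)+z$ holds the spectra assigned
class $z$ (1 = high, 2 = poor) by feature $f$. Membership is recorded in the
binary affinity matrix $A_{n \times v}$ (each row sums to $m$), and the
groups' nominal classes in the one-hot matrix $Y_{v \times 2}$. The unknowns
are row-stochastic matrices $U_{n \times 2}$ (spectrum class probabilities)
and $Q_{v \times 2}$ (group class probabilities), estimated by minimizing

$$J(U, Q) = \sum_{z}\sum_{i}\sum_{j} a_{ij}\,(u_{iz} - q_{jz})^2
  \;+\; \alpha \sum_{z}\sum_{j} (q_{jz} - y_{jz})^2,$$

subject to each row of $U$ and $Q$ lying on the probability simplex. The
first term makes spectra agree with their groups; the second anchors groups
to their initial labels with confidence $\alpha$. $J = 0$ exactly when all
ten assessors agree on every spectrum.

Because $J$ is quadratic in $U$ for fixed $Q$ and vice versa, alternating
exact minimization gives closed-form updates:

$$u_{iz} = \frac{1}{m}\sum_j a_{ij} q_{jz}, \qquad
  q_{jz} = \frac{\sum_i a_{ij} u_{iz} + \alpha y_{jz}}{\alpha + \sum_i a_{ij}}.$$

Starting from $Q^0 = Y$, induction shows every iterate is row-stochastic with
entries in $[0,1]$ — the simplex constraints never need to be projected — and
the cost is non-increasing and bounded below, so the iteration converges to a
stationary point. Both properties are asserted on every solve and
property-tested on hundreds of random instances; the fixed point is also
checked against a direct solve of the linear fixed-point system and a generic
box-constrained numerical minimizer of $J$.

### Tunable parameters

* `percentile` (default 50): share of spectra each feature may call high.
  With heavily imbalanced data (real runs are ~95% poor) 50% is deliberately
  generous; the consensus stage, not the split, supplies the precision.
  Exactly `ceiling(n * p / 100)` spectra go to class 1, ties broken by input
  position so runs are reproducible.
* `alpha` (default 90): confidence in the initial group labels. Large
  `alpha` pins $Q \to Y$ and $U$ to the one-step majority-vote average
  (checked at $\alpha = 10^8$ in the tests); small `alpha` lets strongly
  coherent spectra pull groups away from their nominal labels.
* `epsilon` (default 1e-6): stopping tolerance on the Frobenius norm
  $\lVert U^t - U^{t-1}\rVert_F$ (the stopping rule's norm is otherwise
  unspecified; Frobenius is the natural choice for a matrix iterate).
* `max_iter` (default 1000): a cap, flagged rather than thrown — in practice
  the solve converges in tens of iterations because `alpha` makes the
  Q-update a strong contraction.
* `threshold` (default 0.5): the final call is high iff
  $u_{i1} \ge$ `threshold` (boundary counts as high). Filtering uses the
  fixed threshold; ROC evaluation sweeps it.

## The synthetic data generator

Real label sets require a database search; the generator provides labelled
data with the structure the features are built to detect, at desk scale:

* **High-quality spectra**: a random peptide (length 8–16, uniform residues),
  singly charged b- and y-ion ladders — consecutive same-series ions differ
  by residue masses, and each b/y pair sums to the configured pair-sum
  target — with ions dropped independently (p = 0.2), water/ammonia-loss
  satellites added (p = 0.3) at 20–50% of the parent intensity, lognormal
  fragment intensities, Gaussian m/z jitter (sd 0.05 Da), and 10–40 uniform
  noise peaks with much weaker lognormal intensities. The precursor is the
  singly protonated peptide.
* **Poor-quality spectra**: 20–70 uniform-random peaks on 100–1600 m/z with
  noise intensities, and a precursor mass drawn uniformly from 300–900 Da —
  deliberately smaller than the peptide precursors, mirroring the observation
  motivating f2.
* The default dataset is 50 high + 950 poor spectra (5% high), matching the
  ~95%-poor class balance of real ion-trap runs.

All randomness flows from the single mandatory `seed`; the caller's RNG state
is saved and restored, and the same config yields byte-identical MGF output.

What the generator does *not* emulate: multiply charged fragments and
precursors (the features themselves assume singly charged peaks, a known
limitation for triply charged spectra), isotope envelopes, correlated
chemical noise, retention-time structure, and instrument-specific intensity
response. Passing the end-to-end recovery test therefore shows the pipeline
is wired correctly and separates ladder structure from noise; it does not
certify performance on any particular instrument's data, where the operating
point must be read off a labelled subset or accepted on faith.

Peak counts for poor spectra (20–70) were chosen to overlap the high-quality
peak counts so that the pair features, not raw peak numbers, carry the
signal; on such data f4, f8 and f9 are intentionally weak or even inverted
assessors, which is realistic and exercises the consensus stage's robustness
to a minority of misleading features.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 1000
simulated spectra (about 5 s), property-test the solver invariants on 400
random instances with up to 50 spectra and 10 features, and verify the
feature window scans against brute-force enumeration on spectra of up to 50
peaks — sizes at which the brute-force oracles are exact and fast. The
solver's monotone-cost assertion uses a relative slack of $10^{-9}$ to absorb
floating-point rounding; duplicate m/z values are merged at construction time
(summed intensity) so pair counting never sees ties; zero-intensity peaks are
dropped on input because they contribute nothing to any feature and would
make NormI ill-defined on pathological all-zero spectra.

## Known limitations

* Features f3/f6/f7/f10 assume singly charged fragments; triply charged
  precursors produce doubly charged fragments these features miss.
* The percentile binarization with a global default of 50% is crude when the
  true high-quality fraction is far from 50%; the consensus compensates but
  an adaptive cut-off would be a natural extension.
* `predict()` on new spectra binarizes with the per-feature value cut-offs
  learned at fit time; spectra tied exactly at a cut-off may be classed
  differently than they would have been inside the original percentile split.
* No denoising is applied before feature computation; a peak-filtering hook
  can be composed upstream of `assess_quality()` if desired.
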