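---
title: "Probabilistic cross-peak matching: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic cross-peak matching: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftmatch)
```

## The matching problem and its posterior

Given R reference cross-peaks and T target cross-peaks from two spectra of
the same molecule, a matching is a binary R x T matrix M with at most one 1
per row and per column; all-zero rows and columns encode peaks without a
counterpart. `shiftmatch` models M as a random variable and estimates its
posterior given the observed chemical-shift differences, under the
assumption that peak movement comes either from positional noise or from a
fast-exchange chemical shift perturbation (CSP). Rather than reporting one
best matching, the package reports, per reference peak, the marginal
probability of every target assignment and of having no match at all. The
posterior probability is the package's confidence score, and the evaluation
utilities let the user verify on synthetic data that it is calibrated:
matches reported at probability p are correct about a fraction p of the
time.

## Features and the three-component likelihood

The only feature used is the uncertainty-normalised squared distance

$$D_{rt} = \sum_{k=1}^{K} \frac{(\delta_{r,k} - \delta_{t,k})^2}
          {\sigma_{r,k}^2 + \sigma_{t,k}^2},$$

where K is the spectral dimensionality and each spectrum carries its own
per-dimension positional uncertainty $\sigma$ (ppm). Three conditional laws
classify each $D_{rt}$:

* **Matched, noise only.** If peak positions fluctuate with Gaussian noise
  of the stated uncertainties, $D_{rt}$ for a true match is exactly
  $\chi^2_K$. No free parameters.
* **Matched with a CSP.** Genuinely perturbed matches have heavy-tailed
  displacement; their $D_{rt}$ is modelled as Fréchet with shape
  $\alpha \ge 1$ and scale $s > 0$ (density
  $(\alpha/s)(d/s)^{-1-\alpha} e^{-(d/s)^{-\alpha}}$, zero at the origin).
  Both parameters are learned. The matched likelihood is the mixture
  $\phi\,f_{\text{Fréchet}} + (1-\phi)\,f_{\chi^2}$ with learned weight
  $\phi \in [0,1]$.
* **Not matched.** Distances between unrelated peaks are approximately
  uniform over the scale of the spectrum, so the non-match likelihood is a
  constant $1/\omega$. $\omega$ is not free: it is solved so that the
  matched and non-matched likelihoods cross exactly at the normalised
  squared distance $D_{\max}$ of the largest CSP the user expects — beyond
  that distance, disappearance plus a new peak is the better explanation.

All likelihood arithmetic is in log space; $\omega$ is carried as
$\log\omega$ so the crossing point can sit far below double precision
without overflow.

### Converting the expected maximum CSP to $D_{\max}$

Users state the largest expected CSP in ppm on the *combined* CSP scale
(per-dimension differences weighted 1 for ^1^H, 0.101 for ^15^N, 0.252 for
^13^C, then combined as a Euclidean norm). The package converts this to a
normalised squared distance by splitting the stated magnitude equally over
dimensions on the combined scale — the displacement
$\Delta_k = c /(\text{scale}_k \sqrt{K})$ has combined CSP exactly $c$ —
and normalising by the pooled variances. A `max_csp_distance` argument
bypasses the conversion entirely. The choice of split is a convention; any
single displacement direction with combined CSP $c$ differs from it by at
most a factor of $K$ in $D_{\max}$, which moves $\log\omega$ by
$\log K$ — small relative to the likelihood ratios that drive matching.

## Decision parameterisation and reference-peak ordering

A matching is built as one decision per reference peak: a target index or
"no match". The decision likelihood matrix S has entries
$S_{rt} = f_{\text{match}}(D_{rt}) \cdot (1/\omega)^{T-1}$ and
$S_{r,T+1} = (1/\omega)^{T}$, so that a complete decision set multiplies to
the full-matrix likelihood.

Decisions are not taken in input order. Per reference peak, a candidate set
is built by (1) dropping targets whose matched likelihood is below the
non-match level, (2) normalising the survivors (plus the never-dropped
no-match outcome) to probabilities, and (3) dropping targets below 1/20 of
the best target's probability. Two reference peaks "compete" when they share
a candidate with probabilities within a factor of 20 of each other; their
distance is the reciprocal competing-candidate count (infinite when none).
Shortest paths over this graph feed single-linkage clustering cut at 1.0 —
because every finite hop is at most 1, clusters are exactly the connected
components — and, within each cluster, optimal leaf ordering of the
dendrogram places the most entangled peaks adjacently. Clusters are
processed in ascending order of their smallest member index; the ordering
only affects sampling efficiency, not the posterior.

## The sequential Monte Carlo sampler

N particles (N starts at max(64, R)) extend their partial matchings cluster
by cluster. The proposal for a decision looks ahead over the next rows of
the same cluster: the weight of decision i is the beam-search approximation
of the summed likelihood of all completions of the cluster consistent with
i, retaining at most `beam_width` (default 1000) highest-likelihood paths
per expansion. Importance weights are the exact ratio of target to proposal
probability, so every lookahead approximation below is a proposal-quality
choice, never a bias:

* the lookahead horizon spans `lookahead_depth` (default 2) subsequent rows;
* lookahead partitions are computed on the cluster's *relevant* columns
  (within $e^{14}$ of a row maximum, capped at the top 24), via a single
  beam run from which every "column t consumed" partition is read off as
  the sum over retained paths avoiding t;
* per-row draws group particles by their availability pattern over the
  row's head columns (within $e^{12}$ of the maximum) and drop decisions
  below $e^{-20.7}$ of the maximum from the proposal support (total
  truncated mass below $T \times 10^{-9}$); the recorded proposal
  probability is the exact truncated law given each particle's available
  support.

Degeneracy is handled on three levels:

1. **Width escalation.** If a cluster's incremental weights have an
   effective-sample-size (ESS) ratio below 0.2 while the beam is still
   inexact, the cluster's decisions are discarded and the beam width grows
   five-fold (up to `beam_width_cap`); once the width covers every
   lookahead branch, a low ESS cannot be improved by widening and the
   cluster is accepted.
2. **Adaptive stratified resampling.** Accumulated weights are resampled
   (stratified, one uniform per stratum) whenever their ESS ratio drops
   below `resample_threshold` (default 0.25). Resampling after *every*
   cluster was evaluated and rejected: with hundreds of mostly independent
   clusters, per-cluster resampling provably erodes the particle genealogy
   (measured on the package's own benchmark: unique ancestors fell from 200
   to 1), which collapses every marginal to 0/1 and destroys calibration.
3. **Rejuvenation.** After the sequential pass, each particle receives
   `gibbs_sweeps` (default 2) full-conditional re-draws of every row plus
   Metropolis swap proposals between any two rows sharing a plausible
   target. Both kernels leave the matching posterior invariant, so the
   importance weights stay valid; they restore the per-row diversity and
   two-peak exchange mixing that sequential decisions and resampling erode.

Finally, two independent ensembles are drawn and their weighted per-pair
marginal frequencies compared; if any frequency differs by more than 0.1,
N doubles and sampling repeats (persisting across EM iterations). The two
ensembles are merged into the returned sample, and marginals are
importance-weighted frequencies. If frequencies fail to stabilise after
`max_doublings` doublings the run proceeds with the merged sample and a
warning rather than aborting.

## Expectation–maximization

* **Initialisation.** $\theta = (\alpha, s)$ starts from the Fréchet MLE of
  the per-row minimum distances after discarding values below
  `init_min_distance` (default 3 — noise-level matches), with the shape
  clamped at 1; if fewer than three values survive, a warning is emitted
  and a neutral start (shape 1.5, scale = median survivor or
  $D_{\max}/2$) is used. The Beta prior on $\phi$ has mean equal to the
  user's expected CSP fraction and standard deviation
  $2 \times \text{mean} \times \text{variance scale}$; whenever the moment
  solution is infeasible or yields a pseudo-count below 1, both
  pseudo-counts are rescaled (mean-preserving) so the smaller equals 1.
  $\phi$ starts at the prior mean and $\omega$ at the crossing solution.
* **E step.** $P(M_{rt}=1)$ is the weighted frequency of the pair in the
  sampled matchings; the CSP responsibility is
  $\phi f_{\text{Fréchet}} / f_{\text{match}}$ per cell.
* **M step.** $\phi$ has the closed-form Beta-regularised MAP update
  $(\sum p^{\text{csp}} p^{\text{match}} + a - 1)/(\sum p^{\text{match}} +
  a + b - 2)$ over matched cells, with $a$ the CSP-category pseudo-count.
  $\theta$ maximises the $p^{\text{match}}$-weighted expected log matched
  density numerically (L-BFGS-B, warm-started, shape bounded at 1); a
  failed or non-improving optimisation keeps the previous value with a
  warning. $\omega$ is re-solved at the new $(\theta, \phi)$.
* **Convergence.** The loop stops when the largest relative change over
  $\{\alpha, s, \phi, \log\omega\}$ falls below `em_tol` (default 0.01,
  $\log\omega$ because $\omega$ itself may exceed double range), or after
  `em_max_iter` (default 30) iterations with a warning. A final sampling
  pass at the converged parameters produces the reported marginals.

## What the simulator emulates — and what it does not

`simulate_peak_lists()` generates data from the model's own assumptions:
uniform peak placement with a minimum-spacing rejection step (crowding
control in normalised units), per-dimension Gaussian jitter with the pooled
uncertainty so noise-only matched distances are exactly $\chi^2_K$, a
Fréchet-distributed *added* squared displacement in a uniformly random
direction for the CSP subset, dropped references and uniform clutter. Its
defaults are the package's benchmark conditions: 200 peaks over an amide
region (H 6.5–10.5 ppm, N 100–135 ppm), uncertainties 0.0015/0.015 ppm,
CSP fraction 0.1 with Fréchet(1.5, 8), 5% dropped, 5% spurious, minimum
spacing 5.

Passing tests on this generator demonstrates internal consistency —
correct likelihoods, a sampler that converges to the exact posterior,
parameter recovery, calibrated confidences — under the model's own
generative assumptions. Real spectra violate those assumptions in ways the
simulator does not reproduce: correlated peak movement, non-Gaussian
position errors from distorted lineshapes, intensity information (ignored
by the model), and systematic peak-picking artefacts. Calibration on real
data therefore has to be checked against annotated spectra.

Two simulator details worth knowing: the realised matched distance is
$|z + v|^2$ with $z$ the Gaussian noise and $|v|^2$ Fréchet, so recovered
scales run slightly above the injected one (the noise adds roughly K to
the mean); and `true_csp_ppm` records the combined CSP of the *realised*
positions, which is what a detector can hope to see.

## Benchmark and evaluation choices

The recovery benchmark feeds the matcher an expected maximum CSP of
0.07 ppm, the ~99.9th percentile of the simulated CSP law. This is the
"informed user" condition appropriate for a recovery experiment. Supplying
instead a strongly overestimated bound (for instance 0.2 ppm, a sensible
default for a fragment screen) enlarges $\omega$ so far that dropped
references prefer distant clutter over no-match; the fitted Fréchet tail
then flattens toward the shape bound. That behaviour is the model answering
the question it was asked — "could this peak have moved 0.2 ppm?" — and
illustrates why the expected-maximum-CSP input deserves thought on real
data.

The crowded CSP-detection benchmark (60 peaks in a 0.6 x 6 ppm window with
doubled uncertainties, 30% CSPs with scale 50, 20% clutter) is deliberately
ambiguous: about half its references hold two or more candidate targets.
There, requiring a single >= 0.95 match finds almost no significant CSPs,
while summing marginal mass over all significantly-moved targets detects
half of them at the same confidence level — the practical argument for
marginal-mass hit detection in screening.

Evaluation conventions: accuracy is correct/made matches, completeness is
correct/true matches, both reported per posterior bin and cumulatively
above a cutoff; empty bins carry NA accuracy. CSP estimates are
probability-weighted means with *population* standard deviations (weights
are probabilities, not counts). CSP-bin edges for found/missed histograms
default to log-spaced values between 0.001 and 1 ppm and are configurable.

## Numerical choices and degenerate inputs

* Exact zero distances: the $\chi^2_1$ density diverges at 0, so K = 1
  evaluations clamp d to ~10 machine epsilons (identical coordinates occur
  with quantised ppm values). The Fréchet density is exactly 0 at d = 0.
* Ties: argmax ties in reports resolve to the lower target index and are
  flagged; beam pruning and leaf-ordering ties resolve by deterministic
  construction order and lowest index respectively.
* Determinism: a single integer seed drives every random draw; a repeated
  run is bit-identical, including the EM trajectory.
* Degenerate ensembles (all weights zero) and a beam width exceeding its
  cap raise errors naming the likely cause.

## Known limitations

* Pure R implementation: a 200 x 200 matching with EM runs in tens of
  seconds; thousands of peaks would want a compiled inner loop.
* The model ignores peak intensities and lineshapes, treats dimensions'
  uncertainties as globally fixed per spectrum, and assumes at most
  one-to-one matching (no peak splitting/merging).
* Posterior correlations between specific assignment pairs are sampled but
  only marginals are reported.
* The matched-CSP law is a single Fréchet; multimodal perturbation
  magnitudes (e.g. two binding sites) are fit by one heavy tail.
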