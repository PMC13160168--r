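# shiftmatch

Probabilistic matching of cross-peaks between two multidimensional NMR peak
lists, with calibrated posterior confidence for every proposed match.

## The problem

Comparing two heteronuclear NMR spectra of the same molecule — a reference
spectrum and a spectrum perturbed by ligand binding, pH, temperature, or
simply re-acquisition — requires mapping each reference cross-peak onto its
counterpart in the target list. In crowded regions the mapping is ambiguous:
a peak that moved (a chemical shift perturbation, CSP) may have several
plausible destinations, peaks can vanish (exchange broadening, picking
errors), and spurious peaks appear. Manual matching is slow and subjective,
and point-estimate matchers give no sense of which assignments to trust.

`shiftmatch` treats the matching matrix **M** (one-to-one, rows = reference
peaks, columns = target peaks, all-zero rows/columns allowed) as a random
variable and estimates its full Bayesian posterior. Users get, for every
reference peak, marginal probabilities over all target peaks *and* the
explicit no-match outcome.

## The model

For reference peak r and target peak t the feature is the
uncertainty-normalised squared distance

    D[r,t] = sum_k (delta_r,k - delta_t,k)^2 / (sigma_r,k^2 + sigma_t,k^2)

with per-dimension, per-spectrum positional uncertainties sigma. Each D[r,t]
is classified by a three-component likelihood:

* **matched, noise only** — D ~ chi-squared with K degrees of freedom
  (K = number of dimensions);
* **matched, genuine CSP** — D ~ Frechet(shape alpha >= 1, scale s), a
  heavy-tailed law for real perturbations, mixed with the noise component
  with weight phi;
* **not matched** — a constant pseudo-likelihood 1/omega, with omega fixed
  so that matching and non-matching are equally likely at the largest CSP
  the user expects.

The posterior over matching matrices is sampled by a sequential Monte Carlo
sampler: reference peaks are clustered by candidate-target overlap, ordered
by optimal leaf ordering, and decided sequentially with beam-search
lookahead proposals, importance weighting, adaptive stratified resampling,
and invariant rejuvenation (full-conditional re-draws plus pairwise swap
moves). alpha, s, phi and omega are fitted by expectation–maximization with
a Beta-prior MAP update for phi. Marginal match probabilities are the
weighted frequencies over the sampled matrices.

## Worked example

```r
library(shiftmatch)

# a synthetic 30-peak amide pair with known ground truth: 10% of matched
# peaks carry a Frechet-distributed CSP, 5% of peaks drop out, 5% clutter
sim <- simulate_peak_lists(n_ref = 30, seed = 42)

fit <- match_peaks(sim$reference, sim$target,
                   max_csp = 0.07,       # largest expected combined CSP, ppm
                   csp_fraction = 0.1,   # expected fraction of CSPs
                   seed = 42)
glance(fit)
#>   n_ref n_tgt   dof iterations converged    phi frechet_shape frechet_scale
#> 1    30    30     2          4 TRUE      0.0920          1.98          12.9
```

EM converged in 4 iterations; the recovered CSP fraction (phi = 0.09) and
Frechet parameters sit near the generative values (0.1, and shape 1.5 /
scale 8 within the precision a 30-peak list supports). The per-reference
report is the `tidy()` method:

```r
tidy(fit)[1:6, c("reference_id", "target_id", "posterior_probability",
                 "csp_ppm", "csp_posterior_mass")]
#>   reference_id target_id posterior_probability  csp_ppm csp_posterior_mass
#> 1            1        18                     1  0.00125                  0
#> 2            2         3                     1  0.00155                  0
#> 3            3        13                     1  0.00252                  0
#> 4            4        22                     1  0.00327                  0
#> 5            5         8                     1  0.00189                  0
#> 6            6        NA                     1 NA                        0
```

Reference 6 is confidently unmatched (its target was dropped in the
simulation); the others match with posterior ~1 and sub-0.004 ppm combined
CSPs — noise-level movements. Marginal-mass CSP detection flags peaks whose
probability mass sits on significantly moved targets (> 0.01 ppm), even
when the specific destination is uncertain:

```r
dplyr::filter(detect_csps(fit), detected)
#>   reference_id csp_posterior_mass detected best_target_id best_probability
#> 1            7                  1 TRUE                 21                1
```

Against the simulation's ground truth, every match made at posterior >= 0.95
is correct and complete:

```r
evaluate_matches(tidy(fit), sim$truth) |> dplyr::filter(bin_low >= 0.95)
#>   bin_low bin_high  n accuracy cum_accuracy cum_completeness
#> 1    0.95        1 28        1            1                1
```

Real peak lists enter through `read_sparky_list()` (Sparky/POKY `.list`
exports) or `read_peak_table()` (CSV/TSV); `write_match_report()` saves the
report. A command line interface with `match`, `simulate` and `evaluate`
subcommands lives at `inst/cli/shiftmatch.R` (see `?cli_run`).

## Package layout

* `R/peak-list.R`, `R/io.R` — peak-list container and Sparky/CSV readers.
* `R/likelihood.R` — distances, the three likelihood components, omega.
* `R/ordering.R` — candidate sets, overlap clustering, decision order.
* `R/smc.R` — decision matrix, beam proposals, SMC sampler.
* `R/em.R` — initialisation, EM updates, `match_peaks()`.
* `R/analysis.R` — reports, CSP detection/estimation, evaluation.
* `R/simulate.R` — synthetic peak-list pairs with ground truth.
* `vignettes/matching-methods.Rmd` — the model, sampler design, parameter
  choices and limitations.
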