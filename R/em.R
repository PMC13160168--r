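#' Control parameters for matching
#'
#' Tunables of the sampler and EM loop. `beam_width` starts the beam search at
#' the default width of 1000 and escalates five-fold on poor
#' proposal-to-target agreement up to `beam_width_cap`; `ess_threshold` is the
#' effective-sample-size ratio below which a cluster is re-sampled with a
#' wider beam; `freq_tol` is the largest per-pair marginal frequency
#' difference tolerated between two independent ensembles before the particle
#' count doubles; `candidate_prob_ratio` is the factor for the candidate-set
#' pruning and overlap rules; `init_min_distance` filters row-minimum
#' distances used to seed the Frechet fit.
#'
#' @param candidate_prob_ratio Candidate/overlap probability ratio (default 20).
#' @param beam_width Starting beam width (default 1000).
#' @param beam_width_cap Largest allowed beam width (default 125000).
#' @param ess_threshold Resampling ESS-ratio threshold (default 0.2).
#' @param freq_tol Frequency-stability tolerance (default 0.1).
#' @param resample_threshold Accumulated ESS ratio below which the ensemble is
#'   stratified-resampled (default 0.25). Resampling only on demand preserves
#'   lineage diversity across the many independent clusters of a typical list.
#' @param gibbs_sweeps Full-conditional rejuvenation sweeps applied to every
#'   particle after the sequential pass (default 2); the kernel leaves the
#'   posterior invariant and restores the per-row diversity that resampling
#'   erodes.
#' @param lookahead_depth Number of subsequent cluster rows the beam-search
#'   lookahead spans when proposing a decision (default 2); decisions further
#'   ahead are corrected by weighting, resampling and rejuvenation.
#' @param min_particles Floor on the particle count (default 64).
#' @param max_doublings Cap on particle-count doublings (default 8).
#' @param em_tol Relative parameter-change convergence tolerance (default 1e-2).
#' @param em_max_iter Maximum EM iterations (default 30).
#' @param init_min_distance Lower cutoff on row minima for initialisation
#'   (default 3, normalised squared distance units).
#' @return A named list of class `match_control`.
#' @export
match_control <- function(candidate_prob_ratio = 20, beam_width = 1000,
                          beam_width_cap = 125000, ess_threshold = 0.2,
                          freq_tol = 0.1, resample_threshold = 0.25,
                          gibbs_sweeps = 2, lookahead_depth = 2, min_particles = 64,
                          max_doublings = 8, em_tol = 1e-2, em_max_iter = 30,
                          init_min_distance = 3) {
  structure(list(candidate_prob_ratio = candidate_prob_ratio,
                 beam_width = beam_width, beam_width_cap = beam_width_cap,
                 ess_threshold = ess_threshold, freq_tol = freq_tol,
                 resample_threshold = resample_threshold,
                 gibbs_sweeps = gibbs_sweeps,
                 lookahead_depth = lookahead_depth,
                 min_particles = min_particles, max_doublings = max_doublings,
                 em_tol = em_tol, em_max_iter = em_max_iter,
                 init_min_distance = init_min_distance),
            class = "match_control")
}

# Frechet maximum likelihood with the shape bounded below at 1
frechet_mle <- function(x, start = c(1.5, stats::median(x))) {
  nll <- function(par) {
    v <- -sum(csp_log_density(x, par[[1]], par[[2]]))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- optim(pmax(start, c(1, 1e-8)), nll, method = "L-BFGS-B",
               lower = c(1, 1e-8), upper = c(1e3, 1e15))
  c(shape = fit$par[[1]], scale = fit$par[[2]])
}

# Beta prior with mean m and target sd 2*m*variance_scale; when the moment
# solution is infeasible or gives a pseudo-count below 1, both parameters are
# rescaled by a common factor (mean-preserving) so min(a, b) = 1
beta_prior <- function(m, variance_scale) {
  if (m <= 0 || m >= 1) stopf("`csp_fraction` must be in (0, 1)")
  v <- (2 * m * variance_scale)^2
  ab <- m * (1 - m) / v - 1
  if (ab > 0) {
    a <- m * ab; b <- (1 - m) * ab
    if (min(a, b) >= 1) return(c(a = a, b = b))
    sc <- 1 / min(a, b)
    return(c(a = a * sc, b = b * sc))
  }
  # infeasible variance: smallest admissible pseudo-counts at that mean
  if (m <= 0.5) c(a = 1, b = (1 - m) / m) else c(a = m / (1 - m), b = 1)
}

#' Initial model parameters
#'
#' The Frechet component is seeded by collecting the smallest distance in each
#' reference row, discarding values below `init_min_distance` (these are
#' noise-level matches), and fitting the Frechet MLE with the shape bounded at
#' 1. The Beta prior on the CSP fraction has mean `csp_fraction` and standard
#' deviation `2 * csp_fraction * variance_scale`, rescaled mean-preserving so
#' both pseudo-counts are >= 1; `phi` starts at the prior mean, and `omega`
#' is solved so matching and non-matching likelihoods cross at
#' `max_csp_distance`.
#'
#' @inheritParams build_decision_matrix
#' @param max_csp_distance Dmax, normalised squared distance of the largest
#'   expected CSP (see [max_csp_to_distance()]).
#' @param csp_fraction Expected fraction of reference peaks undergoing a CSP,
#'   in (0, 1).
#' @param variance_scale Scaling factor on the prior standard deviation
#'   (default 2).
#' @param init_min_distance Cutoff below which row minima are discarded
#'   (default 3).
#' @param dof Number of spectral dimensions K.
#' @return A [match_params()] with `omega` set.
#' @export
initialize_params <- function(d, max_csp_distance, csp_fraction,
                              variance_scale = 2, init_min_distance = 3,
                              dof = 2L) {
  mins <- apply(d, 1, min)
  surv <- mins[mins >= init_min_distance]
  if (length(surv) < 3) {
    warnf("only %d row-minimum distances >= %g; falling back to default Frechet start",
          length(surv), init_min_distance)
    theta <- c(shape = 1.5,
               scale = if (length(surv)) stats::median(surv) else max_csp_distance / 2)
  } else {
    theta <- frechet_mle(surv)
  }
  pr <- beta_prior(csp_fraction, variance_scale)
  params <- match_params(frechet_shape = theta[["shape"]],
                         frechet_scale = theta[["scale"]],
                         phi = csp_fraction,
                         prior_a = pr[["a"]], prior_b = pr[["b"]],
                         max_csp_distance = max_csp_distance, dof = dof)
  solve_omega(params)
}

#' Posterior marginals from a sampled ensemble
#'
#' `p_match[r, t]` is the frequency with which reference r was matched to
#' target t across the sampled matchings (column T+1 = no match); `p_csp` is
#' the per-cell posterior probability that a matched pair arose from a CSP
#' rather than noise, `phi * f_csp(d) / f_match(d)`.
#'
#' @param ensemble A `match_ensemble` from [sample_posterior()].
#' @inheritParams build_decision_matrix
#' @return A list of class `match_marginals` with matrices `p_match`
#'   (R x (T+1)) and `p_csp` (R x T).
#' @export
expectation <- function(ensemble, d, params) {
  p_match <- ensemble$p_match
  if (params$phi == 0) {
    p_csp <- matrix(0, nrow(d), ncol(d))
  } else {
    lc <- log(params$phi) +
      csp_log_density(as.vector(d), params$frechet_shape, params$frechet_scale)
    lm <- match_log_density(as.vector(d), params)
    p <- exp(lc - lm)
    p[!is.finite(p)] <- 0
    p_csp <- matrix(pmin(p, 1), nrow(d), ncol(d))
  }
  structure(list(p_match = p_match, p_csp = p_csp), class = "match_marginals")
}

#' EM updates of the mixture parameters
#'
#' `update_phi()` is the closed-form Beta-regularised MAP update of the CSP
#' mixture weight: `(sum p_csp * p_match + a - 1) / (sum p_match + a + b - 2)`
#' with sums over matched cells only (the no-match column is excluded) and
#' `a` the CSP-category pseudo-count. `update_theta()` numerically maximises
#' the `p_match`-weighted expected log matching density over the Frechet
#' shape (>= 1) and scale, warm-started at the current values; if the
#' optimiser fails to improve the objective the previous values are kept.
#'
#' @param marginals A `match_marginals` from [expectation()].
#' @inheritParams build_decision_matrix
#' @return `update_phi()`: the updated phi scalar. `update_theta()`: named
#'   vector `c(shape, scale)`.
#' @export
update_phi <- function(marginals, params) {
  tn <- ncol(marginals$p_csp)
  pm <- marginals$p_match[, seq_len(tn), drop = FALSE]
  den <- sum(pm) + params$prior_a + params$prior_b - 2
  if (den <= 0) {
    warnf("no matches in ensemble; keeping phi = %g", params$phi)
    return(params$phi)
  }
  num <- sum(marginals$p_csp * pm) + params$prior_a - 1
  min(max(num / den, 0), 1)
}

#' @rdname update_phi
#' @export
update_theta <- function(marginals, d, params) {
  tn <- ncol(d)
  pm <- marginals$p_match[, seq_len(tn), drop = FALSE]
  use <- which(pm > 0)
  prev <- c(shape = params$frechet_shape, scale = params$frechet_scale)
  if (!length(use)) {
    warnf("no matched cells; keeping Frechet parameters")
    return(prev)
  }
  dv <- d[use]; wv <- pm[use]
  phi <- params$phi
  ln <- noise_log_density(dv, params$dof)
  obj <- function(par) {
    lc <- csp_log_density(dv, par[[1]], par[[2]])
    lm <- if (phi == 0) ln else if (phi == 1) lc else
      logaddexp(log(phi) + lc, log1p(-phi) + ln)
    v <- -sum(wv * lm)
    if (!is.finite(v)) 1e10 else v
  }
  fit <- tryCatch(
    optim(pmax(prev, c(1, 1e-8)), obj, method = "L-BFGS-B",
          lower = c(1, 1e-8), upper = c(1e3, 1e15)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > obj(prev)) {
    if (is.null(fit)) warnf("theta optimiser failed; keeping previous values")
    return(prev)
  }
  c(shape = fit$par[[1]], scale = fit$par[[2]])
}

#' Match peaks between two spectra
#'
#' Fits the full model by expectation-maximization: each iteration rebuilds
#' the candidate sets and decision order at the current parameters, samples
#' the posterior over matching matrices by SMC, and updates the CSP mixture
#' weight (Beta-MAP), the Frechet parameters (weighted MLE), and the
#' non-match level (likelihood crossing at the largest expected CSP), until
#' the largest relative parameter change drops below `control$em_tol`. A final
#' sampling pass at the converged parameters yields the reported marginals.
#'
#' @param ref,tgt Reference and target [peak_list()]s.
#' @param max_csp Largest expected combined CSP, ppm (default 0.2). Ignored if
#'   `max_csp_distance` is given.
#' @param csp_fraction Expected fraction of reference peaks undergoing a CSP
#'   (default 0.1).
#' @param variance_scale Prior standard-deviation scaling factor (default 2).
#' @param scales Per-dimension combined-CSP scale factors; resolved from the
#'   peak lists' axis nuclei when `NULL` (see [csp_scales()]).
#' @param max_csp_distance Optional direct override of Dmax (normalised
#'   squared distance), bypassing the ppm conversion.
#' @param control A [match_control()] list.
#' @param seed Optional integer seed; the whole run is deterministic given it.
#' @return A `peak_match` fit. Use [tidy()] for the per-reference match
#'   report, [glance()] for a one-row fit summary, [detect_csps()] for
#'   marginal-mass CSP detection, and [autoplot()] for diagnostics.
#' @examples
#' sim <- simulate_peak_lists(n_ref = 20, seed = 1)
#' fit <- match_peaks(sim$reference, sim$target, seed = 1)
#' glance(fit)
#' tidy(fit)
#' @export
match_peaks <- function(ref, tgt, max_csp = 0.2, csp_fraction = 0.1,
                        variance_scale = 2, scales = NULL,
                        max_csp_distance = NULL, control = match_control(),
                        seed = NULL) {
  validate_peak_pair(ref, tgt)
  if (!is.null(seed)) set.seed(seed)
  scales <- scales %||% csp_scales(peak_nuclei(ref) %||%
    stopf("peak lists carry no axis nuclei; supply `scales` explicitly"))
  d <- distance_matrix(ref, tgt)
  dmax <- max_csp_distance %||%
    max_csp_to_distance(max_csp, peak_sigmas(ref), peak_sigmas(tgt), scales)
  params <- initialize_params(d, dmax, csp_fraction, variance_scale,
                              control$init_min_distance, dof = n_dims(ref))

  n <- max(control$min_particles, nrow(d))
  history <- list()
  converged <- FALSE
  iter <- 0L
  marg <- NULL
  repeat {
    iter <- iter + 1L
    ord <- build_ordering(d, params, control$candidate_prob_ratio)
    smp <- sample_posterior(d, params, ord, control, n_particles = n)
    n <- smp$n_particles
    marg <- expectation(smp, d, params)
    phi_new <- update_phi(marg, params)
    params_new <- params
    params_new$phi <- phi_new
    theta_new <- update_theta(marg, d, params_new)
    params_new$frechet_shape <- theta_new[["shape"]]
    params_new$frechet_scale <- theta_new[["scale"]]
    params_new <- solve_omega(params_new)
    # omega enters on the log scale: it can exceed double range and its
    # relative change is then |delta log omega| to first order
    old <- c(params$frechet_shape, params$frechet_scale, params$phi,
             params$log_omega)
    new <- c(params_new$frechet_shape, params_new$frechet_scale, params_new$phi,
             params_new$log_omega)
    delta <- max(abs(new - old) / pmax(abs(old), 1e-6))
    history[[iter]] <- tibble::tibble(
      iteration = iter, frechet_shape = new[[1]], frechet_scale = new[[2]],
      phi = new[[3]], log_omega = new[[4]], delta = delta, n_particles = n)
    params <- params_new
    if (delta < control$em_tol) { converged <- TRUE; break }
    if (iter >= control$em_max_iter) break
  }
  if (!converged) warnf("EM did not converge in %d iterations", iter)

  ord <- build_ordering(d, params, control$candidate_prob_ratio)
  smp <- sample_posterior(d, params, ord, control, n_particles = n)
  marg <- expectation(smp, d, params)

  structure(list(reference = ref, target = tgt, d = d, params = params,
                 marginals = marg, ensemble = smp, ordering = ord,
                 scales = scales, param_history = dplyr::bind_rows(history),
                 converged = converged, iterations = iter, control = control),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("Peak matching fit: %d reference x %d target peaks (K = %d)\n",
              nrow(x$d), ncol(x$d), x$params$dof))
  cat(sprintf("  EM %s after %d iterations; %d sampled matchings\n",
              if (x$converged) "converged" else "NOT converged", x$iterations,
              nrow(x$ensemble$decisions)))
  print(x$params)
  invisible(x)
}
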