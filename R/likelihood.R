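#' Model parameters for the matching likelihood
#'
#' Bundles the parameters of the three-component likelihood over
#' uncertainty-normalised squared distances d:
#' a chi-squared noise component with `dof` degrees of freedom (matched peaks
#' that moved only by positional noise), a Frechet CSP component with shape
#' `frechet_shape` (>= 1) and scale `frechet_scale` (> 0) for matched peaks
#' that underwent a genuine chemical shift perturbation, mixed with weight
#' `phi`, and a constant non-match pseudo-likelihood `1/omega`. `prior_a` and
#' `prior_b` are the Beta prior pseudo-counts regularising `phi` during EM
#' (`prior_a` is the CSP-category count). `max_csp_distance` is the normalised
#' squared distance corresponding to the largest CSP the user expects; `omega`
#' is defined so that the matching and non-matching likelihoods are equal
#' there (see [solve_omega()]).
#'
#' @param frechet_shape Frechet shape alpha, >= 1 (dimensionless).
#' @param frechet_scale Frechet scale s, > 0 (normalised squared distance
#'   units).
#' @param phi Mixture weight of the CSP component, in `[0, 1]`.
#' @param omega Non-match level omega > 0; the non-match density is `1/omega`.
#'   May be `NULL` until [solve_omega()] is called.
#' @param prior_a,prior_b Beta prior parameters, each >= 1.
#' @param max_csp_distance Dmax > 0, finite.
#' @param dof Number of spectral dimensions K.
#' @return A list of class `match_params`.
#' @export
match_params <- function(frechet_shape, frechet_scale, phi, omega = NULL,
                         prior_a = 1, prior_b = 1, max_csp_distance, dof) {
  if (!is.numeric(frechet_shape) || frechet_shape < 1 || !is.finite(frechet_shape)) {
    stopf("`frechet_shape` must be finite and >= 1")
  }
  if (!is.numeric(frechet_scale) || frechet_scale <= 0 || !is.finite(frechet_scale)) {
    stopf("`frechet_scale` must be finite and > 0")
  }
  if (!is.numeric(phi) || phi < 0 || phi > 1) stopf("`phi` must be in [0, 1]")
  if (!is.null(omega) && (is.na(omega) || omega <= 0)) {
    stopf("`omega` must be > 0")
  }
  if (prior_a < 1 || prior_b < 1) stopf("Beta prior parameters must be >= 1")
  if (!is.numeric(max_csp_distance) || max_csp_distance <= 0 ||
      !is.finite(max_csp_distance)) {
    stopf("`max_csp_distance` must be finite and > 0")
  }
  if (!is_count(dof)) stopf("`dof` must be a positive integer")
  structure(list(frechet_shape = frechet_shape, frechet_scale = frechet_scale,
                 phi = phi, omega = omega,
                 log_omega = if (is.null(omega)) NULL else log(omega),
                 prior_a = prior_a, prior_b = prior_b,
                 max_csp_distance = max_csp_distance, dof = as.integer(dof)),
            class = "match_params")
}

#' @export
print.match_params <- function(x, ...) {
  cat("Matching model parameters\n")
  cat(sprintf("  Frechet shape alpha = %.6g, scale s = %.6g\n",
              x$frechet_shape, x$frechet_scale))
  cat(sprintf("  CSP mixture weight phi = %.6g\n", x$phi))
  cat(sprintf("  non-match level log(omega) = %s\n",
              if (is.null(x$log_omega)) "(unset)" else sprintf("%.6g", x$log_omega)))
  cat(sprintf("  Beta prior (a, b) = (%.4g, %.4g); Dmax = %.6g; K = %d\n",
              x$prior_a, x$prior_b, x$max_csp_distance, x$dof))
  invisible(x)
}

#' Uncertainty-normalised squared distance matrix
#'
#' For reference peak r and target peak t the normalised squared distance is
#' `D[r, t] = sum_k (delta_r[k] - delta_t[k])^2 / (sigma_r[k]^2 + sigma_t[k]^2)`
#' so that for matched peaks displaced only by positional noise D is
#' chi-squared distributed with K degrees of freedom.
#'
#' @param ref,tgt Reference and target [peak_list()]s of equal dimensionality.
#' @return An R x T numeric matrix.
#' @export
distance_matrix <- function(ref, tgt) {
  validate_peak_pair(ref, tgt)
  sr <- shift_matrix(ref); st <- shift_matrix(tgt)
  pooled <- peak_sigmas(ref)^2 + peak_sigmas(tgt)^2
  d <- matrix(0, nrow(sr), nrow(st))
  for (k in seq_len(ncol(sr))) {
    d <- d + outer(sr[, k], st[, k], "-")^2 / pooled[[k]]
  }
  d
}

#' Component log-densities of the matching model
#'
#' `noise_log_density()` is the log chi-squared PDF with `dof` degrees of
#' freedom (matched, noise only). `csp_log_density()` is the log Frechet PDF
#' `log[(alpha/s) (d/s)^(-1-alpha) exp(-(d/s)^(-alpha))]`, with density 0 at
#' d = 0 (the analytic limit). `nomatch_log_density()` is the constant
#' `log(1/omega)`. `match_log_density()` is the log of the mixture
#' `phi * csp + (1 - phi) * noise`, evaluated stably in log space.
#'
#' @param d Normalised squared distance(s), >= 0 (vectorised).
#' @param dof Degrees of freedom K >= 1.
#' @param shape,scale Frechet shape (>= 1) and scale (> 0).
#' @param params A [match_params()] object.
#' @return Log density, same length as `d`.
#' @export
noise_log_density <- function(d, dof) {
  if (any(d < 0)) stopf("domain error: d must be >= 0")
  if (!is_count(dof)) stopf("`dof` must be a positive integer")
  # identical coordinates occur with quantised ppm values; the K = 1 density
  # diverges at 0, so clamp to a representable point just above it
  if (dof == 1L) d <- pmax(d, .Machine$double.eps * 10)
  dchisq(d, df = dof, log = TRUE)
}

#' @rdname noise_log_density
#' @export
csp_log_density <- function(d, shape, scale) {
  if (any(d < 0)) stopf("domain error: d must be >= 0")
  if (!is.finite(shape) || shape < 1) stopf("domain error: `shape` must be >= 1")
  if (!is.finite(scale) || scale <= 0) stopf("domain error: `scale` must be > 0")
  out <- rep(-Inf, length(d))
  pos <- d > 0
  z <- d[pos] / scale
  out[pos] <- log(shape / scale) + (-1 - shape) * log(z) - z^(-shape)
  out
}

#' @rdname noise_log_density
#' @export
nomatch_log_density <- function(params) {
  if (is.null(params$log_omega)) stopf("omega is unset; call solve_omega() first")
  -params$log_omega
}

#' @rdname noise_log_density
#' @export
match_log_density <- function(d, params) {
  phi <- params$phi
  lc <- csp_log_density(d, params$frechet_shape, params$frechet_scale)
  ln <- noise_log_density(d, params$dof)
  if (phi == 0) return(ln)
  if (phi == 1) return(lc)
  logaddexp(log(phi) + lc, log1p(-phi) + ln)
}

#' Solve for the non-match level omega
#'
#' Sets `omega = 1 / match_density(Dmax)` so that, at the largest expected CSP
#' distance Dmax, the matching and non-matching likelihoods are exactly equal:
#' beyond Dmax a peak is more likely to have disappeared than to have moved.
#' Omega is carried in log space internally (`log_omega`), so a match density
#' below the smallest representable double is still usable; the linear `omega`
#' field is `Inf` in that regime.
#'
#' @param params A [match_params()] object with `max_csp_distance` set.
#' @return `params` with `omega`/`log_omega` updated.
#' @export
solve_omega <- function(params) {
  lm <- match_log_density(params$max_csp_distance, params)
  if (!is.finite(lm)) {
    stopf("match density is zero at Dmax = %g; choose a smaller expected maximum CSP",
          params$max_csp_distance)
  }
  params$log_omega <- -lm
  params$omega <- exp(-lm)
  params
}

#' Convert an expected maximum CSP (ppm) to a normalised squared distance
#'
#' The combined-CSP magnitude `max_csp_ppm` is split equally over the K
#' dimensions on the combined-CSP scale: the per-dimension displacement is
#' `max_csp_ppm / (scale_k * sqrt(K))` ppm, so that the combined CSP (see
#' [combined_csp()]) of the conversion displacement equals `max_csp_ppm`
#' exactly. The displacement is then normalised by the pooled per-dimension
#' variances of the two spectra.
#'
#' @param max_csp_ppm Largest expected combined CSP, ppm.
#' @param sigmas_ref,sigmas_tgt Per-dimension uncertainties of the two spectra
#'   (ppm).
#' @param scales Per-dimension combined-CSP scale factors (1 for 1H, 0.101 for
#'   15N, 0.252 for 13C); see [csp_scales()].
#' @return Dmax, the normalised squared distance of that displacement.
#' @export
max_csp_to_distance <- function(max_csp_ppm, sigmas_ref, sigmas_tgt, scales) {
  k <- length(sigmas_ref)
  if (length(sigmas_tgt) != k || length(scales) != k) {
    stopf("dimension error: sigmas and scales must share length K")
  }
  if (max_csp_ppm <= 0) stopf("`max_csp_ppm` must be > 0")
  delta <- max_csp_ppm / (scales * sqrt(k))
  sum(delta^2 / (sigmas_ref^2 + sigmas_tgt^2))
}
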