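#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a peak-match fit into the per-reference match report
#'
#' @param x A `peak_match` from [match_peaks()].
#' @param cutoff,csp_cutoff_ppm See [best_matches()].
#' @param ... Unused.
#' @return The [best_matches()] report tibble.
#' @method tidy peak_match
#' @export
tidy.peak_match <- function(x, cutoff = 0.95, csp_cutoff_ppm = 0.01, ...) {
  best_matches(x, cutoff = cutoff, csp_cutoff_ppm = csp_cutoff_ppm)
}

#' One-row summary of a peak-match fit
#'
#' @param x A `peak_match` from [match_peaks()].
#' @param ... Unused.
#' @return A one-row tibble with peak counts, EM iterations and convergence,
#'   the fitted parameters, and the sampler's final particle count.
#' @method glance peak_match
#' @export
glance.peak_match <- function(x, ...) {
  tibble::tibble(n_ref = nrow(x$d), n_tgt = ncol(x$d), dof = x$params$dof,
                 iterations = x$iterations, converged = x$converged,
                 phi = x$params$phi,
                 frechet_shape = x$params$frechet_shape,
                 frechet_scale = x$params$frechet_scale,
                 omega = x$params$omega,
                 log_omega = x$params$log_omega,
                 n_particles = x$ensemble$n_particles,
                 n_sampled = nrow(x$ensemble$decisions))
}
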