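#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_point
#'   geom_vline labs scale_x_log10 scale_y_log10 after_stat
NULL

#' @export
ggplot2::autoplot

#' Diagnostic plot of a peak-match fit
#'
#' Histogram of all pairwise normalised squared distances split into matched
#' (marginal match probability of the pair > 0.5) and unmatched, overlaid with
#' the fitted chi-squared noise, Frechet CSP and uniform non-match components,
#' on log-log axes.
#'
#' @param object A `peak_match` fit.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_match
#' @export
autoplot.peak_match <- function(object, bins = 60, ...) {
  d <- object$d
  tn <- ncol(d)
  p <- object$marginals$p_match[, seq_len(tn), drop = FALSE]
  df <- tibble::tibble(distance = as.vector(d),
                       status = ifelse(as.vector(p) > 0.5, "matched", "unmatched"))
  df <- df[df$distance > 0, ]
  pars <- object$params
  xs <- exp(seq(log(max(min(df$distance), 1e-6)), log(max(df$distance)),
                length.out = 400))
  dens <- dplyr::bind_rows(
    tibble::tibble(x = xs, y = exp(noise_log_density(xs, pars$dof)),
                   component = "noise (chi-squared)"),
    tibble::tibble(x = xs, y = exp(csp_log_density(xs, pars$frechet_shape,
                                                   pars$frechet_scale)),
                   component = "CSP (Frechet)"),
    tibble::tibble(x = xs, y = exp(match_log_density(xs, pars)),
                   component = "matched mixture"),
    tibble::tibble(x = xs, y = rep(1 / pars$omega, length(xs)),
                   component = "non-match"))
  dens <- dens[dens$y > 0, ]
  ggplot(df, aes(x = .data$distance)) +
    geom_histogram(aes(y = after_stat(density), fill = .data$status),
                   bins = bins, alpha = 0.5, position = "identity") +
    geom_line(data = dens, aes(x = .data$x, y = .data$y,
                               colour = .data$component)) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "normalised squared distance", y = "density",
         title = "Distance distribution and fitted likelihood components")
}

#' Accuracy/completeness plot of a match evaluation
#'
#' Per-bin accuracy plus cumulative accuracy and completeness as functions of
#' the posterior-probability cutoff, with a reference line at 0.95.
#'
#' @param object A `match_evaluation` from [evaluate_matches()].
#' @param cutoff Cutoff indicator line (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_evaluation
#' @export
autoplot.match_evaluation <- function(object, cutoff = 0.95, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("bin_low", "accuracy", "cum_accuracy",
                                  "cum_completeness")],
    cols = -"bin_low", names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot(long, aes(x = .data$bin_low, y = .data$value,
                   colour = .data$metric, shape = .data$metric)) +
    geom_point() + geom_line() +
    geom_vline(xintercept = cutoff, linetype = "dotted") +
    labs(x = "posterior probability (bin lower edge)", y = NULL,
         title = "Match accuracy and completeness vs posterior probability")
}

#' @importFrom rlang .data
NULL
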