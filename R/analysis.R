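#' Combined-CSP scale factors from axis nuclei
#'
#' Maps nucleus labels to the conventional per-dimension weights used when
#' collapsing a multidimensional shift difference into a single combined CSP:
#' 1 for 1H, 0.101 for 15N, 0.252 for 13C. Labels may carry mass numbers
#' ("15N", "13C"); unknown nuclei raise an error (supply explicit scales).
#'
#' @param nuclei Character vector of axis nucleus labels.
#' @return Numeric vector of scale factors.
#' @export
csp_scales <- function(nuclei) {
  known <- c(H = 1.0, N = 0.101, C = 0.252)
  el <- toupper(gsub("[^A-Za-z]", "", nuclei))
  el <- substr(el, nchar(el), nchar(el))  # "HN" axis label means the H of N-H
  bad <- !(el %in% names(known))
  if (any(bad)) {
    stopf("unknown nucleus label(s): %s; supply `scales` explicitly",
          paste(nuclei[bad], collapse = ", "))
  }
  unname(known[el])
}

#' Combined chemical shift perturbation (ppm)
#'
#' The per-dimension shift differences are scaled (1 for 1H, 0.101 for 15N,
#' 0.252 for 13C by default) and combined as a Euclidean distance:
#' `sqrt(sum_k (scale_k * (delta_ref_k - delta_tgt_k))^2)`.
#'
#' @param ref,tgt [peak_list()]s of equal dimensionality.
#' @param scales Per-dimension scale factors; resolved from the reference
#'   list's axis nuclei when `NULL`.
#' @return An R x T matrix of combined CSPs in ppm.
#' @export
combined_csp <- function(ref, tgt, scales = NULL) {
  validate_peak_pair(ref, tgt)
  scales <- scales %||% csp_scales(peak_nuclei(ref) %||%
    stopf("peak lists carry no axis nuclei; supply `scales` explicitly"))
  if (length(scales) != n_dims(ref)) {
    stopf("dimension error: `scales` must have length K = %d", n_dims(ref))
  }
  sr <- shift_matrix(ref); st <- shift_matrix(tgt)
  out <- matrix(0, nrow(sr), nrow(st))
  for (k in seq_len(ncol(sr))) {
    out <- out + (scales[[k]] * outer(sr[, k], st[, k], "-"))^2
  }
  sqrt(out)
}

# probability-weighted mean and population SD of combined CSPs over targets,
# weights renormalised over the row's non-NO_MATCH mass
csp_estimate_row <- function(p_row_targets, csp_row) {
  tot <- sum(p_row_targets)
  if (tot <= 0) return(c(mean = NA_real_, sd = NA_real_))
  w <- p_row_targets / tot
  mu <- sum(w * csp_row)
  c(mean = mu, sd = sqrt(max(sum(w * (csp_row - mu)^2), 0)))
}

#' Best matches and match report
#'
#' For every reference peak, reports the highest-marginal-probability decision
#' (a target or no match, ties resolved toward the lower target index and
#' flagged), its posterior probability, the combined CSP to the best target,
#' the marginal posterior mass on significant-CSP targets, and the
#' probability-weighted CSP estimate (mean and population SD over targets).
#' Rows whose best probability falls below `cutoff` are flagged, not removed.
#'
#' @param fit A `peak_match` from [match_peaks()].
#' @param cutoff Posterior probability cutoff used for flagging (default 0.95).
#' @param csp_cutoff_ppm Combined-CSP significance cutoff (default 0.01 ppm).
#' @return A tibble with one row per reference peak: `reference_id`,
#'   `reference_label`, `target_id` (`NA` = no match), `target_label`,
#'   `posterior_probability`, `csp_ppm`, `csp_posterior_mass`,
#'   `csp_estimate_mean`, `csp_estimate_sd`, `below_cutoff`, `tie`.
#' @export
best_matches <- function(fit, cutoff = 0.95, csp_cutoff_ppm = 0.01) {
  pm <- fit$marginals$p_match
  tn <- ncol(pm) - 1L
  csp <- combined_csp(fit$reference, fit$target, fit$scales)
  rows <- lapply(seq_len(nrow(pm)), function(r) {
    p <- pm[r, ]
    best <- which(p == max(p))
    tie <- length(best) > 1L
    best <- best[[1L]]
    is_match <- best <= tn
    target_mass <- p[seq_len(tn)]
    sig_mass <- sum(target_mass[csp[r, ] > csp_cutoff_ppm])
    est <- csp_estimate_row(target_mass, csp[r, ])
    tibble::tibble(
      reference_id = fit$reference$peak_id[[r]],
      reference_label = fit$reference$label[[r]],
      target_id = if (is_match) fit$target$peak_id[[best]] else NA_integer_,
      target_label = if (is_match) fit$target$label[[best]] else NA_character_,
      posterior_probability = p[[best]],
      csp_ppm = if (is_match) csp[r, best] else NA_real_,
      csp_posterior_mass = sig_mass,
      csp_estimate_mean = est[["mean"]],
      csp_estimate_sd = est[["sd"]],
      below_cutoff = p[[best]] < cutoff,
      tie = tie)
  })
  dplyr::bind_rows(rows)
}

#' Marginal-mass CSP detection
#'
#' A reference peak is called perturbed when at least `mass_cutoff` of its
#' marginal match-probability mass lies on targets whose combined CSP exceeds
#' `csp_cutoff_ppm` -- the peak then moved significantly even if *which*
#' target it moved to is ambiguous. The no-match mass never counts toward
#' detection. For comparison the single-best-match detector is also reported:
#' best decision is a significant-CSP target with posterior >= `mass_cutoff`.
#'
#' @inheritParams best_matches
#' @param mass_cutoff Posterior mass required to call a CSP (default 0.95).
#' @return A tibble with `reference_id`, `csp_posterior_mass`, `detected`
#'   (mass rule), `best_target_id`, `best_probability`, `best_csp_ppm`, and
#'   `detected_best` (single-best rule).
#' @export
detect_csps <- function(fit, csp_cutoff_ppm = 0.01, mass_cutoff = 0.95) {
  rep <- best_matches(fit, cutoff = mass_cutoff, csp_cutoff_ppm = csp_cutoff_ppm)
  tibble::tibble(
    reference_id = rep$reference_id,
    csp_posterior_mass = rep$csp_posterior_mass,
    detected = rep$csp_posterior_mass >= mass_cutoff,
    best_target_id = rep$target_id,
    best_probability = rep$posterior_probability,
    best_csp_ppm = rep$csp_ppm,
    detected_best = !is.na(rep$target_id) &
      rep$posterior_probability >= mass_cutoff &
      !is.na(rep$csp_ppm) & rep$csp_ppm > csp_cutoff_ppm)
}

#' Evaluate matches against ground truth
#'
#' Bins the per-reference best matches by posterior probability and reports,
#' per bin, the accuracy of made matches (correct/total, `NA` for empty bins)
#' and, cumulatively at each bin's lower edge, the accuracy and the
#' completeness (correct matches at or above the cutoff divided by the total
#' number of true matches).
#'
#' @param report A match report from [best_matches()]/[tidy()].
#' @param truth Ground-truth tibble with columns `reference_id` and
#'   `target_id` (`NA` = truly unmatched), e.g. from [simulate_peak_lists()].
#' @param bins Numeric vector of bin edges over `[0, 1]`.
#' @return A `match_evaluation` tibble: `bin_low`, `bin_high`, `n`,
#'   `accuracy`, `cum_accuracy`, `cum_completeness`.
#' @export
evaluate_matches <- function(report, truth, bins = seq(0, 1, by = 0.05)) {
  if (!all(report$reference_id %in% truth$reference_id)) {
    stopf("truth/reference mismatch: truth must cover all reference peaks")
  }
  tt <- truth$target_id[match(report$reference_id, truth$reference_id)]
  made <- !is.na(report$target_id)
  correct <- made & !is.na(tt) & report$target_id == tt
  p <- report$posterior_probability
  n_true <- sum(!is.na(tt))
  bins <- round(bins, 10)  # snap seq() float error so edges compare exactly
  lo <- bins[-length(bins)]; hi <- bins[-1]
  idx <- pmin(findInterval(p, bins, rightmost.closed = TRUE), length(lo))
  per_bin <- function(b) {
    inb <- made & idx == b
    if (!any(inb)) return(c(n = 0, acc = NA_real_))
    c(n = sum(inb), acc = sum(correct[inb]) / sum(inb))
  }
  stats <- vapply(seq_along(lo), per_bin, numeric(2))
  cum <- vapply(lo, function(cut) {
    sel <- made & p >= cut
    c(acc = if (any(sel)) sum(correct[sel]) / sum(sel) else NA_real_,
      comp = if (n_true) sum(correct[sel]) / n_true else NA_real_)
  }, numeric(2))
  out <- tibble::tibble(bin_low = lo, bin_high = hi,
                        n = as.integer(stats["n", ]),
                        accuracy = stats["acc", ],
                        cum_accuracy = cum["acc", ],
                        cum_completeness = cum["comp", ])
  class(out) <- c("match_evaluation", class(out))
  out
}

#' Found and missed true matches binned by CSP magnitude
#'
#' For every truly matched reference peak, classifies the match as found or
#' missed at the given posterior cutoff -- under the single-best rule
#' (`mode = "best"`: the algorithm made the correct match with posterior >=
#' cutoff) or the marginal-mass rule (`mode = "mass"`: at least `cutoff` of
#' the marginal mass lies on significant-CSP targets) -- and tabulates the
#' counts over bins of the true combined CSP.
#'
#' @inheritParams evaluate_matches
#' @param truth Ground-truth tibble with `reference_id`, `target_id`, and
#'   `true_csp_ppm`.
#' @param mode `"best"` or `"mass"`.
#' @param cutoff Posterior (or mass) cutoff, default 0.95.
#' @param bins True-CSP bin edges in ppm (log-spaced default).
#' @return A tibble `bin_low`, `bin_high`, `n_true`, `found`, `missed`.
#' @export
evaluate_csp_bins <- function(report, truth, mode = c("best", "mass"),
                              cutoff = 0.95,
                              bins = c(0, 10^seq(-3, 0, length.out = 13))) {
  mode <- match.arg(mode)
  if (!all(report$reference_id %in% truth$reference_id)) {
    stopf("truth/reference mismatch: truth must cover all reference peaks")
  }
  tr <- truth[match(report$reference_id, truth$reference_id), ]
  keep <- !is.na(tr$target_id)
  rep_m <- report[keep, ]; tr_m <- tr[keep, ]
  correct <- !is.na(rep_m$target_id) & rep_m$target_id == tr_m$target_id
  found <- switch(mode,
    best = correct & rep_m$posterior_probability >= cutoff,
    mass = rep_m$csp_posterior_mass >= cutoff)
  idx <- pmin(findInterval(tr_m$true_csp_ppm, bins, rightmost.closed = TRUE),
              length(bins) - 1L)
  lo <- bins[-length(bins)]; hi <- bins[-1]
  n_found <- vapply(seq_along(lo), function(b) sum(found & idx == b), integer(1))
  n_missed <- vapply(seq_along(lo), function(b) sum(!found & idx == b), integer(1))
  tibble::tibble(
    bin_low = lo, bin_high = hi,
    n_true = vapply(seq_along(lo), function(b) sum(idx == b), integer(1)),
    found = n_found, missed = n_missed)
}
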