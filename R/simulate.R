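#' Simulate a reference/target peak-list pair with known ground truth
#'
#' Generates data under the matching model's own assumptions. Reference peaks
#' are placed uniformly over the shift ranges, subject to a minimum pairwise
#' spacing (`min_spacing`, in normalised distance units, i.e. sqrt of the
#' normalised squared distance) enforced by rejection. The target list starts
#' as a copy jittered per dimension with Gaussian noise of standard deviation
#' `sqrt(sigmas_ref^2 + sigmas_tgt^2)`, so the normalised squared distance of
#' a noise-only matched pair is exactly chi-squared with K degrees of freedom.
#' A `csp_fraction` subset of the surviving matches is additionally displaced
#' in a uniformly random direction so that the added normalised squared
#' distance follows a Frechet law with the given shape and scale. A
#' `drop_fraction` of reference peaks lose their target (truth records no
#' match) and `spurious_fraction * n_ref` unmatched clutter peaks are added to
#' the target; target order is shuffled.
#'
#' @param n_ref Number of reference peaks.
#' @param shift_ranges Named list of per-dimension ppm ranges.
#' @param sigmas_ref,sigmas_tgt Per-dimension uncertainties (ppm).
#' @param nuclei Axis nucleus labels.
#' @param csp_fraction Fraction of matched peaks carrying a CSP.
#' @param csp_shape,csp_scale Frechet shape/scale of the added normalised
#'   squared CSP distance.
#' @param drop_fraction Fraction of reference peaks absent from the target.
#' @param spurious_fraction Extra target peaks, as a fraction of `n_ref`.
#' @param min_spacing Minimum pairwise normalised distance between reference
#'   peaks (0 disables the crowding control).
#' @param seed Optional integer seed.
#' @return A list with `reference` and `target` ([peak_list()]s) and `truth`,
#'   a tibble with `reference_id`, `target_id` (`NA` = no match), `csp_flag`,
#'   and `true_csp_ppm` (combined CSP between the realised positions; `NA`
#'   for unmatched references).
#' @examples
#' sim <- simulate_peak_lists(n_ref = 30, seed = 42)
#' table(is.na(sim$truth$target_id))
#' @export
simulate_peak_lists <- function(n_ref = 200,
                                shift_ranges = list(H = c(6.5, 10.5),
                                                    N = c(100, 135)),
                                sigmas_ref = c(0.0015, 0.015),
                                sigmas_tgt = sigmas_ref,
                                nuclei = names(shift_ranges),
                                csp_fraction = 0.1,
                                csp_shape = 1.5, csp_scale = 8,
                                drop_fraction = 0.05,
                                spurious_fraction = 0.05,
                                min_spacing = 5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(shift_ranges)
  if (length(sigmas_ref) != k || length(sigmas_tgt) != k) {
    stopf("dimension error: sigmas must match the number of shift ranges")
  }
  for (f in c(csp_fraction, drop_fraction, spurious_fraction)) {
    if (f < 0 || f >= 1) stopf("fractions must be in [0, 1)")
  }
  pooled_sd <- sqrt(sigmas_ref^2 + sigmas_tgt^2)
  lo <- vapply(shift_ranges, min, numeric(1))
  hi <- vapply(shift_ranges, max, numeric(1))

  draw_uniform <- function(n) {
    vapply(seq_len(k), function(j) runif(n, lo[[j]], hi[[j]]), numeric(n))
  }
  # Poisson-disk style rejection in normalised coordinates
  ref <- matrix(NA_real_, n_ref, k)
  placed <- 0L
  attempts <- 0L
  while (placed < n_ref) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_ref) {
      stopf("cannot place %d reference peaks at min_spacing = %g in the given ranges",
            n_ref, min_spacing)
    }
    cand <- draw_uniform(1L)
    if (placed > 0L && min_spacing > 0) {
      dn <- sweep(ref[seq_len(placed), , drop = FALSE], 2, cand)
      d2 <- rowSums(sweep(dn, 2, pooled_sd, "/")^2)
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    ref[placed, ] <- cand
  }

  tgt <- ref + matrix(rnorm(n_ref * k), n_ref, k) %*% diag(pooled_sd, k)

  n_drop <- round(drop_fraction * n_ref)
  dropped <- if (n_drop > 0) sample(n_ref, n_drop) else integer(0)
  matched <- setdiff(seq_len(n_ref), dropped)

  n_csp <- round(csp_fraction * length(matched))
  csp_refs <- if (n_csp > 0) sample(matched, n_csp) else integer(0)
  if (length(csp_refs)) {
    # Frechet via inverse CDF: d = scale * (-log U)^(-1/shape)
    dstar <- csp_scale * (-log(runif(length(csp_refs))))^(-1 / csp_shape)
    dir <- matrix(rnorm(length(csp_refs) * k), ncol = k)
    dir <- dir / sqrt(rowSums(dir^2))
    disp <- dir * sqrt(dstar)                        # normalised coordinates
    tgt[csp_refs, ] <- tgt[csp_refs, ] +
      disp %*% diag(pooled_sd, k)                    # back to ppm
  }

  n_spur <- round(spurious_fraction * n_ref)
  tgt_all <- rbind(tgt[matched, , drop = FALSE],
                   if (n_spur > 0) draw_uniform(n_spur))
  perm <- sample(nrow(tgt_all))
  tgt_all <- tgt_all[perm, , drop = FALSE]
  # position of matched reference i's target after the shuffle
  tgt_of_ref <- rep(NA_integer_, n_ref)
  tgt_of_ref[matched] <- match(seq_along(matched), perm)

  ref_pl <- peak_list(as.data.frame(ref) |> setNames(names(shift_ranges)),
                      sigmas = sigmas_ref, nuclei = nuclei,
                      labels = sprintf("R%d", seq_len(n_ref)),
                      spectrum_id = "simulated_reference")
  tgt_pl <- peak_list(as.data.frame(tgt_all) |> setNames(names(shift_ranges)),
                      sigmas = sigmas_tgt, nuclei = nuclei,
                      labels = sprintf("T%d", seq_len(nrow(tgt_all))),
                      spectrum_id = "simulated_target")

  scales <- tryCatch(csp_scales(nuclei), error = function(e) rep(1, k))
  true_csp <- rep(NA_real_, n_ref)
  m <- !is.na(tgt_of_ref)
  if (any(m)) {
    dppm <- ref[m, , drop = FALSE] - tgt_all[tgt_of_ref[m], , drop = FALSE]
    true_csp[m] <- sqrt(rowSums(sweep(dppm, 2, scales, "*")^2))
  }
  truth <- tibble::tibble(reference_id = seq_len(n_ref),
                          target_id = tgt_of_ref,
                          csp_flag = seq_len(n_ref) %in% csp_refs,
                          true_csp_ppm = true_csp)
  list(reference = ref_pl, target = tgt_pl, truth = truth)
}

#' Simulate a benchmark suite
#'
#' One [simulate_peak_lists()] call per seed, deterministic per seed.
#'
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [simulate_peak_lists()].
#' @return A list of simulation triples, one per seed.
#' @export
simulate_benchmark <- function(seeds, ...) {
  if (!length(seeds)) stopf("`seeds` must be non-empty")
  lapply(seeds, function(s) simulate_peak_lists(..., seed = s))
}
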