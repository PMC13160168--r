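# minimal hand-built fit object for analysis-level tests
fake_fit <- function(p_match, ref, tgt, phi = 0.1) {
  params <- solve_omega(match_params(frechet_shape = 1.5, frechet_scale = 5,
                                     phi = phi, max_csp_distance = 100,
                                     dof = n_dims(ref)))
  structure(list(reference = ref, target = tgt,
                 d = distance_matrix(ref, tgt), params = params,
                 marginals = structure(list(
                   p_match = p_match,
                   p_csp = matrix(0, nrow(p_match), ncol(p_match) - 1L)),
                   class = "match_marginals"),
                 scales = csp_scales(peak_nuclei(ref))),
            class = "peak_match")
}

test_that("combined CSP uses the nitrogen and carbon scaling conventions", {
  ref <- make_list(rbind(c(8.00, 120.0)))
  tgt <- make_list(rbind(c(8.01, 120.1)))
  # hand value with the 0.101 nitrogen factor
  expect_equal(combined_csp(ref, tgt)[1, 1],
               sqrt(1e-4 + (0.101 * 0.1)^2), tolerance = 1e-9)
  expect_equal(combined_csp(ref, ref)[1, 1], 0)
  expect_equal(csp_scales(c("H", "N", "C")), c(1, 0.101, 0.252))
  expect_equal(csp_scales(c("1H", "15N", "13C")), c(1, 0.101, 0.252))
  expect_error(csp_scales(c("H", "P")), "unknown nucleus")
})

test_that("best matches report argmax decisions with tie and cutoff flags", {
  ref <- make_list(rbind(c(8.0, 120), c(8.5, 115), c(9.0, 110)))
  tgt <- make_list(rbind(c(8.0, 120), c(8.5, 115)))
  pm <- rbind(c(0.97, 0.02, 0.01),
              c(0.005, 0.005, 0.99),
              c(0.45, 0.45, 0.10))
  fit <- fake_fit(pm, ref, tgt)
  rep <- best_matches(fit)
  expect_equal(rep$target_id, c(1L, NA, 1L))
  expect_equal(rep$posterior_probability, c(0.97, 0.99, 0.45))
  expect_true(is.na(rep$csp_ppm[2]))
  expect_equal(rep$below_cutoff, c(FALSE, FALSE, TRUE))
  expect_equal(rep$tie, c(FALSE, FALSE, TRUE))
})

test_that("csp posterior mass, detection rules and weighted estimates behave", {
  ref <- make_list(rbind(c(8.0, 120)))
  # two targets with significant CSPs (0.02 and 0.04 ppm in H), one at noise
  tgt <- make_list(rbind(c(8.02, 120), c(8.04, 120), c(8.0001, 120)))
  # mass split over the two significant targets: detected by mass, not best
  fit <- fake_fit(rbind(c(0.5, 0.5, 0.0, 0.0)), ref, tgt)
  det <- detect_csps(fit)
  expect_equal(det$csp_posterior_mass, 1.0)
  expect_true(det$detected)
  expect_false(det$detected_best)
  rep <- best_matches(fit)
  expect_equal(rep$csp_estimate_mean, 0.03, tolerance = 1e-9)
  expect_equal(rep$csp_estimate_sd, 0.01, tolerance = 1e-9)  # population SD

  # all mass on the sub-cutoff target: nothing detected
  fit2 <- fake_fit(rbind(c(0, 0, 1, 0)), ref, tgt)
  det2 <- detect_csps(fit2)
  expect_equal(det2$csp_posterior_mass, 0)
  expect_false(det2$detected)

  # all mass on NO_MATCH: empty CSP estimate
  fit3 <- fake_fit(rbind(c(0, 0, 0, 1)), ref, tgt)
  rep3 <- best_matches(fit3)
  expect_true(is.na(rep3$csp_estimate_mean))
  # mass never counts the no-match column
  expect_equal(rep3$csp_posterior_mass, 0)
})

test_that("mass detection is a superset of best-match detection", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 12
    pm <- matrix(runif(n * 6), n, 6)
    pm <- pm / rowSums(pm)
    ref <- make_list(cbind(runif(n, 7, 9), runif(n, 105, 130)))
    tgt <- make_list(cbind(runif(5, 7, 9), runif(5, 105, 130)))
    det <- detect_csps(fake_fit(pm, ref, tgt))
    expect_true(all(!det$detected_best | det$detected))
    expect_true(all(det$csp_posterior_mass <= 1 - pm[, 6] + 1e-9))
  }
})

test_that("evaluation bins accuracy and accumulates completeness correctly", {
  report <- tibble::tibble(
    reference_id = 1:12,
    target_id = c(1:8, 9L, 10L, NA, NA),
    posterior_probability = c(rep(0.98, 8), 0.97, 0.99, 0.9, 0.3),
    csp_posterior_mass = 0)
  truth <- tibble::tibble(reference_id = 1:12,
                          target_id = c(1:8, 21L, 22L, 11L, NA))
  ev <- evaluate_matches(report, truth, bins = seq(0, 1, 0.05))
  top <- ev[ev$bin_low == 0.95, ]
  # 10 matches made at >= 0.95, 8 correct -> accuracy 0.8
  expect_equal(top$n, 10L)
  expect_equal(top$accuracy, 0.8)
  expect_equal(top$cum_accuracy, 0.8)
  # 11 true matches, 8 found above the cutoff
  expect_equal(top$cum_completeness, 8 / 11)
  # cumulative completeness is non-increasing in the cutoff
  cc <- ev$cum_completeness[!is.na(ev$cum_completeness)]
  expect_true(all(diff(cc) <= 1e-12))
  # empty bins carry NA accuracy
  expect_true(is.na(ev$accuracy[ev$bin_low == 0.5]))
  expect_error(evaluate_matches(report, truth[1:5, ], ), "mismatch")
})

test_that("perfect reports give unit accuracy and completeness", {
  report <- tibble::tibble(reference_id = 1:5, target_id = 1:5,
                           posterior_probability = rep(1, 5),
                           csp_posterior_mass = 1)
  truth <- tibble::tibble(reference_id = 1:5, target_id = 1:5,
                          true_csp_ppm = c(0.02, 0.03, 0.001, 0.05, 0.2))
  ev <- evaluate_matches(report, truth)
  expect_equal(ev$cum_accuracy[ev$bin_low == 0.95], 1)
  expect_equal(ev$cum_completeness[ev$bin_low == 0.95], 1)
  bins <- evaluate_csp_bins(report, truth, mode = "best")
  expect_equal(sum(bins$found), 5L)
  expect_equal(sum(bins$missed), 0L)
  binm <- evaluate_csp_bins(report, truth, mode = "mass")
  expect_equal(sum(binm$found), 5L)
})
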