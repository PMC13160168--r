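test_that("the Beta prior construction hits the requested mean with pseudo-counts >= 1", {
  # csp_fraction 0.1, variance scale 2: target sd 0.4 is infeasible for a
  # Beta with mean 0.1, so the pseudo-counts floor at min(a, b) = 1 while the
  # mean is preserved
  pr <- shiftmatch:::beta_prior(0.1, 2)
  expect_equal(unname(pr["a"] / sum(pr)), 0.1, tolerance = 1e-12)
  expect_equal(unname(pr["a"]), 1)
  expect_equal(unname(pr["b"]), 9)
  # a feasible small-variance case solves the moment equations exactly
  pr2 <- shiftmatch:::beta_prior(0.3, 0.1)
  m <- pr2["a"] / sum(pr2)
  v <- prod(pr2) / (sum(pr2)^2 * (sum(pr2) + 1))
  expect_equal(unname(m), 0.3, tolerance = 1e-10)
  expect_equal(unname(sqrt(v)), 2 * 0.3 * 0.1, tolerance = 1e-8)
  expect_true(all(pr2 >= 1))
})

test_that("initialisation recovers Frechet row-minimum structure and falls back", {
  set.seed(21)
  # synthetic row minima: Frechet(2, 8) body plus sub-threshold noise values
  n <- 200
  fre <- 8 * (-log(runif(n)))^(-1 / 2)
  noise <- rchisq(50, df = 2)
  d <- matrix(c(fre, noise), ncol = 1)  # row minima equal the values
  p <- suppressWarnings(initialize_params(d, max_csp_distance = 5000,
                                          csp_fraction = 0.1,
                                          variance_scale = 2, dof = 2L))
  expect_gt(p$frechet_shape, 2 * 0.8)
  expect_lt(p$frechet_shape, 2 * 1.2)
  expect_gt(p$frechet_scale, 8 * 0.8)
  expect_lt(p$frechet_scale, 8 * 1.2)
  expect_equal(p$phi, 0.1)
  # omega defining property holds immediately after initialisation
  expect_lt(abs(match_log_density(5000, p) + p$log_omega), 1e-12)

  # all minima below the filter: fallback with a warning
  d0 <- matrix(runif(20, 0, 2), ncol = 1)
  expect_warning(p0 <- initialize_params(d0, 100, 0.1, 2, dof = 2L),
                 "falling back")
  expect_equal(p0$frechet_shape, 1.5)
})

test_that("expectation turns ensembles into frequencies and responsibilities", {
  p <- solve_omega(match_params(frechet_shape = 1.5, frechet_scale = 5,
                                phi = 0.3, max_csp_distance = 60, dof = 2L))
  d <- matrix(c(2, 30, 45, 1), 2, 2)
  ens <- structure(list(
    decisions = rbind(c(1L, 2L), c(1L, 2L), c(1L, 3L), c(3L, 2L)),
    log_weights = rep(log(0.25), 4),
    p_match = shiftmatch:::decision_freqs(
      rbind(c(1L, 2L), c(1L, 2L), c(1L, 3L), c(3L, 2L)),
      rep(log(0.25), 4), 2L)), class = "match_ensemble")
  m <- expectation(ens, d, p)
  expect_equal(m$p_match[1, 1], 0.75)
  expect_equal(m$p_match[1, 3], 0.25)
  expect_equal(dim(m$p_csp), c(2L, 2L))
  # responsibility formula: phi * csp / match, 0.5 at the balance point
  bal <- uniroot(function(x) log(0.3) + csp_log_density(x, 1.5, 5) -
                   (log(0.7) + noise_log_density(x, 2L)), c(0.1, 50))$root
  mb <- expectation(ens, matrix(bal, 2, 2), p)
  expect_equal(mb$p_csp[1, 1], 0.5, tolerance = 1e-4)
  # phi = 0 collapses all responsibilities to zero
  p0 <- solve_omega(match_params(frechet_shape = 1.5, frechet_scale = 5,
                                 phi = 0, max_csp_distance = 60, dof = 2L))
  expect_true(all(expectation(ens, d, p0)$p_csp == 0))
})

test_that("phi update is the regularised MAP with safe degenerate behaviour", {
  p <- solve_omega(match_params(frechet_shape = 1.5, frechet_scale = 5,
                                phi = 0.4, prior_a = 1, prior_b = 1,
                                max_csp_distance = 60, dof = 2L))
  # uniform prior a = b = 1, sums 3 and 10: phi = 0.3 by hand
  marg <- list(p_match = cbind(matrix(0, 2, 2), c(0, 0)), p_csp = matrix(0, 2, 2))
  marg$p_match[1:2, 1:2] <- matrix(c(4, 2, 3, 1), 2) / 1  # sums to 10
  marg$p_csp[1:2, 1:2] <- 3 / 10 * matrix(c(1, 1, 1, 1), 2) *
    matrix(c(4, 2, 3, 1), 2) / matrix(c(4, 2, 3, 1), 2)
  marg$p_csp <- matrix(0.3, 2, 2)  # so sum(p_csp * p_match) = 3
  phi <- update_phi(marg, p)
  expect_equal(phi, 0.3, tolerance = 1e-12)
  # no matches: keep previous value with a warning
  empty <- list(p_match = cbind(matrix(0, 2, 2), c(1, 1)),
                p_csp = matrix(0, 2, 2))
  expect_warning(phi2 <- update_phi(empty, p), "keeping phi")
  expect_equal(phi2, 0.4)
  # dominating prior pins the update at the prior mean
  pbig <- p; pbig$prior_a <- 1000; pbig$prior_b <- 9000
  expect_equal(update_phi(marg, pbig), 0.1, tolerance = 2e-3)
})

test_that("theta update recovers simulated Frechet distances and never regresses", {
  set.seed(33)
  n <- 300
  dcsp <- 8 * (-log(runif(n)))^(-1 / 1.5)
  d <- matrix(dcsp, ncol = 1)
  p <- solve_omega(match_params(frechet_shape = 1.2, frechet_scale = 4,
                                phi = 1, max_csp_distance = 5000, dof = 2L))
  marg <- list(p_match = cbind(matrix(1, n, 1), 0), p_csp = matrix(1, n, 1))
  th <- update_theta(marg, d, p)
  expect_lt(abs(th[["shape"]] - 1.5) / 1.5, 0.1)
  expect_lt(abs(th[["scale"]] - 8) / 8, 0.1)
  # monotone improvement of the weighted objective
  obj <- function(sh, sc) {
    sum(log(1) + csp_log_density(dcsp, sh, sc))
  }
  expect_gte(obj(th[["shape"]], th[["scale"]]), obj(1.2, 4))
  # a single matched cell stays within bounds without crashing
  p1 <- p; marg1 <- list(p_match = cbind(matrix(1, 1, 1), 0),
                         p_csp = matrix(1, 1, 1))
  th1 <- update_theta(marg1, matrix(7, 1, 1), p1)
  expect_gte(th1[["shape"]], 1)
  expect_gt(th1[["scale"]], 0)
})

test_that("an unambiguous pair matches with probability ~1 and runs are reproducible", {
  ref <- make_list(rbind(c(8.0, 120), c(9.5, 110)))
  tgt <- make_list(rbind(c(8.0005, 120.004), c(9.5004, 109.996)))
  fit <- suppressWarnings(match_peaks(ref, tgt, max_csp = 0.05, seed = 5))
  rep <- tidy(fit)
  expect_equal(rep$target_id, 1:2)
  expect_true(all(rep$posterior_probability > 0.99))
  fit2 <- suppressWarnings(match_peaks(ref, tgt, max_csp = 0.05, seed = 5))
  expect_identical(fit$param_history, fit2$param_history)
  expect_identical(fit$ensemble$decisions, fit2$ensemble$decisions)
  g <- glance(fit)
  expect_true(g$phi >= 0 && g$phi <= 1)
  expect_gte(g$frechet_shape, 1)
  expect_lt(abs(match_log_density(fit$params$max_csp_distance, fit$params) +
                  fit$params$log_omega), 1e-12)
})

test_that("EM keeps every parameter inside its admissible range", {
  sim <- simulate_peak_lists(n_ref = 40, seed = 13)
  fit <- suppressWarnings(match_peaks(sim$reference, sim$target,
                                      max_csp = 0.07, seed = 13))
  h <- fit$param_history
  expect_true(all(h$phi >= 0 & h$phi <= 1))
  expect_true(all(h$frechet_shape >= 1))
  expect_true(all(h$frechet_scale > 0))
  expect_true(all(is.finite(h$log_omega)))
})
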