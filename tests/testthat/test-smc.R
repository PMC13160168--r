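simple_params <- function(phi = 0.2, dmax = 40) {
  solve_omega(match_params(frechet_shape = 1.5, frechet_scale = 5, phi = phi,
                           prior_a = 1, prior_b = 9,
                           max_csp_distance = dmax, dof = 2L))
}

test_that("decision matrix composes match and no-match likelihoods", {
  p <- simple_params()
  d <- matrix(c(1, 3, 10, 2), 2, 2)
  s <- build_decision_matrix(d, p)
  lnm <- nomatch_log_density(p)
  expect_equal(dim(s), c(2L, 3L))
  for (r in 1:2) for (t in 1:2) {
    expect_equal(s[r, t], match_log_density(d[r, t], p) + lnm,
                 tolerance = 1e-12)
  }
  expect_equal(s[, 3], rep(2 * lnm, 2), tolerance = 1e-12)
  # every row shares the (T-1) no-match factor; the no-match column carries
  # exactly one more
  expect_equal(s[1, 3] - (s[1, 1] - match_log_density(d[1, 1], p)), lnm)
})

test_that("beam proposal matches exact lookahead enumeration at large width", {
  set.seed(101)
  for (rep in 1:6) {
    p <- random_small_instance(3, 3, seed = 200 + rep)
    d <- matrix(runif(9, 0, 30), 3, 3)
    log_s <- build_decision_matrix(d, p)
    cl <- 1:3
    avail <- rep(TRUE, 3)
    got <- beam_proposal(log_s, cl, 1, avail, width = 1e6)
    # exact lookahead by full enumeration over decisions of rows 2..3
    want <- numeric(4)
    for (i in c(1:3, 4L)) {
      av <- avail
      if (i != 4L) av[i] <- FALSE
      tot <- 0
      for (j in c(which(av), 4L)) {
        av2 <- av
        if (j != 4L) av2[j] <- FALSE
        for (k in c(which(av2), 4L)) {
          tot <- tot + exp(log_s[1, i] + log_s[2, j] + log_s[3, k])
        }
      }
      want[i] <- tot
    }
    expect_equal(got, want / sum(want), tolerance = 1e-9)
  }
})

test_that("beam proposal collapses to the row likelihoods with no lookahead", {
  p <- simple_params()
  d <- matrix(c(2, 8, 30), 1, 3)
  log_s <- build_decision_matrix(d, p)
  got <- beam_proposal(log_s, cluster_rows = 1L, position = 1L,
                       avail = rep(TRUE, 3), width = 10)
  w <- exp(log_s[1, ] - max(log_s[1, ]))
  expect_equal(got, w / sum(w), tolerance = 1e-12)
})

test_that("width-1 beam is the greedy best-completion proposal", {
  p <- random_small_instance(2, 2, seed = 17)
  d <- matrix(c(1, 4, 6, 2), 2, 2)
  log_s <- build_decision_matrix(d, p)
  got <- beam_proposal(log_s, 1:2, 1, rep(TRUE, 2), width = 1)
  want <- numeric(3)
  for (i in 1:3) {
    av <- c(TRUE, TRUE)
    if (i <= 2) av[i] <- FALSE
    best <- max(log_s[2, c(which(av), 3L)])
    want[i] <- exp(log_s[1, i] + best)
  }
  expect_equal(got, want / sum(want), tolerance = 1e-12)
})

test_that("ess ratio is 1 for equal weights and 1/N for one-hot weights", {
  expect_equal(ess_ratio(rep(-3.2, 50)), 1)
  expect_equal(ess_ratio(c(0, rep(-1e6, 99))), 0.01, tolerance = 1e-6)
  expect_equal(ess_ratio(log(c(0.7, 0.3))), 1 / (2 * 0.58), tolerance = 1e-9)
  expect_error(ess_ratio(rep(-Inf, 4)), "degenerate")
})

test_that("stratified resampling has the right copy-count behaviour", {
  set.seed(88)
  # uniform weights: the identity permutation
  expect_equal(stratified_resample(rep(0, 64)), 1:64)
  # all weight on the first particle
  expect_equal(stratified_resample(log(c(1, 1e-300))), c(1L, 1L))
  # empirical copy counts track N * weight within binomial-scale error
  w <- c(0.5, 0.3, 0.15, 0.05)
  n <- 4L
  counts <- matrix(0, 1000, 4)
  for (i in seq_len(1000)) {
    idx <- stratified_resample(log(w))
    counts[i, ] <- tabulate(idx, 4)
  }
  expected <- n * w
  se <- sqrt(n * w * (1 - w) / 1000)
  expect_true(all(abs(colMeans(counts) - expected) < 4 * se + 1e-9))
})

test_that("sampled matchings respect exclusivity and dominated rows go unmatched", {
  p <- simple_params()
  # single reference far from the single target: always NO_MATCH
  d <- matrix(5000, 1, 1)
  smp <- sample_posterior(d, p, config = match_control(min_particles = 64),
                          seed = 3)
  expect_true(all(smp$decisions == 2L))

  # exclusivity on a crowded random instance, thousands of matrices
  set.seed(12)
  d <- matrix(runif(12 * 10, 0, 60), 12, 10)
  smp <- sample_posterior(d, p, config = match_control(min_particles = 256),
                          seed = 4)
  for (i in seq_len(nrow(smp$decisions))) {
    tgt <- smp$decisions[i, smp$decisions[i, ] <= 10L]
    expect_false(any(duplicated(tgt)))
  }
  # marginal rows sum to one
  expect_equal(rowSums(smp$p_match), rep(1, 12), tolerance = 1e-9)
})

test_that("ensemble frequencies converge to the enumerated posterior", {
  tvs <- vapply(1:5, function(i) {
    p <- random_small_instance(3, 3, seed = 400 + i)
    set.seed(500 + i)
    d <- matrix(runif(9, 0, 30), 3, 3)
    smp <- sample_posterior(d, p, config = match_control(min_particles = 4000),
                            seed = 600 + i)
    tv_distance(d, p, smp)
  }, numeric(1))
  expect_lt(max(tvs), 0.05)
})

test_that("sampling is deterministic under a fixed seed", {
  p <- simple_params()
  set.seed(900)
  d <- matrix(runif(30, 0, 50), 6, 5)
  a <- sample_posterior(d, p, config = match_control(min_particles = 128), seed = 11)
  b <- sample_posterior(d, p, config = match_control(min_particles = 128), seed = 11)
  expect_identical(a$decisions, b$decisions)
  expect_equal(a$log_weights, b$log_weights)
})
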