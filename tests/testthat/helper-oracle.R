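# Brute-force oracles used to validate the sampler and ordering machinery on
# tiny instances.

# all valid decision vectors (length R, values in 1..T for a target or T+1
# for no match, targets used at most once)
enumerate_matchings <- function(r, tn) {
  nm <- tn + 1L
  out <- list()
  recurse <- function(row, used, acc) {
    if (row > r) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (t in c(setdiff(seq_len(tn), used), nm)) {
      recurse(row + 1L, if (t == nm) used else c(used, t), c(acc, t))
    }
  }
  recurse(1L, integer(0), integer(0))
  out
}

# exact posterior over complete matchings under the decision-likelihood
# parameterisation (uniform prior)
exact_posterior <- function(d, params) {
  log_s <- build_decision_matrix(d, params)
  ms <- enumerate_matchings(nrow(d), ncol(d))
  logl <- vapply(ms, function(m) {
    sum(log_s[cbind(seq_len(nrow(d)), m)])
  }, numeric(1))
  p <- exp(logl - max(logl))
  list(matchings = ms, probs = p / sum(p))
}

# weighted empirical distribution of an ensemble over complete matchings,
# keyed by the decision vector
ensemble_distribution <- function(ensemble) {
  keys <- apply(ensemble$decisions, 1, paste, collapse = ",")
  w <- exp(ensemble$log_weights - max(ensemble$log_weights))
  w <- w / sum(w)
  tapply(w, keys, sum)
}

tv_distance <- function(d, params, ensemble) {
  ex <- exact_posterior(d, params)
  keys <- vapply(ex$matchings, paste, character(1), collapse = ",")
  emp <- ensemble_distribution(ensemble)
  empv <- ifelse(keys %in% names(emp), emp[keys], 0)
  extra <- setdiff(names(emp), keys)  # should be empty: all matchings valid
  sum(abs(ex$probs - empv)) / 2 + sum(emp[extra])
}

# random tiny instance: peak lists + params with omega solved
random_small_instance <- function(r, tn, seed, dmax = 40) {
  set.seed(seed)
  d <- matrix(stats::runif(r * tn, 0, 25), r, tn)
  params <- match_params(frechet_shape = 1 + stats::runif(1, 0, 2),
                         frechet_scale = stats::runif(1, 2, 10),
                         phi = stats::runif(1, 0.05, 0.5),
                         prior_a = 1, prior_b = 9,
                         max_csp_distance = dmax, dof = 2L)
  solve_omega(params)
}

# two-dimensional peak list helper
make_list <- function(shift_mat, sigmas = c(0.0015, 0.015),
                      nuclei = c("H", "N")) {
  peak_list(as.data.frame(shift_mat) |> stats::setNames(nuclei),
            sigmas = sigmas, nuclei = nuclei)
}
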