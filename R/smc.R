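#' Decision likelihood matrix
#'
#' Row r holds the log-likelihoods of the T+1 decisions available to reference
#' peak r: matching target t (the matching likelihood at `d[r, t]` times the
#' non-match likelihood for every other target, columns 1..T) or matching
#' nothing (the non-match likelihood for all T targets, column T+1).
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param params A [match_params()] with `omega` set.
#' @return An R x (T+1) matrix of log decision likelihoods.
#' @export
build_decision_matrix <- function(d, params) {
  tn <- ncol(d)
  lnm <- nomatch_log_density(params)
  lm <- matrix(match_log_density(as.vector(d), params), nrow(d), tn)
  cbind(lm + (tn - 1) * lnm, rep(tn * lnm, nrow(d)))
}

#' Beam-search proposal distribution for one decision
#'
#' Proposal probabilities over the decisions available to the reference peak at
#' `position` within its cluster. The weight of decision i is the sum, over
#' partial decision sets that start with i and extend through the remaining
#' rows of the cluster (respecting column exclusivity), of the product of
#' decision likelihoods -- approximated by retaining at most `width` beams of
#' highest likelihood after each row expansion. With no remaining rows this
#' collapses to the normalised available entries of row r.
#'
#' @param log_s Decision matrix from [build_decision_matrix()].
#' @param cluster_rows Integer vector of the cluster's rows in decision order.
#' @param position Index into `cluster_rows` of the row being decided.
#' @param avail Logical vector of length T: targets still unconsumed for this
#'   particle.
#' @param width Beam width, >= 1.
#' @return Numeric vector of length T+1 of proposal probabilities (zero for
#'   unavailable decisions); column T+1 is the no-match decision.
#' @export
beam_proposal <- function(log_s, cluster_rows, position, avail, width) {
  tn <- ncol(log_s) - 1L
  nm <- tn + 1L
  stopifnot(width >= 1, position >= 1, position <= length(cluster_rows))
  r <- cluster_rows[[position]]
  rem <- cluster_rows[seq_along(cluster_rows) > position]
  dec <- c(which(avail), nm)
  if (!length(rem)) {
    lw <- log_s[r, dec]
  } else {
    lw <- vapply(dec, function(i) {
      av <- avail
      if (i != nm) av[[i]] <- FALSE
      log_s[r, i] + beam_partition(log_s, rem, av, width)
    }, numeric(1))
  }
  p <- numeric(nm)
  w <- exp(lw - max(lw))
  p[dec] <- w / sum(w)
  p
}

# beam search over decision paths through `rows` starting from availability
# `avail`, retaining at most `width` highest-likelihood paths after each row
# expansion; returns the surviving paths (log-likelihoods and their picks).
# Exact whenever the number of live beams never exceeds `width`.
beam_paths <- function(log_s, rows, avail, width) {
  tn <- ncol(log_s) - 1L
  nm <- tn + 1L
  logl <- 0
  picks <- matrix(integer(0), nrow = 1, ncol = 0)
  for (r in rows) {
    cand <- c(which(avail), nm)
    nb <- length(logl)
    nc <- length(cand)
    newl <- rep(logl, times = nc) + rep(log_s[r, cand], each = nb)
    if (ncol(picks)) {
      for (j in seq_len(nc)) {
        if (cand[[j]] != nm) {
          hit <- rowSums(picks == cand[[j]]) > 0
          if (any(hit)) newl[(j - 1L) * nb + which(hit)] <- -Inf
        }
      }
    }
    newpicks <- cbind(picks[rep.int(seq_len(nb), nc), , drop = FALSE],
                      rep(cand, each = nb))
    keep <- which(is.finite(newl))
    if (length(keep) > width) {
      # stable order: ties broken by construction order, deterministic
      keep <- keep[order(newl[keep], decreasing = TRUE)[seq_len(width)]]
    }
    logl <- newl[keep]
    picks <- newpicks[keep, , drop = FALSE]
    if (!length(logl)) break
  }
  list(logl = logl, picks = picks)
}

# log of the beam-approximated partition function over decision paths
beam_partition <- function(log_s, rows, avail, width) {
  bp <- beam_paths(log_s, rows, avail, width)
  if (!length(bp$logl)) return(-Inf)
  logsumexp(bp$logl)
}

#' Effective sample size ratio
#'
#' `(sum w)^2 / (N * sum w^2)` computed stably from log-weights; 1 for equal
#' weights, 1/N for a one-hot weight vector.
#'
#' @param log_weights Vector of particle log-weights.
#' @return Scalar in (0, 1].
#' @export
ess_ratio <- function(log_weights) {
  m <- max(log_weights)
  if (!is.finite(m)) stopf("degenerate ensemble: all weights are zero")
  w <- exp(log_weights - m)
  sum(w)^2 / (length(w) * sum(w^2))
}

#' Stratified resampling
#'
#' Draws one index per equal-probability stratum `[(j-1)/N, j/N)` by inverting
#' the cumulative normalised weights, so the expected copy count of particle i
#' is `N * w_i` with lower variance than multinomial resampling.
#'
#' @param log_weights Vector of N particle log-weights.
#' @return Integer vector of N resampled particle indices.
#' @export
stratified_resample <- function(log_weights) {
  n <- length(log_weights)
  m <- max(log_weights)
  if (!is.finite(m)) stopf("degenerate ensemble: all weights are zero")
  w <- exp(log_weights - m)
  cw <- cumsum(w) / sum(w)
  u <- (seq_len(n) - 1L + runif(n)) / n
  findInterval(u, cw, left.open = TRUE) + 1L
}

# ---- vectorised particle engine ------------------------------------------

# Columns that can influence a cluster's lookahead sums: targets whose
# decision likelihood, for some row of the cluster, lies within exp(thr) of
# that row's best decision. Columns below that carry a vanishing share of any
# partial partition function, so the lookahead treats them as always
# available; the sampled support is still masked per particle, keeping
# importance weights exact.
cluster_relevant_cols <- function(log_s, cl, thr = 14, cap = 8L) {
  tn <- ncol(log_s) - 1L
  score <- rep(-Inf, tn)
  for (r in cl) {
    score <- pmax(score, log_s[r, seq_len(tn)] - max(log_s[r, ]))
  }
  idx <- which(score >= -thr)
  if (length(idx) > cap) idx <- idx[order(score[idx], decreasing = TRUE)[seq_len(cap)]]
  rel <- rep(FALSE, tn)
  rel[idx] <- TRUE
  rel
}

# lookahead-adjusted decision log-weights for a non-final cluster row, for one
# pattern of consumed relevant columns: base[i] = log S[r, i] + log of the
# beam partition over the remaining cluster rows given decision i
deep_base <- function(log_s, cl, pos, relidx, consumed_rel, width,
                      depth = 2L) {
  tn <- ncol(log_s) - 1L
  nmc <- tn + 1L
  rem <- cl[(pos + 1L):length(cl)]
  rem <- rem[seq_len(min(length(rem), depth))]
  av0 <- rep(FALSE, tn)
  av0[relidx] <- TRUE
  av0[consumed_rel] <- FALSE
  ls1 <- log_s[cl[[pos]], ]
  # one beam run yields every exclusion partition: the lookahead for taking
  # column t is the sum over retained paths that avoid t
  bp <- beam_paths(log_s, rem, av0, width)
  if (!length(bp$logl)) return(ls1)
  l0 <- logsumexp(bp$logl)
  la <- rep(l0, nmc)
  for (t in relidx) {
    if (av0[[t]]) {
      hit <- rowSums(bp$picks == t) > 0
      if (any(hit)) {
        la[[t]] <- if (all(hit)) -Inf else logsumexp(bp$logl[!hit])
      }
    }
  }
  ls1 + la
}

# Draw one decision per particle from the categorical defined by `base`
# restricted to the particle's available decisions. Only "head" columns
# (within exp(12) of the row maximum) can change the distribution measurably
# when consumed, so particles are grouped by their availability pattern over
# the head columns; decisions below exp(-20.7) of the maximum are dropped
# from the proposal support (total mass < T * 1e-9). Draws landing on a
# consumed tail column are redrawn from the particle's available support, and
# the recorded log proposal is the truncated law: log pr[pick] - log of the
# particle's available support mass. Returns picks and log proposal
# probabilities.
draw_row_grouped <- function(base, avail, members, tn) {
  nmc <- tn + 1L
  mx <- max(base)
  sup_t <- which(base[seq_len(tn)] >= mx - 20.7)
  head_t <- sup_t[base[sup_t] >= mx - 12]
  # the head pattern only selects which proposal vector a particle draws
  # from (the recorded proposal is always the exact truncated law), so it can
  # be capped for grouping efficiency
  if (length(head_t) > 24L) {
    head_t <- head_t[order(base[head_t], decreasing = TRUE)[1:24]]
  }
  tail_t <- setdiff(sup_t, head_t)
  pick <- integer(length(members))
  dlp <- numeric(length(members))
  if (length(head_t)) {
    key <- as.vector(avail[members, head_t, drop = FALSE] %*%
                       2^(seq_along(head_t) - 1))
  } else {
    key <- rep(0, length(members))
  }
  for (grp in split(seq_along(members), key)) {
    avh <- avail[members[[grp[[1L]]]], head_t]
    dec_ids <- c(head_t[avh], tail_t, nmc)
    pr <- exp(base[dec_ids] - mx)
    pr <- pr / sum(pr)
    tgt <- dec_ids <= tn
    tgt_ids <- dec_ids[tgt]
    pr_nm <- sum(pr[!tgt])
    a <- avail[members[grp], tgt_ids, drop = FALSE]
    mass <- as.vector(a %*% pr[tgt]) + pr_nm
    ii <- sample.int(length(dec_ids), length(grp), TRUE, prob = pr)
    pk <- dec_ids[ii]
    is_t <- pk <= tn
    if (any(is_t)) {
      rows <- which(is_t)
      bad <- rows[!a[cbind(rows, match(pk[rows], tgt_ids))]]
      for (b in bad) {
        ok <- c(tgt_ids[a[b, ]], nmc)
        prb <- pr[match(ok, dec_ids)]
        pk[[b]] <- ok[sample.int(length(ok), 1L, prob = prb)]
      }
    }
    pick[grp] <- pk
    dlp[grp] <- log(pr[match(pk, dec_ids)]) - log(mass)
  }
  list(pick = pick, dlp = dlp)
}

# sample one complete ensemble of N decision sets; `state` carries the beam
# width so escalations persist across clusters and repeated ensembles.
# Per cluster, the incremental weights gate beam-width escalation (ESS ratio
# < ess_threshold discards the cluster's decisions and widens the beam, while
# the beam can still be inexact); the accumulated weights trigger stratified
# resampling only when their ESS ratio falls below resample_threshold, which
# preserves lineage diversity across the many independent clusters of a
# typical peak list. Returns the decision matrix and final log-weights.
sample_ensemble <- function(log_s, ordering, n, config, state) {
  rr <- nrow(log_s)
  tn <- ncol(log_s) - 1L
  nm <- tn + 1L
  dec <- matrix(0L, n, rr)
  avail <- matrix(TRUE, n, tn)
  lw_tot <- numeric(n)  # accumulated log-weights since last resample
  # rows whose proposal is numerically a point mass (all but < 1e-9 of the
  # unmasked proposal mass on one decision) decide in O(1) for the whole
  # ensemble, provided no particle has consumed that decision; weight
  # increments are then constant across particles and cancel on normalisation
  row_top <- max.col(log_s, ties.method = "first")
  top_val <- log_s[cbind(seq_len(rr), row_top)]
  alt_mass <- vapply(seq_len(rr), function(r) {
    -expm1(top_val[[r]] - logsumexp(log_s[r, ]))
  }, numeric(1))
  fast_row <- alt_mass < 1e-9
  all_members <- seq_len(n)
  for (cl in ordering$clusters) {
    if (length(cl) == 1L && fast_row[[cl[[1L]]]]) {
      top <- row_top[[cl[[1L]]]]
      if (top == nm) {
        dec[, cl[[1L]]] <- nm
        next
      }
      if (all(avail[, top])) {
        dec[, cl[[1L]]] <- top
        avail[, top] <- FALSE
        next
      }
    }
    multi <- length(cl) > 1L
    # per-position lookahead spans at most lookahead_depth subsequent rows;
    # only columns relevant to those rows influence the lookahead, so
    # particles are grouped by that (much smaller) pattern
    if (multi) {
      len <- length(cl)
      rel_pos <- vector("list", len - 1L)
      for (pos in seq_len(len - 1L)) {
        rem <- cl[(pos + 1L):len]
        rem <- rem[seq_len(min(length(rem), config$lookahead_depth))]
        rel_pos[[pos]] <- which(cluster_relevant_cols(log_s, rem))
      }
      branch <- max(vapply(rel_pos, length, integer(1))) + 1
      depth <- min(len - 1L, config$lookahead_depth)
    }
    repeat {
      # the beam is exact once its width covers every lookahead branch; past
      # that point a low ESS reflects weight variance inherited from earlier
      # clusters, which widening cannot reduce
      beam_exact <- !multi || branch^depth <= state$width
      # widening is attempted only if exactness is reachable within the cap
      can_exact <- multi && branch^depth <= config$beam_width_cap
      lt <- numeric(n)  # cluster-incremental log target
      lp <- numeric(n)  # cluster-incremental log proposal
      for (pos in seq_along(cl)) {
        r <- cl[[pos]]
        if (pos == length(cl)) {
          drawn <- draw_row_grouped(log_s[r, ], avail, all_members, tn)
          pick <- drawn$pick
          lp <- lp + drawn$dlp
        } else {
          # lookahead bases are memoised per pattern of consumed relevant
          # columns; particles are drawn per pattern group
          relidx <- rel_pos[[pos]]
          if (length(relidx)) {
            rkey <- as.vector(avail[, relidx, drop = FALSE] %*%
                                2^(seq_along(relidx) - 1))
          } else {
            rkey <- rep(0, n)
          }
          pick <- integer(n)
          for (grp in split(all_members, rkey)) {
            consumed_rel <- relidx[!avail[grp[[1L]], relidx]]
            base <- deep_base(log_s, cl, pos, relidx, consumed_rel,
                              state$width, config$lookahead_depth)
            drawn <- draw_row_grouped(base, avail, grp, tn)
            pick[grp] <- drawn$pick
            lp[grp] <- lp[grp] + drawn$dlp
          }
        }
        lt <- lt + log_s[cbind(rep.int(r, n), pick)]
        dec[, r] <- pick
        hitt <- pick != nm
        avail[cbind(which(hitt), pick[hitt])] <- FALSE
      }
      if (beam_exact || !can_exact ||
          ess_ratio(lt - lp) >= config$ess_threshold) break
      # poor proposal/target agreement: discard the cluster's decisions
      # (inverse update; the consumed targets were necessarily free before
      # this cluster), widen the beam, and retry
      for (r in cl) {
        pk <- dec[, r]
        h <- pk > 0L & pk <= tn
        avail[cbind(which(h), pk[h])] <- TRUE
        dec[, r] <- 0L
      }
      state$width <- state$width * 5
      if (state$width > config$beam_width_cap) {
        stopf(paste0("proposal failure: beam width exceeded %d -- ",
                     "check peak lists/parameters"), config$beam_width_cap)
      }
    }
    lw_tot <- lw_tot + (lt - lp)
    if (ess_ratio(lw_tot) < config$resample_threshold) {
      idx <- stratified_resample(lw_tot)
      dec <- dec[idx, , drop = FALSE]
      avail <- avail[idx, , drop = FALSE]
      lw_tot <- numeric(n)
    }
  }
  # rejuvenation: full-conditional (Gibbs) re-draws of every row plus
  # Metropolis swap moves between any two rows sharing a plausible target,
  # applied to each particle independently. Both kernels leave the matching
  # posterior invariant, so the importance weights remain valid; they restore
  # the per-row diversity and mode mixing (two-row assignment exchanges,
  # including across clusters) that stratified resampling and sequential
  # decisions erode.
  rows_by_col <- vector("list", tn)
  for (r in seq_len(rr)) {
    ls <- log_s[r, ]
    for (t in which(ls[seq_len(tn)] >= max(ls) - 12)) {
      rows_by_col[[t]] <- c(rows_by_col[[t]], r)
    }
  }
  swap_pairs <- unique(do.call(cbind, c(list(matrix(integer(0), 2, 0)),
    lapply(rows_by_col, function(rs) {
      if (length(rs) < 2L) return(matrix(integer(0), 2, 0))
      utils::combn(rs, 2L)
    }))), MARGIN = 2)
  for (sweep in seq_len(config$gibbs_sweeps)) {
    for (r in ordering$decision_order) {
      cur <- dec[, r]
      h <- cur <= tn
      if (any(h)) avail[cbind(which(h), cur[h])] <- TRUE
      if (fast_row[[r]] &&
          (row_top[[r]] == nm || all(avail[, row_top[[r]]]))) {
        pick <- rep.int(row_top[[r]], n)
      } else {
        pick <- draw_row_grouped(log_s[r, ], avail, all_members, tn)$pick
      }
      dec[, r] <- pick
      h <- pick != nm
      avail[cbind(which(h), pick[h])] <- FALSE
    }
    for (pi in seq_len(ncol(swap_pairs))) {
      a <- swap_pairs[1L, pi]; b <- swap_pairs[2L, pi]
      da <- dec[, a]; db <- dec[, b]
      lr <- log_s[cbind(rep.int(a, n), db)] +
        log_s[cbind(rep.int(b, n), da)] -
        log_s[cbind(rep.int(a, n), da)] -
        log_s[cbind(rep.int(b, n), db)]
      acc <- which(log(runif(n)) < lr & da != db)
      if (length(acc)) {
        dec[acc, a] <- db[acc]
        dec[acc, b] <- da[acc]
      }
    }
  }
  lw_tot <- lw_tot - logsumexp(lw_tot)
  list(decisions = dec, log_weights = lw_tot)
}

# weighted marginal frequency of every reference -> decision pair
decision_freqs <- function(dec, log_weights, tn) {
  w <- exp(log_weights - max(log_weights))
  w <- w / sum(w)
  out <- matrix(0, ncol(dec), tn + 1L)
  for (r in seq_len(ncol(dec))) {
    sums <- rowsum(w, dec[, r])
    out[r, as.integer(rownames(sums))] <- sums
  }
  out
}

#' Sample complete matching matrices from the posterior
#'
#' Runs the full sequential Monte Carlo loop: decisions are drawn cluster by
#' cluster in the reference decision order using beam-search lookahead
#' proposals. Per cluster, an effective-sample-size ratio below
#' `ess_threshold` (while the beam is still inexact) discards the cluster's
#' decisions and retries with a five-fold wider beam; the accumulated
#' importance weights trigger stratified resampling whenever their ESS ratio
#' falls below `resample_threshold`. Two independent ensembles are drawn and
#' their per-pair weighted marginal frequencies compared; if any frequency
#' differs by more than `freq_tol` the particle count is doubled and sampling
#' repeated. The two ensembles are merged in the returned sample.
#'
#' @inheritParams build_decision_matrix
#' @param ordering A `peak_ordering` from [order_reference_peaks()] (or
#'   `NULL` to build one from `d` and `params`).
#' @param config A [match_control()] list.
#' @param seed Optional integer seed (set once; all draws flow from it).
#' @param n_particles Starting particle count; defaults to
#'   `max(min_particles, R)`.
#' @return A `match_ensemble`: list with `decisions` (matrix of decision
#'   indices, one row per sampled matching, column T+1 meaning no match),
#'   `n_particles` (the stabilised N), `p_match` (R x (T+1) marginal
#'   frequencies), and `beam_width` (final width).
#' @export
sample_posterior <- function(d, params, ordering = NULL,
                             config = match_control(), seed = NULL,
                             n_particles = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rr <- nrow(d); tn <- ncol(d)
  if (is.null(ordering)) ordering <- build_ordering(d, params,
                                                    config$candidate_prob_ratio)
  log_s <- build_decision_matrix(d, params)
  n <- n_particles %||% max(config$min_particles, rr)
  state <- new.env(parent = emptyenv())
  state$width <- config$beam_width
  doublings <- 0L
  repeat {
    e1 <- sample_ensemble(log_s, ordering, n, config, state)
    e2 <- sample_ensemble(log_s, ordering, n, config, state)
    f1 <- decision_freqs(e1$decisions, e1$log_weights, tn)
    f2 <- decision_freqs(e2$decisions, e2$log_weights, tn)
    if (max(abs(f1 - f2)) <= config$freq_tol) break
    doublings <- doublings + 1L
    if (doublings > config$max_doublings) {
      warnf(paste0("marginal frequencies did not stabilise after %d sample-size",
                   " doublings; proceeding with the merged sample"),
            config$max_doublings)
      break
    }
    n <- n * 2L
  }
  # merge the two ensembles, each contributing half of the total mass
  dec <- rbind(e1$decisions, e2$decisions)
  lw <- c(e1$log_weights - log(2), e2$log_weights - log(2))
  structure(list(decisions = dec, log_weights = lw, n_particles = n,
                 p_match = (f1 + f2) / 2,
                 beam_width = state$width),
            class = "match_ensemble")
}

#' @export
print.match_ensemble <- function(x, ...) {
  cat(sprintf("SMC matching ensemble: %d sampled matchings (%d particles/run), %d reference peaks\n",
              nrow(x$decisions), x$n_particles, ncol(x$decisions)))
  invisible(x)
}
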