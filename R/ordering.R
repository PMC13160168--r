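#' Per-reference candidate target sets
#'
#' For every reference peak, target peaks whose matching likelihood is below
#' the non-match likelihood `1/omega` are eliminated; the surviving
#' likelihoods (plus the always-present no-match decision) are normalised to
#' probabilities; targets whose probability is more than `ratio` times smaller
#' than the best target's are then dropped. The no-match candidate is never
#' dropped.
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param params A [match_params()] with `omega` set.
#' @param ratio Probability ratio for the pruning rule (default 20).
#' @return A list with one element per reference peak, each a list with
#'   `targets` (integer indices of surviving targets, possibly empty),
#'   `probs` (their normalised probabilities) and `nomatch_prob`.
#' @export
candidate_sets <- function(d, params, ratio = 20) {
  lnm <- nomatch_log_density(params)
  lmat <- matrix(match_log_density(as.vector(d), params), nrow(d), ncol(d))
  lapply(seq_len(nrow(d)), function(r) {
    keep <- which(lmat[r, ] >= lnm)
    ll <- c(lmat[r, keep], lnm)             # candidates + NO_MATCH
    p <- exp(ll - logsumexp(ll))
    if (length(keep)) {
      pt <- p[seq_along(keep)]
      ok <- pt >= max(pt) / ratio
      keep <- keep[ok]
      ll <- c(lmat[r, keep], lnm)
      p <- exp(ll - logsumexp(ll))
    }
    list(targets = keep,
         probs = if (length(keep)) p[seq_along(keep)] else numeric(0),
         nomatch_prob = p[length(p)])
  })
}

#' Overlap distance between reference peaks
#'
#' Two reference peaks "compete" for a target when the target appears in both
#' candidate sets with match probabilities within a factor `ratio` of each
#' other. The distance between two reference peaks is the multiplicative
#' inverse of their competing-target count (`Inf` for no overlap, 0 on the
#' diagonal). The no-match pseudo-candidate never counts as overlap.
#'
#' @param sets Candidate sets from [candidate_sets()].
#' @param ratio Probability ratio defining "competing" (default 20).
#' @return A symmetric R x R matrix.
#' @export
overlap_distance_matrix <- function(sets, ratio = 20) {
  r <- length(sets)
  out <- matrix(Inf, r, r)
  diag(out) <- 0
  for (i in seq_len(r)) {
    ti <- sets[[i]]$targets
    if (!length(ti)) next
    for (j in seq_len(r)) {
      if (j <= i) next
      tj <- sets[[j]]$targets
      common <- intersect(ti, tj)
      if (!length(common)) next
      pi <- sets[[i]]$probs[match(common, ti)]
      pj <- sets[[j]]$probs[match(common, tj)]
      ratio_ij <- pmax(pi, pj) / pmin(pi, pj)
      n <- sum(ratio_ij <= ratio)
      if (n > 0) out[i, j] <- out[j, i] <- 1 / n
    }
  }
  out
}

#' All-pairs shortest path distances
#'
#' Shortest paths over the weighted graph whose edges are the finite entries
#' of `dist`; disconnected pairs stay `Inf`.
#'
#' @param dist Symmetric non-negative matrix with zero diagonal; `Inf` encodes
#'   a missing edge.
#' @return Matrix of the same shape with path distances.
#' @export
shortest_path_matrix <- function(dist) {
  r <- nrow(dist)
  if (r == 1L) return(matrix(0, 1, 1))
  edges <- which(upper.tri(dist) & is.finite(dist), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = r, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- dist[edges]
  }
  out <- igraph::distances(g)
  dimnames(out) <- NULL
  out
}

# Bar-Joseph optimal leaf ordering of a single-linkage dendrogram over a small
# distance matrix; returns a permutation of seq_len(nrow(d)). Ties are broken
# toward the lexicographically smallest order (lowest index first).
olo_order <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(1L)
  if (n == 2L) return(1:2)
  hc <- hclust(as.dist(d), method = "single")
  key <- function(u, v) paste(u, v)
  solve_node <- function(node) {
    if (node < 0) {
      leaf <- -node
      res <- list()
      res[[key(leaf, leaf)]] <- list(cost = 0, ord = leaf)
      return(res)
    }
    a <- solve_node(hc$merge[node, 1])
    b <- solve_node(hc$merge[node, 2])
    res <- list()
    add <- function(cost, ord) {
      k <- key(ord[[1]], ord[[length(ord)]])
      cur <- res[[k]]
      better <- is.null(cur) || cost < cur$cost - 1e-12 ||
        (abs(cost - cur$cost) <= 1e-12 &&
           paste(ord, collapse = ",") < paste(cur$ord, collapse = ","))
      if (better) res[[k]] <<- list(cost = cost, ord = ord)
    }
    variants <- function(x) {
      lapply(x, function(e) list(e, list(cost = e$cost, ord = rev(e$ord))))
    }
    av <- unlist(variants(a), recursive = FALSE)
    bv <- unlist(variants(b), recursive = FALSE)
    for (ea in av) for (eb in bv) {
      ja <- ea$ord[[length(ea$ord)]]; jb <- eb$ord[[1]]
      add(ea$cost + eb$cost + d[ja, jb], c(ea$ord, eb$ord))
      ja2 <- eb$ord[[length(eb$ord)]]; jb2 <- ea$ord[[1]]
      add(ea$cost + eb$cost + d[ja2, jb2], c(eb$ord, ea$ord))
    }
    res
  }
  res <- solve_node(nrow(hc$merge))
  costs <- vapply(res, `[[`, numeric(1), "cost")
  best <- res[order(costs, vapply(res, function(e) paste(e$ord, collapse = ","),
                                  character(1)))][[1]]
  best$ord
}

#' Cluster reference peaks and fix the decision order
#'
#' Reference peaks are clustered by single-linkage agglomerative clustering of
#' the shortest-path overlap distances, cut at distance 1.0 -- since every
#' finite hop distance is `1/overlap <= 1`, any two reference peaks connected
#' by a finite path land in the same cluster. Within each cluster the leaves
#' are arranged by optimal leaf ordering of the single-linkage dendrogram, so
#' strongly competing reference peaks sit adjacently in the decision sequence.
#' Clusters are processed in ascending order of their smallest member index.
#'
#' @param paths Shortest-path matrix from [shortest_path_matrix()].
#' @return A list of class `peak_ordering` with `clusters` (list of integer
#'   vectors, each in decision order) and `decision_order` (the concatenated
#'   permutation).
#' @export
order_reference_peaks <- function(paths) {
  r <- nrow(paths)
  finite <- is.finite(paths)
  if (r == 1L) {
    membership <- 1L
  } else {
    big <- max(2, 2 * max(paths[finite]))
    dmat <- paths
    dmat[!finite] <- big
    hc <- hclust(as.dist(dmat), method = "single")
    membership <- cutree(hc, h = 1.0)
  }
  ids <- split(seq_len(r), membership)
  ids <- ids[order(vapply(ids, min, integer(1)))]
  clusters <- lapply(ids, function(members) {
    if (length(members) <= 2L) return(members)
    sub <- paths[members, members, drop = FALSE]
    members[olo_order(sub)]
  })
  names(clusters) <- NULL
  structure(list(clusters = clusters,
                 decision_order = unlist(clusters, use.names = FALSE)),
            class = "peak_ordering")
}

#' @export
print.peak_ordering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("Reference peak ordering: %d peaks in %d clusters (largest %d)\n",
              length(x$decision_order), length(sizes), max(sizes)))
  invisible(x)
}

# One call building candidate sets -> overlap -> shortest paths -> ordering
build_ordering <- function(d, params, ratio = 20) {
  sets <- candidate_sets(d, params, ratio = ratio)
  ov <- overlap_distance_matrix(sets, ratio = ratio)
  order_reference_peaks(shortest_path_matrix(ov))
}
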