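#' Weighted graph container
#'
#' Wraps a nonnegative, symmetric, zero-diagonal adjacency matrix together
#' with the derived quantities used by the graph measures: node strength
#' \eqn{k_i = \sum_j A_{ij}} and total weight \eqn{m = \frac{1}{2}\sum_{ij} A_{ij}}.
#'
#' @param adjacency N x N numeric matrix, \eqn{A_{ij} \ge 0}, symmetric,
#'   zero diagonal.
#' @return object of class \code{"weighted_graph"}: list with
#'   \code{adjacency}, \code{strength}, \code{m}, \code{n_edges}.
#' @export
weighted_graph <- function(adjacency) {
  stopifnot(is.matrix(adjacency), is.numeric(adjacency),
            nrow(adjacency) == ncol(adjacency))
  if (any(adjacency < 0))
    stop("weighted_graph requires nonnegative weights", call. = FALSE)
  if (max(abs(adjacency - t(adjacency))) > 1e-12)
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  k <- rowSums(adjacency)
  structure(
    list(adjacency = adjacency, strength = k, m = sum(k) / 2,
         n_edges = sum(adjacency[upper.tri(adjacency)] > 0)),
    class = "weighted_graph"
  )
}

#' Proportional thresholding of a connectivity matrix
#'
#' Builds the weighted adjacency used by all graph measures: negative edges
#' are preserved by taking absolute values, then only the strongest
#' \code{cost} fraction of all possible edges is retained (weights kept, not
#' binarized). Retention counts \eqn{\lceil cost \cdot N(N-1)/2 \rceil} of
#' the \eqn{N(N-1)/2} possible upper-triangle entries; ties at the cutoff are
#' broken by (row, column) lexicographic order so the result is
#' deterministic.
#'
#' @param matrix raw symmetric connectivity matrix (entries may be negative),
#'   zero diagonal.
#' @param cost proportion of possible edges to keep, in (0, 1].
#' @return a [weighted_graph()].
#' @export
prepare_adjacency <- function(matrix, cost) {
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1)
    stop("cost must be a single proportion in (0, 1]", call. = FALSE)
  w <- abs(matrix)
  diag(w) <- 0
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  n_possible <- nrow(ut)
  keep <- ceiling(cost * n_possible)
  vals <- w[upper.tri(w)]
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  drop_idx <- ord[-seq_len(keep)]
  if (length(drop_idx)) {
    a <- w
    a[ut[drop_idx, , drop = FALSE]] <- 0
    a[lower.tri(a)] <- 0
    a <- a + t(a)
  } else {
    a <- w
  }
  weighted_graph(a)
}

#' Participation coefficient
#'
#' \eqn{PC_i = 1 - \sum_s (k_{is}/k_i)^2}, where \eqn{k_{is}} is node
#' \eqn{i}'s summed edge weight into community \eqn{s}. 0 means all of a
#' node's strength stays inside its own community; values approach
#' \eqn{1 - 1/M} when strength is spread evenly over all \eqn{M}
#' communities. Isolated nodes (\eqn{k_i = 0}) get \eqn{PC_i = 0} by
#' convention.
#'
#' @param graph a [weighted_graph()].
#' @param membership integer community id per node (e.g. from
#'   [node_communities()] or [newman_communities()]).
#' @return numeric vector of per-node participation coefficients.
#' @export
participation_coefficient <- function(graph, membership) {
  a <- graph$adjacency
  stopifnot(length(membership) == nrow(a), !anyNA(membership))
  comm <- sort(unique(membership))
  ind <- outer(membership, comm, "==") * 1
  kis <- a %*% ind                      # per-node per-community strength
  k <- graph$strength
  pc <- numeric(length(k))
  pos <- k > 0
  pc[pos] <- 1 - rowSums((kis[pos, , drop = FALSE] / k[pos])^2)
  pc
}

# Shared single pass of Brandes' algorithm: betweenness and the
# global-efficiency sum need the same shortest paths, so the sweep computes
# them together.
.path_metrics <- function(graph) {
  brandes_path_metrics(graph$adjacency)
}

#' Betweenness centrality (weighted, unnormalized)
#'
#' Shortest paths are computed on edge lengths \eqn{L_{ij} = 1/A_{ij}} (the
#' standard inverse-weight transform: stronger connections are shorter).
#' \eqn{c_B(v) = \sum_{s<t,\, s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}}
#' over unordered node pairs; unnormalized, so values range from 0 upward.
#' Pairs with no connecting path contribute 0.
#'
#' @param graph a [weighted_graph()].
#' @return numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(graph) {
  .path_metrics(graph)$bc
}

#' Global efficiency
#'
#' \eqn{E = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}} with \eqn{d_{ij}} the
#' shortest-path distance on lengths \eqn{1/A_{ij}}; disconnected pairs
#' contribute 0. Equals 1 for a complete unit-weight graph and 0 for an
#' edgeless one.
#'
#' @param graph a [weighted_graph()].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(graph) {
  n <- nrow(graph$adjacency)
  if (n < 2L) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  .path_metrics(graph)$efficiency
}

#' Modularity of a partition
#'
#' \eqn{Q = \frac{1}{2m} \sum_{ij} (A_{ij} - k_i k_j / 2m)\,\delta(c_i, c_j)}.
#' The all-in-one partition has \eqn{Q = 0}.
#'
#' @param graph a [weighted_graph()].
#' @param membership community id per node.
#' @return scalar modularity.
#' @export
modularity_q <- function(graph, membership) {
  if (graph$m <= 0) stop("modularity is undefined for an empty graph (m = 0)",
                         call. = FALSE)
  a <- graph$adjacency
  stopifnot(length(membership) == nrow(a))
  m2 <- 2 * graph$m
  q <- 0
  for (s in unique(membership)) {
    idx <- membership == s
    w_in <- sum(a[idx, idx])           # counts both (i,j) and (j,i)
    k_s <- sum(graph$strength[idx])
    q <- q + w_in / m2 - (k_s / m2)^2
  }
  q
}

# Kernighan-Lin style fine-tuning of a bisection sign vector s on the
# (generalized) modularity matrix Bg: repeatedly sweep all nodes, flipping
# the best single node each step (moves that lower q are allowed during a
# sweep), keep the best configuration seen, repeat while it improves
# q = s' Bg s. Incremental O(n) updates per flip.
.kl_refine <- function(Bg, s) {
  n <- length(s)
  dB <- diag(Bg)
  exact_q <- function(sv) sum(sv * (Bg %*% sv))
  q <- exact_q(s)
  for (round in seq_len(2L * n + 16L)) {
    s_best_round <- s
    q_best_round <- q
    s_iter <- s
    Bs <- as.vector(Bg %*% s_iter)
    q_iter <- q
    unmoved <- rep(TRUE, n)
    while (any(unmoved)) {
      dq <- -4 * s_iter * Bs + 4 * dB
      dq[!unmoved] <- -Inf
      i <- which.max(dq)
      q_iter <- q_iter + dq[i]
      Bs <- Bs - 2 * s_iter[i] * Bg[, i]
      s_iter[i] <- -s_iter[i]
      unmoved[i] <- FALSE
      if (q_iter > q_best_round + 1e-12) {
        q_best_round <- q_iter
        s_best_round <- s_iter
      }
    }
    # re-evaluate exactly: accumulated increments carry float error that
    # could otherwise fake an improvement forever
    q_best_round <- exact_q(s_best_round)
    if (q_best_round > q + 1e-10) {
      q <- q_best_round
      s <- s_best_round
    } else break
  }
  s
}

#' Newman spectral community detection
#'
#' Recursive spectral bisection on the modularity matrix
#' \eqn{B_{ij} = A_{ij} - k_i k_j / 2m}: each candidate module is split by
#' the sign of the leading eigenvector of its generalized modularity matrix,
#' the split is fine-tuned with Kernighan-Lin style node swaps, and
#' accepted only if it increases \eqn{Q}. The complete division is then
#' fine-tuned by a Kernighan-Lin pass allowing node moves between any
#' communities (including new ones) and merges of community pairs. The same
#' fine-tuning is also run from the multi-way divisions given by the sign
#' patterns of the top 1-3 eigenvectors of \eqn{B} (and, on small graphs,
#' from all-singletons), and the highest-\eqn{Q} division wins. Zero
#' eigenvector entries join the positive group; eigenvector signs are fixed
#' by their largest-magnitude entry, so the procedure is deterministic for
#' a given graph.
#'
#' @param graph a [weighted_graph()].
#' @return integer membership vector (communities numbered 1..M in order of
#'   their smallest node index).
#' @export
newman_communities <- function(graph) {
  n <- nrow(graph$adjacency)
  if (graph$m <= 0) {
    warning("graph has no edges; returning a single community", call. = FALSE)
    return(rep(1L, n))
  }
  a <- graph$adjacency
  k <- graph$strength
  B <- a - outer(k, k) / (2 * graph$m)
  eps <- 1e-10
  score <- function(mm) sum(B[outer(mm, mm, "==")])

  # one spectral bisection attempt (leading eigenvector sign + KL swaps) on
  # the node subset g; returns the within-module sign vector or NULL
  try_split <- function(g) {
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    v <- eigen(Bg, symmetric = TRUE)$vectors[, 1L]
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- .kl_refine(Bg, ifelse(v < 0, -1, 1))
    if (sum(s * (Bg %*% s)) > eps && length(unique(s)) == 2L) s else NULL
  }

  # merge any community pair whose union raises Q, re-tuning after each
  polish <- function(mm) {
    mm <- kl_partition_refine_cpp(B, as.integer(mm))
    repeat {
      comms <- sort(unique(mm))
      if (length(comms) < 2L) break
      best_gain <- eps
      best_pair <- NULL
      for (i in seq_along(comms)[-length(comms)]) {
        for (j in seq(i + 1L, length(comms))) {
          gain <- 2 * sum(B[mm == comms[i], mm == comms[j], drop = FALSE])
          if (gain > best_gain) {
            best_gain <- gain
            best_pair <- c(comms[i], comms[j])
          }
        }
      }
      if (is.null(best_pair)) break
      mm[mm == best_pair[2L]] <- best_pair[1L]
      mm <- kl_partition_refine_cpp(B, as.integer(mm))
    }
    mm
  }

  # candidate 1: recursive spectral bisection with per-split fine-tuning
  membership <- rep(1L, n)
  repeat {
    changed <- FALSE
    for (cm in unique(membership)) {
      idx <- which(membership == cm)
      if (length(idx) < 2L) next
      s <- try_split(idx)
      if (!is.null(s)) {
        membership[idx[s < 0]] <- max(membership) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  candidates <- list(membership)

  # candidates 2-4: multi-way divisions from the sign patterns of the top
  # d eigenvectors of B (Newman's multi-eigenvector generalization)
  ev <- eigen(B, symmetric = TRUE)$vectors
  for (d in seq_len(min(3L, n))) {
    v <- ev[, seq_len(d), drop = FALSE]
    for (j in seq_len(d))
      if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
    pat <- (v >= 0) %*% 2^(seq_len(d) - 1)
    candidates <- c(candidates, list(match(pat, unique(pat))))
  }
  # candidate 5: all-singletons start (small graphs only; the KL pass from
  # here is an agglomerative sweep and costs O(n^2) memory/time per move)
  if (n <= 100L) candidates <- c(candidates, list(seq_len(n)))

  refined <- lapply(candidates, polish)
  best <- refined[[which.max(vapply(refined, score, numeric(1L)))]]
  # renumber communities 1..M in order of smallest node index
  match(best, unique(best))
}
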