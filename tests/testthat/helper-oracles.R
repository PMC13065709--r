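# Independent oracles for the graph measures: exhaustive enumeration over
# simple paths and over all set partitions. Only usable for tiny graphs.

# All-simple-paths enumeration: exact shortest-path distances, betweenness
# (unordered pairs, fractional), and global efficiency. Edge lengths are
# 1/weight; graphs in the oracle suite use weights 1/k (k small integer) so
# path lengths are integer-valued doubles and tie detection is exact.
oracle_path_metrics <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths_d <- numeric(0)
      paths_inter <- list()
      rec <- function(v, visited, d, inter) {
        if (v == t) {
          paths_d[length(paths_d) + 1] <<- d
          paths_inter[[length(paths_inter) + 1]] <<- inter
          return(invisible())
        }
        for (u in which(adj[v, ] > 0)) {
          if (!visited[u]) {
            vis2 <- visited
            vis2[u] <- TRUE
            rec(u, vis2, d + 1 / adj[v, u], c(inter, u))
          }
        }
      }
      vis <- rep(FALSE, n)
      vis[s] <- TRUE
      rec(s, vis, 0, integer(0))
      if (length(paths_d)) {
        dmin <- min(paths_d)
        dist[s, t] <- dist[t, s] <- dmin
        sel <- which(paths_d == dmin)
        sigma <- length(sel)
        for (i in sel) {
          for (v in setdiff(paths_inter[[i]], t))
            bc[v] <- bc[v] + 1 / sigma
        }
      }
    }
  }
  inv <- 1 / dist
  diag(inv) <- 0
  inv[is.infinite(dist)] <- 0
  list(bc = bc, dist = dist, efficiency = sum(inv) / (n * (n - 1)))
}

# Direct double-sum evaluation of Q = (1/2m) sum_ij (A_ij - k_i k_j/2m) d(ci,cj)
oracle_modularity <- function(adj, membership) {
  k <- rowSums(adj)
  m2 <- sum(k)
  b <- adj - outer(k, k) / m2
  sum(b[outer(membership, membership, "==")]) / m2
}

# Enumerate every set partition of n items (restricted growth strings) and
# return the maximum modularity and an attaining membership vector.
oracle_best_partition <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  m2 <- sum(k)
  b <- adj - outer(k, k) / m2
  best <- -Inf
  best_mem <- rep(1L, n)
  mem <- integer(n)
  rec <- function(i, maxg) {
    if (i > n) {
      q <- sum(b[outer(mem, mem, "==")]) / m2
      if (q > best) {
        best <<- q
        best_mem <<- mem
      }
      return(invisible())
    }
    for (g in seq_len(maxg + 1L)) {
      mem[i] <<- g
      rec(i + 1L, max(maxg, g))
    }
  }
  rec(1L, 0L)
  list(q = best, membership = best_mem)
}

# Brute-force Benjamini-Hochberg: adj_(i) = min_{j >= i} min(1, p_(j) m / j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[seq(i, m)] * m / seq(i, m))), numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Random weighted graph with integer-reciprocal weights (exact path ties),
# symmetric, zero diagonal, possibly disconnected.
random_test_graph <- function(n, density = 0.6) {
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  on_edges <- ut[stats::runif(length(ut)) < density]
  a[on_edges] <- 1 / sample(1:5, length(on_edges), replace = TRUE)
  a + t(a)
}

# Small 64-node / 8-network node table used across tests.
small_node_table <- function(n_per_net = 4L) {
  nets <- paste0("Net", 1:7)
  cort <- data.frame(
    hemisphere = rep(c("left", "right"), each = 7L * n_per_net),
    network = rep(rep(nets, each = n_per_net), 2L),
    parcel_name = paste0("P", seq_len(14L * n_per_net)),
    stringsAsFactors = FALSE
  )
  sub <- data.frame(
    hemisphere = rep(c("left", "right"), each = n_per_net),
    structure_name = paste0("S", seq_len(2L * n_per_net)),
    stringsAsFactors = FALSE
  )
  build_node_table(cort, sub)
}
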