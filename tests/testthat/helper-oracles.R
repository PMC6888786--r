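# Independent oracles used across tests. These deliberately avoid the
# package's own reachability/centrality code paths.

# Random digraph as a directed_network (uses the ambient RNG stream).
random_digraph <- function(q, p_edge = 0.25) {
  adj <- matrix(stats::runif(q * q) < p_edge, q, q)
  diag(adj) <- FALSE
  directed_network(adj)
}

# Reachability through igraph shortest-path distances (independent of the
# package's boolean-closure routine).
igraph_reach <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  r <- is.finite(d)
  diag(r) <- FALSE
  r
}

# Brute-force brokerage: ordered pairs (s, t), s,t != i, reachable in D but
# not in D - i.
pair_disconnect_count <- function(adj, i) {
  R <- igraph_reach(adj)
  Rm <- igraph_reach(adj[-i, -i, drop = FALSE])
  keep <- setdiff(seq_len(nrow(adj)), i)
  sum(R[keep, keep] & !Rm)
}

# Naive directed betweenness: BFS distances and shortest-path counts per
# source, then the pair-combination formula
#   lambda_i(st) = sigma(s,i) * sigma(i,t) * [d(s,i) + d(i,t) == d(s,t)].
naive_betweenness <- function(adj) {
  q <- nrow(adj)
  D <- matrix(Inf, q, q)
  S <- matrix(0, q, q)
  for (s in seq_len(q)) {
    dist <- rep(Inf, q)
    cnt <- rep(0, q)
    dist[s] <- 0
    cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
            cnt[w] <- cnt[v]
          } else if (dist[w] == dist[v] + 1) {
            cnt[w] <- cnt[w] + cnt[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- cnt
  }
  bc <- numeric(q)
  for (i in seq_len(q)) {
    for (s in seq_len(q)) {
      if (s == i) next
      for (t in seq_len(q)) {
        if (t == i || t == s || !is.finite(D[s, t])) next
        if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
            D[s, i] + D[i, t] == D[s, t]) {
          bc[i] <- bc[i] + S[s, i] * S[i, t] / S[s, t]
        }
      }
    }
  }
  bc
}

# Reachability by accumulating plain matrix powers (a second routine,
# structured differently from both the package's squaring closure and
# igraph's BFS distances).
reach_via_powers <- function(adj) {
  q <- nrow(adj)
  A <- adj * 1
  P <- A
  R <- A > 0
  k <- 1
  while (k < q) {
    P <- (P %*% A) > 0
    R <- R | P
    P <- P * 1
    k <- k + 1
  }
  diag(R) <- FALSE
  R
}

# Brute-force brokerage via the powers routine.
powers_pair_disconnect <- function(adj, i) {
  R <- reach_via_powers(adj)
  Rm <- reach_via_powers(adj[-i, -i, drop = FALSE])
  keep <- setdiff(seq_len(nrow(adj)), i)
  as.integer(sum(R[keep, keep] & !Rm))
}

# Stationary covariance of a VAR(1) X(t) = A X(t-1) + E, Var(E) = s^2 I,
# from the discrete Lyapunov equation via vectorization.
var1_stationary_cov <- function(A, innov_sd = 1) {
  q <- nrow(A)
  vecS <- solve(diag(q * q) - kronecker(A, A), as.vector(diag(innov_sd^2, q)))
  matrix(vecS, q, q)
}

# All digraphs on n nodes (n small), as a list of adjacency matrices.
all_digraphs <- function(n) {
  slots <- which(row(diag(n)) != col(diag(n)))
  m <- length(slots)
  lapply(seq_len(2^m) - 1L, function(code) {
    adj <- matrix(FALSE, n, n)
    adj[slots] <- bitwAnd(code, 2^(seq_len(m) - 1L)) > 0
    adj
  })
}
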