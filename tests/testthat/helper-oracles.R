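# Independent brute-force graph oracles (BFS distances + explicit
# shortest-path enumeration) and small fixture builders. These deliberately
# avoid igraph so metric tests compare two independent routes.

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(A[v, ] > 0)) {
          if (!is.finite(D[s, u]) && u != s) {
            D[s, u] <- d
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# all shortest paths between s and t, as lists of vertex sequences
bf_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  walk <- function(v, path) {
    if (v == t) return(list(path))
    nbrs <- which(A[v, ] > 0 & D[, t] == D[v, t] - 1)
    out <- list()
    for (u in nbrs) out <- c(out, walk(u, c(path, u)))
    out
  }
  walk(s, s)
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- bf_shortest_paths(A, D, s, t)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

bf_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bf_distances(A)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_local_efficiency <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

adjacency_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  A
}

# all 2^choose(n,2) graphs on n labelled nodes
enumerate_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L)
    A <- matrix(0L, n, n)
    on <- which(bits == 1L)
    A[pairs[on, , drop = FALSE]] <- 1L
    A + t(A)
  })
}

random_adjacency <- function(n, m) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- sample.int(nrow(pairs), m)
  A <- matrix(0L, n, n)
  A[pairs[sel, , drop = FALSE]] <- 1L
  A + t(A)
}

ring_lattice <- function(n, k_half) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (off in seq_len(k_half)) {
      j <- ((i - 1 + off) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

random_symmetric_weights <- function(k) {
  W <- matrix(rnorm(k * k), k, k)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# time series whose empirical correlation matrix is exactly `target`
ts_with_exact_correlation <- function(n_frames, target) {
  p <- ncol(target)
  Z <- matrix(rnorm(n_frames * p), n_frames, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  S <- crossprod(Z) / (n_frames - 1)
  Zw <- Z %*% solve(chol(S))          # empirical covariance = identity
  Zw %*% chol(target)
}

co_cluster_ref <- function(labels, dn = NULL) {
  m <- outer(labels, labels, "==") * 1
  dimnames(m) <- dn
  m
}
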