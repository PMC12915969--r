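# Brute-force graph oracles, written independently of igraph:
# all-pairs BFS distances, shortest-path counting for betweenness, and
# triangle counting for local clustering. Intended for graphs of <= ~10
# nodes; everything is plain loops over the adjacency matrix.

bfs_distances_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (v in frontier) {
        for (u in which(adj[v, ] == 1)) {
          if (is.infinite(dist[u])) {
            dist[u] <- dist[v] + 1
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# sigma[s,t] = number of shortest s-t paths; sigma_v = number through v
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  D <- bfs_distances_oracle(adj)
  sigma <- matrix(0, n, n)
  # count shortest paths by dynamic programming over distance layers
  for (s in seq_len(n)) {
    cnt <- rep(0, n); cnt[s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || is.infinite(D[s, v])) next
      preds <- which(adj[v, ] == 1 & D[s, ] == D[s, v] - 1)
      cnt[v] <- sum(cnt[preds])
    }
    sigma[s, ] <- cnt
  }
  btw <- rep(0, n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.infinite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t] && sigma[s, t] > 0) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

closeness_oracle <- function(adj) {
  n <- nrow(adj)
  D <- bfs_distances_oracle(adj)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) return(0)
    (length(d) / sum(d)) * (length(d) / (n - 1))
  }, 0)
}

clustering_oracle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      links <- links + adj[nb[i], nb[j]]
    }
    2 * links / (k * (k - 1))
  }, 0)
}

apl_oracle <- function(adj) {
  D <- bfs_distances_oracle(adj)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}
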