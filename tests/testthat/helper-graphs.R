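# Graph construction helpers and independent brute-force oracles used to
# cross-check the igraph-backed metric implementations.

# thresh_graph from an explicit weighted edge list (keeps every edge)
tg_from_edges <- function(n, from, to, w = rep(1, length(from))) {
  adj <- matrix(0, n, n)
  for (k in seq_along(from)) {
    adj[from[k], to[k]] <- w[k]
    adj[to[k], from[k]] <- w[k]
  }
  rownames(adj) <- colnames(adj) <- paste0("R", seq_len(n))
  structure(list(adj = adj, proportion = 1, n_edges = length(from),
                 labels = rownames(adj)),
            class = "thresh_graph")
}

tg_path <- function(n, w = rep(1, n - 1)) {
  tg_from_edges(n, seq_len(n - 1), 2:n, w)
}

tg_complete <- function(n, w = 1) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  tg_from_edges(n, idx[, 1], idx[, 2], rep(w, nrow(idx)))
}

tg_star <- function(n) tg_from_edges(n, rep(1, n - 1), 2:n)

tg_random_weighted <- function(n, p_edge = 0.6) {
  repeat {
    adj <- matrix(0, n, n)
    idx <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(idx)) < p_edge
    adj[idx[on, , drop = FALSE]] <- runif(sum(on), 0.1, 1)
    adj <- adj + t(adj)
    if (all(colSums(adj) > 0)) break   # avoid isolated nodes
  }
  rownames(adj) <- colnames(adj) <- paste0("R", seq_len(n))
  structure(list(adj = adj, proportion = 1, n_edges = sum(on),
                 labels = rownames(adj)),
            class = "thresh_graph")
}

# Floyd-Warshall all-pairs distances on edge lengths 1/w (independent of
# igraph's Dijkstra)
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1 / adj[adj > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_efficiency <- function(adj) {
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  mean(inv[upper.tri(inv)])
}

# betweenness by exhaustive enumeration of all simple paths between every
# pair: count shortest paths through each interior node
bf_betweenness <- function(adj, tol = 1e-9) {
  n <- nrow(adj)
  bc <- numeric(n)
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- list(path = path, len = len)
        return()
      }
      for (nb in which(adj[last, ] > 0))
        if (!nb %in% path)
          walk(c(path, nb), len + 1 / adj[last, nb])
    }
    walk(from, 0)
    out
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- all_paths(i, j)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, 0, "len")
    mn <- min(lens)
    shortest <- ps[lens <= mn + tol]
    for (sp in shortest) {
      interior <- setdiff(sp$path, c(i, j))
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  bc
}

# Onnela weighted clustering by explicit triple loop
bf_clustering <- function(adj) {
  n <- nrow(adj)
  mx <- max(adj)
  if (mx == 0) return(numeric(n))
  w <- adj / mx
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in nb) for (b in nb)
      if (a != b) s <- s + (w[i, a] * w[i, b] * w[a, b])^(1 / 3)
    cc[i] <- s / (k * (k - 1))
  }
  cc
}

# every connected graph on <= n nodes, one labelled representative per
# isomorphism class (canonical-form deduplication)
all_connected_graphs <- function(n_max) {
  out <- list()
  for (n in 2:n_max) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    seen <- character()
    for (code in seq_len(2^nrow(idx)) - 1L) {
      on <- as.logical(bitwAnd(code, 2^(seq_len(nrow(idx)) - 1L)))
      if (sum(on) < n - 1) next
      adj <- matrix(0, n, n)
      adj[idx[on, , drop = FALSE]] <- 1
      adj <- adj + t(adj)
      ig <- igraph::graph_from_adjacency_matrix(adj, "undirected")
      if (!igraph::is_connected(ig)) next
      cp <- igraph::canonical_permutation(ig)$labeling
      el <- igraph::as_edgelist(igraph::permute(ig, cp))
      el <- t(apply(el, 1L, sort))
      key <- paste(n, paste(sort(paste(el[, 1], el[, 2])), collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      rownames(adj) <- colnames(adj) <- paste0("R", seq_len(n))
      out[[length(out) + 1L]] <-
        structure(list(adj = adj, proportion = 1, n_edges = sum(on),
                       labels = rownames(adj)),
                  class = "thresh_graph")
    }
  }
  out
}

# exact two-sided rank-sum p-value by exhaustive enumeration of all
# group assignments (no ties assumed)
exact_ranksum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(nx + length(y), nx)
  ws <- colSums(matrix(rank(c(x, y))[combs], nrow = nx))
  mu <- nx * (nx + length(y) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
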