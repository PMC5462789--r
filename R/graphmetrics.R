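# Proportional thresholding and weighted hub metrics, raw and normalized
# against weight-reshuffled surrogate networks.

#' Proportional threshold of a connectivity matrix
#'
#' Keeps the `round(proportion * N(N-1)/2)` largest-weight edges (round
#' half-up) of a symmetric weighted matrix; retained edges keep their
#' original weights. Ties at the cutoff are broken deterministically by
#' ascending (row, column) index.
#'
#' @param cm symmetric numeric connectivity matrix (diagonal ignored).
#' @param proportion fraction of edges to retain, in (0, 1\].
#' @return object of class `thresh_graph`: `adj` (thresholded weighted
#'   adjacency), `proportion`, `n_edges`, `labels`.
#' @export
proportional_threshold <- function(cm, proportion = 0.10) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  n <- nrow(cm)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[ut]
  k <- max(1L, as.integer(round_half_up(proportion * nrow(ut))))
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(min(k, length(ord)))]
  adj <- matrix(0, n, n, dimnames = dimnames(cm))
  adj[ut[keep, , drop = FALSE]] <- w[keep]
  adj <- adj + t(adj)
  structure(list(adj = adj, proportion = proportion,
                 n_edges = length(keep),
                 labels = rownames(cm) %||% paste0("R", seq_len(n))),
            class = "thresh_graph")
}

#' @export
print.thresh_graph <- function(x, ...) {
  cat(sprintf("thresh_graph: %d nodes, %d edges (top %.0f%% by weight)\n",
              nrow(x$adj), x$n_edges, 100 * x$proportion))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# edge length for shortest paths; the inverse-weight map is the default,
# -log(w) available for weights in (0, 1]
edge_lengths <- function(w, map = c("inverse", "neglog")) {
  map <- match.arg(map)
  if (map == "inverse") 1 / w else -log(w)
}

#' Betweenness centrality
#'
#' Number of weighted shortest paths passing through each node, summed over
#' unordered node pairs excluding the endpoints, with path lengths taken as
#' the reciprocal of the edge weight (strong edges are short).
#'
#' @param g a `thresh_graph`.
#' @param length_map `"inverse"` (default) or `"neglog"` weight-to-length
#'   map.
#' @return named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(g, length_map = "inverse") {
  ig <- as_igraph(g)
  bc <- igraph::betweenness(
    ig, directed = FALSE,
    weights = edge_lengths(igraph::E(ig)$weight, length_map))
  stats::setNames(as.numeric(bc), g$labels)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs, with
#' `1/Inf = 0` for disconnected pairs and distances measured on inverse
#' edge weights.
#'
#' @inheritParams betweenness_centrality
#' @return scalar efficiency.
#' @export
global_efficiency <- function(g, length_map = "inverse") {
  n <- nrow(g$adj)
  if (n < 2) stop("need at least 2 nodes")
  ig <- as_igraph(g)
  d <- igraph::distances(
    ig, weights = edge_lengths(igraph::E(ig)$weight, length_map))
  inv <- 1 / d
  diag(inv) <- 0
  mean(inv[upper.tri(inv)])
}

#' Node vulnerability
#'
#' Relative drop in global efficiency when a node and its edges are
#' removed: `V_i = (E - E_i) / E`, where `E_i` is the efficiency of the
#' remaining `N - 1` nodes. Values can be negative (removing a peripheral
#' node can raise mean efficiency).
#'
#' @inheritParams betweenness_centrality
#' @return named numeric vector of vulnerabilities.
#' @export
vulnerability <- function(g, length_map = "inverse") {
  n <- nrow(g$adj)
  if (n < 3) stop("need at least 3 nodes")
  e0 <- global_efficiency(g, length_map)
  if (e0 == 0) stop("global efficiency is zero: vulnerability undefined")
  v <- vapply(seq_len(n), function(i) {
    sub <- structure(list(adj = g$adj[-i, -i, drop = FALSE],
                          labels = g$labels[-i]),
                     class = "thresh_graph")
    (e0 - global_efficiency(sub, length_map)) / e0
  }, 0)
  stats::setNames(v, g$labels)
}

#' Node strength
#'
#' Sum of the weights of the edges incident to each node.
#'
#' @param g a `thresh_graph`.
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(g) {
  stats::setNames(rowSums(g$adj), g$labels)
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (Onnela) form: with weights normalized by the maximum
#' weight, the clustering of node `i` with degree `k_i` is
#' \eqn{\frac{1}{k_i(k_i-1)} \sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat
#' w_{jh})^{1/3}}; nodes with degree < 2 get 0. Quantifies how close a
#' node's neighbourhood is to a clique.
#'
#' @param g a `thresh_graph`.
#' @return named numeric vector of clustering coefficients in \[0, 1\].
#' @export
clustering_coeff <- function(g) {
  w <- g$adj
  mx <- max(w)
  if (mx == 0) return(stats::setNames(rep(0, nrow(w)), g$labels))
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  cc <- ifelse(k > 1, num / (k * (k - 1)), 0)
  stats::setNames(cc, g$labels)
}

raw_metrics <- function(g, length_map = "inverse") {
  cbind(bc = betweenness_centrality(g, length_map),
        vuln = vulnerability(g, length_map),
        strength = node_strength(g),
        clustering = clustering_coeff(g))
}

#' Hub metrics with surrogate normalization
#'
#' Computes betweenness centrality, vulnerability, strength and clustering
#' for every node, and normalizes each by the mean of the same metric over
#' surrogate networks obtained by randomly reshuffling the edge weights
#' over the fixed edge topology (degree sequence preserved). A node/metric
#' whose surrogate mean is zero gets `NA` in the normalized column.
#'
#' @param g a `thresh_graph`.
#' @param n_surrogates number of reshuffled surrogates (>= 1; 500 is the
#'   reference analysis setting).
#' @param seed integer seed for the reshuffling.
#' @param length_map weight-to-length map for path-based metrics.
#' @return data.frame of class `node_metrics` with columns `node`, the raw
#'   metrics (`bc`, `vuln`, `strength`, `clustering`) and their normalized
#'   variants (`*_norm`); attribute `n_surrogates`.
#' @export
normalize_metrics <- function(g, n_surrogates = 500, seed = 1L,
                              length_map = "inverse") {
  if (n_surrogates < 1) stop("need at least one surrogate")
  raw <- raw_metrics(g, length_map)
  ut <- which(upper.tri(g$adj) & g$adj > 0)
  wts <- g$adj[ut]
  acc <- matrix(0, nrow(raw), ncol(raw))
  with_seed(stage_seed(seed, "surrogates"), {
    for (s in seq_len(n_surrogates)) {
      sg <- g
      sg$adj[ut] <- sample(wts)
      sg$adj[lower.tri(sg$adj)] <- t(sg$adj)[lower.tri(sg$adj)]
      acc <- acc + raw_metrics(sg, length_map)
    }
  })
  mu <- acc / n_surrogates
  norm <- raw / mu
  norm[mu == 0] <- NA_real_
  out <- data.frame(node = g$labels, raw,
                    bc_norm = norm[, "bc"], vuln_norm = norm[, "vuln"],
                    strength_norm = norm[, "strength"],
                    clustering_norm = norm[, "clustering"],
                    row.names = NULL)
  attr(out, "n_surrogates") <- n_surrogates
  class(out) <- c("node_metrics", "data.frame")
  out
}
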