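# Consensus community detection and provincial/connector hub
# classification.

normalize_partition <- function(memb, labels = NULL) {
  m <- as.integer(factor(memb, levels = unique(memb)))
  names(m) <- labels %||% names(memb)
  m
}

#' Generate partitions from three community-detection algorithms
#'
#' Runs leading-eigenvector (Newman spectral), Louvain and Infomap
#' community detection `n_runs_per_algo` times each on a weighted graph.
#' Runs differ by their RNG stream and by a random relabeling of the
#' vertices (which perturbs order-dependent tie-breaking), and the whole
#' set is deterministic given `seed`. An algorithm failure on a degenerate
#' graph skips that run with a warning.
#'
#' @param g a `thresh_graph` (or symmetric weighted matrix).
#' @param n_runs_per_algo runs per algorithm (>= 1; 100 is the reference
#'   analysis setting).
#' @param seed integer seed.
#' @return list of integer membership vectors (module ids contiguous
#'   from 1), of length up to `3 * n_runs_per_algo`.
#' @export
detect_partitions <- function(g, n_runs_per_algo = 100, seed = 1L) {
  if (n_runs_per_algo < 1) stop("need n_runs_per_algo >= 1")
  adj <- if (inherits(g, "thresh_graph")) g$adj else as.matrix(g)
  labels <- rownames(adj) %||% paste0("R", seq_len(nrow(adj)))
  n <- nrow(adj)
  algos <- list(
    newman = function(ig) igraph::cluster_leading_eigen(ig),
    louvain = function(ig) igraph::cluster_louvain(ig),
    infomap = function(ig) igraph::cluster_infomap(ig))
  out <- list()
  with_seed(stage_seed(seed, "partitions"), {
    for (a in names(algos)) {
      for (r in seq_len(n_runs_per_algo)) {
        perm <- sample.int(n)
        ig <- igraph::graph_from_adjacency_matrix(
          adj[perm, perm], mode = "undirected", weighted = TRUE,
          diag = FALSE)
        memb <- tryCatch(
          igraph::membership(algos[[a]](ig)),
          error = function(e) {
            warning(sprintf("%s run %d failed: %s", a, r,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(memb)) next
        unperm <- integer(n)
        unperm[perm] <- as.integer(memb)
        out[[length(out) + 1L]] <- normalize_partition(unperm, labels)
      }
    }
  })
  if (!length(out)) stop("no community detection run succeeded")
  out
}

#' Co-assignment (association) matrix of a partition ensemble
#'
#' Entry (i, j) counts how many partitions assign nodes i and j to the
#' same module; the diagonal equals the number of partitions.
#'
#' @param partitions list of membership vectors over the same node set.
#' @return integer matrix with attribute `n_runs`.
#' @export
association_matrix <- function(partitions) {
  if (!length(partitions)) stop("no partitions")
  n <- length(partitions[[1]])
  if (any(vapply(partitions, length, 0L) != n))
    stop("partitions cover inconsistent node sets")
  acc <- matrix(0L, n, n)
  for (p in partitions) acc <- acc + outer(p, p, `==`)
  dimnames(acc) <- list(names(partitions[[1]]), names(partitions[[1]]))
  attr(acc, "n_runs") <- length(partitions)
  acc
}

#' Consensus partition of a partition ensemble
#'
#' Prunes the association matrix by a permutation null -- node labels are
#' permuted within each original partition (module sizes preserved),
#' `n_null` times, and entries not exceeding the null's `level` quantile
#' are set to zero -- then re-clusters the pruned matrix as a weighted
#' graph with the Louvain method. If pruning empties the matrix an
#' all-singleton partition is returned with a warning.
#'
#' @param assoc association matrix from [association_matrix()].
#' @param partitions the partition ensemble behind `assoc`.
#' @param seed integer seed.
#' @param n_null number of null permutations (default 100).
#' @param level null quantile above which co-assignment counts are kept
#'   (default 0.95).
#' @return integer membership vector (modules contiguous from 1).
#' @export
consensus_partition <- function(assoc, partitions, seed = 1L,
                                n_null = 100, level = 0.95) {
  if (length(partitions) < 2) stop("need an ensemble of >= 2 partitions")
  n <- nrow(assoc)
  with_seed(stage_seed(seed, "consensus"), {
    null <- array(0L, c(n, n, n_null))
    for (b in seq_len(n_null)) {
      acc <- matrix(0L, n, n)
      for (p in partitions) {
        q <- p[sample.int(n)]
        acc <- acc + outer(q, q, `==`)
      }
      null[, , b] <- acc
    }
    thr <- apply(null, c(1, 2), stats::quantile, probs = level,
                 names = FALSE)
    pruned <- assoc
    pruned[assoc <= thr] <- 0L
    diag(pruned) <- 0L
    if (all(pruned == 0)) {
      warning("association matrix fully pruned; returning singletons")
      normalize_partition(seq_len(n), rownames(assoc))
    } else {
      ig <- igraph::graph_from_adjacency_matrix(
        pruned, mode = "undirected", weighted = TRUE, diag = FALSE)
      normalize_partition(
        as.integer(igraph::membership(igraph::cluster_louvain(ig))),
        rownames(assoc))
    }
  })
}

#' Consensus clustering of a weighted graph
#'
#' Convenience wrapper running [detect_partitions()],
#' [association_matrix()] and [consensus_partition()] in sequence.
#'
#' @inheritParams detect_partitions
#' @inheritParams consensus_partition
#' @return integer membership vector.
#' @export
consensus_cluster <- function(g, n_runs_per_algo = 100, seed = 1L,
                              n_null = 100, level = 0.95) {
  parts <- detect_partitions(g, n_runs_per_algo, seed)
  consensus_partition(association_matrix(parts), parts, seed,
                      n_null, level)
}

#' Normalized mutual information between two partitions
#'
#' @param a,b membership vectors over the same nodes.
#' @return NMI in \[0, 1\]; 1 for identical partitions.
#' @export
partition_nmi <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "nmi")
}

weighted_within_degree <- function(adj, part) {
  vapply(seq_len(nrow(adj)), function(i)
    sum(adj[i, part == part[i]]), 0)
}

#' Within-module degree z-score
#'
#' For node i in module m, `Z_i = (K_i(m) - mean_m K) / sd_m K`, where
#' `K_i(m)` is the weighted within-module degree and mean and population
#' standard deviation are taken over the nodes of module m. Modules with
#' zero spread (including singletons) get Z = 0 for all members.
#'
#' @param g a `thresh_graph`.
#' @param part membership vector covering the graph's nodes.
#' @return named numeric vector of z-scores.
#' @export
within_module_zscore <- function(g, part) {
  adj <- g$adj
  if (length(part) != nrow(adj)) stop("partition does not cover the graph")
  k <- weighted_within_degree(adj, part)
  z <- numeric(length(k))
  for (m in unique(part)) {
    idx <- part == m
    mu <- mean(k[idx])
    s <- sqrt(mean((k[idx] - mu)^2))   # population sd
    z[idx] <- if (s > 0) (k[idx] - mu) / s else 0
  }
  stats::setNames(z, g$labels)
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (K_i(m) / K_i)^2` over modules m, with weighted
#' degrees; 0 when all of a node's weight stays inside one module, up to
#' `1 - 1/M` for weight spread evenly over M modules. Isolated nodes get
#' P = 0.
#'
#' @inheritParams within_module_zscore
#' @return named numeric vector in \[0, 1).
#' @export
participation_coefficient <- function(g, part) {
  adj <- g$adj
  if (length(part) != nrow(adj)) stop("partition does not cover the graph")
  ktot <- rowSums(adj)
  p <- vapply(seq_len(nrow(adj)), function(i) {
    if (ktot[i] == 0) return(0)
    km <- vapply(unique(part), function(m) sum(adj[i, part == m]), 0)
    1 - sum((km / ktot[i])^2)
  }, 0)
  stats::setNames(p, g$labels)
}

#' Classify nodes into non-hub, provincial and connector hubs
#'
#' Nodes with within-module z-score above 1.5 are hubs; among hubs, a
#' participation coefficient below 0.3 marks a provincial hub (edges
#' mostly inside its own module) and 0.3 or above a connector hub (edges
#' spread across modules). Boundary values Z = 1.5 and P = 0.3 fall to
#' non-hub and connector respectively.
#'
#' @param z named vector of within-module z-scores.
#' @param p named vector of participation coefficients (same nodes).
#' @param z_thresh,p_thresh classification thresholds (defaults 1.5, 0.3).
#' @return data.frame of class `hub_class` with columns `node`, `Z`, `P`,
#'   `label`.
#' @export
classify_hubs <- function(z, p, z_thresh = 1.5, p_thresh = 0.3) {
  if (length(z) != length(p)) stop("Z and P must cover the same nodes")
  label <- ifelse(z > z_thresh,
                  ifelse(p < p_thresh, "provincial", "connector"),
                  "non-hub")
  out <- data.frame(node = names(z) %||% seq_along(z),
                    Z = as.numeric(z), P = as.numeric(p),
                    label = label, row.names = NULL)
  class(out) <- c("hub_class", "data.frame")
  out
}
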