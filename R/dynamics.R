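# Per-window hub extraction, transition matrices, RSN occupancy and
# hub-role timecourses.

#' Per-window metric tables
#'
#' Applies the thresholding + metric stage to every window of a
#' [plv_dynamic()] result.
#'
#' @param wc a `windowed_plv`.
#' @param proportion proportional threshold per window.
#' @param n_surrogates surrogates per window for normalization; 0 skips
#'   normalization (raw metrics only), which is the fast default for long
#'   window sequences.
#' @param seed integer seed.
#' @param length_map weight-to-length map for path-based metrics.
#' @return list of per-window metric data.frames (see
#'   [normalize_metrics()]).
#' @export
windowed_metrics <- function(wc, proportion = 0.10, n_surrogates = 0,
                             seed = 1L, length_map = "inverse") {
  stopifnot(inherits(wc, "windowed_plv"))
  lapply(seq_along(wc$matrices), function(k) {
    g <- proportional_threshold(wc$matrices[[k]], proportion)
    if (n_surrogates > 0) {
      normalize_metrics(g, n_surrogates, seed + k, length_map)
    } else {
      raw <- raw_metrics(g, length_map)
      out <- data.frame(node = g$labels, raw, row.names = NULL)
      class(out) <- c("node_metrics", "data.frame")
      out
    }
  })
}

#' Top node of each window for one metric
#'
#' The argmax node per window; ties are broken by the lowest node index.
#'
#' @param wc_metrics list of per-window metric data.frames
#'   ([windowed_metrics()]).
#' @param metric column name, e.g. `"bc"`, `"vuln"`, `"strength"`,
#'   `"clustering"` (or a normalized variant).
#' @return integer vector of node indices, one per window.
#' @export
top_node_per_window <- function(wc_metrics, metric) {
  if (!length(wc_metrics)) stop("need at least one window")
  vapply(wc_metrics, function(m) {
    v <- m[[metric]]
    if (is.null(v)) stop(sprintf("unknown metric '%s'", metric))
    which.max(v)   # first maximum = lowest index on ties
  }, 0L)
}

#' Transition matrix of a top-node sequence
#'
#' Counts consecutive-window changes of the top node: entry (i, j) is
#' incremented for every pair (top at window w, top at window w + 1).
#' Self-persistence pairs (i = j) are counted by default.
#'
#' @param top_seq integer sequence of node indices.
#' @param n_nodes number of nodes.
#' @param include_self count i = j pairs (default `TRUE`).
#' @return object of class `transition_matrix`: integer matrix with
#'   attribute `n_transitions`.
#' @export
transition_matrix <- function(top_seq, n_nodes, include_self = TRUE) {
  if (!length(top_seq)) stop("need a sequence of length >= 1")
  if (any(top_seq < 1 | top_seq > n_nodes))
    stop("node id out of range")
  tm <- matrix(0L, n_nodes, n_nodes)
  if (length(top_seq) > 1L) {
    from <- top_seq[-length(top_seq)]
    to <- top_seq[-1L]
    if (!include_self) {
      keep <- from != to
      from <- from[keep]; to <- to[keep]
    }
    for (k in seq_along(from))
      tm[from[k], to[k]] <- tm[from[k], to[k]] + 1L
  }
  structure(tm, n_transitions = sum(tm), class = "transition_matrix")
}

#' Significant nodes of each window
#'
#' Operationalizes "the nodes dominating a window" as those whose metric
#' exceeds the window's mean + `n_sd` standard deviations, always
#' including at least the argmax node.
#'
#' @inheritParams top_node_per_window
#' @param n_sd standard-deviation multiplier (default 2).
#' @return list of integer node-index vectors, one per window.
#' @export
significant_nodes_per_window <- function(wc_metrics, metric, n_sd = 2) {
  lapply(wc_metrics, function(m) {
    v <- m[[metric]]
    if (is.null(v)) stop(sprintf("unknown metric '%s'", metric))
    thr <- mean(v) + n_sd * stats::sd(v)
    idx <- which(v > thr)
    if (!length(idx)) idx <- which.max(v)
    idx
  })
}

#' Fractional occupancy of resting-state networks
#'
#' Labels each window by the RSN holding a strict majority of that
#' window's significant nodes ("Other" when no strict majority exists;
#' windows with an empty node set are excluded from the rates) and
#' returns the occurrence rate of each label.
#'
#' @param sig_nodes list of node-index vectors per window
#'   ([significant_nodes_per_window()]).
#' @param affiliation character vector mapping every node to an RSN label
#'   (e.g. `"DMN"`, `"DAN"`, `"SAN"`, `"AUD"`, `"VIS"`, `"Other"`).
#' @return object of class `occupancy_table`: list with `rates` (named,
#'   summing to 1 over labeled windows), `window_labels`, `n_excluded`.
#' @export
rsn_occupancy <- function(sig_nodes, affiliation) {
  labs <- vapply(sig_nodes, function(idx) {
    if (!length(idx)) return(NA_character_)
    if (any(idx > length(affiliation)))
      stop("affiliation does not cover all nodes")
    tab <- table(affiliation[idx])
    top <- which(tab == max(tab))
    if (length(top) > 1 || max(tab) * 2 <= length(idx)) "Other"
    else names(tab)[top]
  }, "")
  n_excluded <- sum(is.na(labs))
  labs_ok <- labs[!is.na(labs)]
  rates <- if (length(labs_ok)) table(labs_ok) / length(labs_ok)
           else table(character())
  structure(list(rates = c(rates), window_labels = labs,
                 n_excluded = n_excluded),
            class = "occupancy_table")
}

#' Hub-role timecourse
#'
#' Collects per-window hub classifications into a node x window label
#' matrix plus per-node counts of provincial and connector assignments.
#'
#' @param per_window_class list of `hub_class` data.frames
#'   ([classify_hubs()]), one per window, over a consistent node set.
#' @return object of class `role_timecourse`: list with `labels` (node x
#'   window character matrix) and `counts` (data.frame with per-node
#'   provincial/connector counts).
#' @export
role_timecourse <- function(per_window_class) {
  if (!length(per_window_class)) stop("need at least one window")
  nodes <- per_window_class[[1]]$node
  lab <- vapply(per_window_class, function(h) {
    if (!identical(h$node, nodes))
      stop("inconsistent node sets across windows")
    h$label
  }, character(length(nodes)))
  lab <- matrix(lab, nrow = length(nodes),
                dimnames = list(nodes, NULL))
  counts <- data.frame(
    node = nodes,
    provincial = rowSums(lab == "provincial"),
    connector = rowSums(lab == "connector"),
    row.names = NULL)
  structure(list(labels = lab, counts = counts),
            class = "role_timecourse")
}
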