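# Weighted minimum-norm source estimation and atlas aggregation.

#' Build a weighted minimum-norm inverse operator
#'
#' Constructs the linear kernel
#' \deqn{K = (G^T W G + \lambda I)^{-1} G^T W}
#' where `G` is the lead-field gain matrix and `W` is a diagonal weighting
#' matrix with entries inversely proportional to the squared norm of the
#' corresponding lead-field column. The weighting counteracts the
#' minimum-norm bias toward superficial (large-gain) sources.
#'
#' @param lf a `lead_field`.
#' @param lambda scalar regularization parameter (>= 0, default 0.2).
#' @return object of class `inverse_operator` with elements `kernel`
#'   (sources x channels), `lambda`, `weight_diag`.
#' @export
build_wmne_operator <- function(lf, lambda = 0.2) {
  stopifnot(inherits(lf, "lead_field"))
  if (lambda < 0) stop("lambda must be non-negative")
  g <- lf$gain
  cn2 <- colSums(g^2)
  if (any(cn2 == 0)) stop("lead field has an all-zero column")
  w <- 1 / cn2
  gtw <- t(g) * w                    # row p of t(G) scaled by w_p: G^T W
  a <- gtw %*% g
  diag(a) <- diag(a) + lambda
  kernel <- solve(a, gtw)
  structure(list(kernel = kernel, lambda = lambda, weight_diag = w),
            class = "inverse_operator")
}

#' Apply an inverse operator to a scalp recording
#'
#' Sample-by-sample linear mapping `S_hat = K X` from channel space to
#' source space.
#'
#' @param op an `inverse_operator`.
#' @param rec a `scalp_rec`.
#' @return a [region_ts()] holding one time series per source (vertex
#'   level; see [aggregate_atlas()] for region level).
#' @export
apply_inverse <- function(op, rec) {
  stopifnot(inherits(op, "inverse_operator"), inherits(rec, "scalp_rec"))
  if (ncol(op$kernel) != nrow(rec$data))
    stop("operator channel count does not match recording")
  s <- op$kernel %*% rec$data
  region_ts(s, rec$fs, "broadband", paste0("S", seq_len(nrow(s))))
}

#' Aggregate vertex-level source series into atlas regions
#'
#' Averages the member-vertex time series of each region after sign
#' alignment: a vertex whose correlation with the region's first vertex is
#' negative is flipped before averaging, so anti-phase vertices (an
#' orientation artifact of normal-constrained source models) do not cancel.
#'
#' @param vertex_ts a [region_ts()] of vertex source series.
#' @param atlas either an integer vector mapping each vertex to a region id,
#'   or a named list of integer vertex-index vectors (one per region).
#' @param region_labels optional region names.
#' @return a [region_ts()] with one series per region.
#' @export
aggregate_atlas <- function(vertex_ts, atlas, region_labels = NULL) {
  stopifnot(inherits(vertex_ts, "region_ts"))
  x <- vertex_ts$data
  if (!is.list(atlas)) {
    if (length(atlas) != nrow(x))
      stop("atlas map must cover every vertex")
    atlas <- split(seq_len(nrow(x)), atlas)
  }
  if (any(vapply(atlas, length, 0L) == 0L)) stop("empty atlas region")
  out <- t(vapply(atlas, function(idx) {
    sub <- x[idx, , drop = FALSE]
    if (length(idx) > 1L) {
      ref <- sub[1L, ]
      for (r in 2:nrow(sub)) {
        cc <- suppressWarnings(cor(ref, sub[r, ]))
        if (!is.na(cc) && cc < 0) sub[r, ] <- -sub[r, ]
      }
    }
    colMeans(sub)
  }, numeric(ncol(x))))
  labs <- region_labels %||% names(atlas) %||% paste0("R", seq_len(nrow(out)))
  region_ts(out, vertex_ts$fs, vertex_ts$band, labs)
}
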