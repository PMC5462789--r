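# Node-, column- and role-level significance testing with Bonferroni
# correction.

#' Bonferroni significance flags
#'
#' An item is significant when its raw p-value is below
#' `alpha / length(p_values)`.
#'
#' @param p_values numeric vector of raw p-values.
#' @param alpha family-wise level in (0, 1).
#' @return logical vector of flags (empty for empty input).
#' @export
bonferroni <- function(p_values, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!length(p_values)) return(logical(0))
  p_values < alpha / length(p_values)
}

significance_result <- function(item, statistic, p, alpha, test) {
  flag <- bonferroni(p, alpha)
  out <- data.frame(item = item, statistic = statistic, p = p,
                    significant = flag, row.names = NULL)
  attr(out, "test") <- test
  attr(out, "alpha") <- alpha
  attr(out, "n_comparisons") <- length(p)
  class(out) <- c("significance_result", "data.frame")
  out
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d significant at alpha = %g (Bonferroni over %d)\n",
              attr(x, "test"), sum(x$significant), nrow(x),
              attr(x, "alpha"), attr(x, "n_comparisons")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Node-level significance of a metric distribution
#'
#' For each node, a two-sided Wilcoxon rank-sum test of that node's metric
#' samples (across windows/epochs) against the pooled samples of all other
#' nodes, Bonferroni-corrected over nodes. Nodes whose samples plus pool
#' are constant get p = 1.
#'
#' @param metric_samples named list: one numeric vector of samples per
#'   node (each of length >= 2).
#' @param alpha family-wise level (default 0.01).
#' @return a `significance_result` (one row per node).
#' @export
node_significance <- function(metric_samples, alpha = 0.01) {
  if (any(vapply(metric_samples, length, 0L) < 2))
    stop("need >= 2 samples per node")
  nodes <- names(metric_samples) %||% seq_along(metric_samples)
  res <- lapply(seq_along(metric_samples), function(i) {
    x <- metric_samples[[i]]
    y <- unlist(metric_samples[-i], use.names = FALSE)
    if (length(unique(c(x, y))) == 1L)
      return(list(stat = NA_real_, p = 1))
    wt <- suppressWarnings(wilcox.test(x, y))
    list(stat = unname(wt$statistic), p = wt$p.value)
  })
  significance_result(nodes,
                      vapply(res, `[[`, 0, "stat"),
                      vapply(res, `[[`, 0, "p"),
                      alpha, "wilcoxon rank-sum vs pooled others")
}

#' Column significance of a transition matrix
#'
#' Tests each destination column against a uniform-destination null: the
#' observed count of transitions into node j is compared to Binomial(n =
#' total transitions, p = 1/N) with a one-sided (enrichment) exact
#' binomial test, Bonferroni-corrected over the N columns.
#'
#' @param tm a `transition_matrix`.
#' @param alpha family-wise level (default 0.01).
#' @return a `significance_result` (one row per column), or an empty one
#'   if the matrix has no transitions or a single node.
#' @export
column_significance <- function(tm, alpha = 0.01) {
  n <- ncol(tm)
  total <- sum(tm)
  if (total < 1 || n < 2)
    return(significance_result(character(0), numeric(0), numeric(0),
                               alpha, "binomial column enrichment"))
  counts <- colSums(unclass(tm))
  p <- vapply(counts, function(k)
    binom.test(k, total, 1 / n, alternative = "greater")$p.value, 0)
  significance_result(colnames(tm) %||% seq_len(n), as.numeric(counts), p,
                      alpha, "binomial column enrichment")
}

#' Role significance of a hub-role timecourse
#'
#' For each node and role (provincial, connector), a goodness-of-fit test
#' of the node's binary role-indicator counts against the pooled
#' across-node proportion of that role: chi-squared without continuity
#' correction, falling back to an exact binomial test when an expected
#' count is below 5. Bonferroni correction is over nodes, separately per
#' role; a role with pooled proportion 0 or 1 is skipped. The significant
#' provincial and connector sets may overlap.
#'
#' @param rt a `role_timecourse`.
#' @param alpha family-wise level (default 0.01).
#' @return named list with elements `provincial` and `connector`, each a
#'   `significance_result` or `NULL` when skipped.
#' @export
role_significance <- function(rt, alpha = 0.01) {
  lab <- rt$labels
  if (ncol(lab) < 2) stop("need >= 2 windows")
  n_w <- ncol(lab)
  out <- list()
  for (role in c("provincial", "connector")) {
    ind <- lab == role
    p0 <- mean(ind)
    if (p0 <= 0 || p0 >= 1) {
      out[[role]] <- NULL
      next
    }
    pv <- apply(ind, 1L, function(b) {
      k <- sum(b)
      expd <- n_w * c(p0, 1 - p0)
      if (any(expd < 5)) {
        binom.test(k, n_w, p0)$p.value
      } else {
        suppressWarnings(
          chisq.test(c(k, n_w - k), p = c(p0, 1 - p0),
                     correct = FALSE)$p.value)
      }
    })
    stat <- rowSums(ind)
    out[[role]] <- significance_result(
      rownames(lab), as.numeric(stat), as.numeric(pv), alpha,
      sprintf("chi-squared %s-role enrichment", role))
  }
  out
}
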