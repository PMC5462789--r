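# planted-partition random graph: edge probability p_in within blocks,
# p_out across, unit weights
planted_graph <- function(n_blocks, block_size, p_in, p_out) {
  n <- n_blocks * block_size
  memb <- rep(seq_len(n_blocks), each = block_size)
  adj <- matrix(0, n, n)
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  same <- memb[idx[, 1]] == memb[idx[, 2]]
  on <- runif(nrow(idx)) < ifelse(same, p_in, p_out)
  adj[idx[on, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- paste0("R", seq_len(n))
  list(g = structure(list(adj = adj, proportion = 1, n_edges = sum(on),
                          labels = rownames(adj)),
                     class = "thresh_graph"),
       truth = memb)
}

test_that("two cliques joined by a weak edge are always split apart", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[5, 6] <- adj[6, 5] <- 0.1
  rownames(adj) <- colnames(adj) <- paste0("R", 1:10)
  g <- structure(list(adj = adj, proportion = 1, n_edges = 21,
                      labels = rownames(adj)), class = "thresh_graph")
  parts <- detect_partitions(g, n_runs_per_algo = 5, seed = 1)
  expect_length(parts, 15)
  planted <- rep(1:2, each = 5)
  expect_true(all(vapply(parts, partition_nmi, 0, b = planted) == 1))
  expect_identical(parts, detect_partitions(g, n_runs_per_algo = 5,
                                            seed = 1))
})

test_that("association matrix counts co-assignments", {
  p1 <- c(a = 1L, b = 1L, c = 2L)   # {ab | c}
  p2 <- c(a = 1L, b = 2L, c = 2L)   # {a | bc}
  am <- association_matrix(list(p1, p2))
  expect_equal(unname(diag(am)), c(2, 2, 2))
  expect_equal(am["a", "b"], 1)
  expect_equal(am["b", "c"], 1)
  expect_equal(am["a", "c"], 0)

  same <- replicate(300, c(x = 1L, y = 1L, z = 2L), simplify = FALSE)
  am2 <- association_matrix(same)
  expect_true(all(am2 %in% c(0L, 300L)))
  expect_error(association_matrix(list(p1, c(a = 1L))), "inconsistent")
})

test_that("consensus of identical partitions returns that partition", {
  p <- c(rep(1L, 4), rep(2L, 4), rep(3L, 4))
  names(p) <- paste0("R", 1:12)
  parts <- replicate(30, p, simplify = FALSE)
  cons <- consensus_partition(association_matrix(parts), parts, seed = 3)
  expect_equal(partition_nmi(cons, p), 1)
})

test_that("consensus clustering recovers planted partitions", {
  # dense contrast: exact recovery expected
  set.seed(101)
  pg <- planted_graph(4, 10, 0.9, 0.05)
  cons <- consensus_cluster(pg$g, n_runs_per_algo = 5, seed = 1)
  expect_equal(partition_nmi(cons, pg$truth), 1)

  # weak contrast (p_in 0.6 / p_out 0.2): each node has more external
  # than internal edges, the planted partition is no longer the
  # modularity optimum, and recovery is partial by construction; the
  # consensus must still carry substantial planted signal
  nmis <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    pg <- planted_graph(4, 10, 0.6, 0.2)
    partition_nmi(consensus_cluster(pg$g, n_runs_per_algo = 5, seed = s),
                  pg$truth)
  }, 0)
  expect_gte(median(nmis), 0.4)
})

test_that("consensus on unstructured ensembles does not invent one block", {
  big_block <- vapply(1:8, function(s) {
    set.seed(s)
    parts <- replicate(30, {
      m <- sample(1:4, 20, replace = TRUE)
      normalize_partition_for_test(m)
    }, simplify = FALSE)
    cons <- suppressWarnings(
      consensus_partition(association_matrix(parts), parts, seed = s))
    max(table(cons))
  }, 0)
  expect_gte(mean(big_block <= 15), 0.95)
})

test_that("within-module z-score matches the hand-computed toy case", {
  # module of 3 with within-degrees (2, 1, 1), plus an isolated module
  g <- tg_from_edges(5, c(1, 1, 4), c(2, 3, 5))
  part <- c(1L, 1L, 1L, 2L, 2L)
  z <- within_module_zscore(g, part)
  expect_equal(unname(z[1:3]), c(sqrt(2), -1 / sqrt(2), -1 / sqrt(2)),
               tolerance = 1e-9)
  expect_equal(unname(z[1]), 1.414, tolerance = 1e-3)
  expect_equal(unname(z[4:5]), c(0, 0))   # sd = 0 convention
  # z-scores sum to ~0 within each module
  expect_lt(abs(sum(z[1:3])), 1e-12)
  # equal within-degrees: all zero
  zeq <- within_module_zscore(tg_complete(4), rep(1L, 4))
  expect_equal(unname(zeq), rep(0, 4))
})

test_that("participation coefficient matches its closed forms", {
  # all weight inside the own module
  g1 <- tg_from_edges(4, c(1, 1), c(2, 3))
  expect_equal(unname(participation_coefficient(
    g1, c(1L, 1L, 1L, 2L))), c(0, 0, 0, 0))
  # weight split equally across two modules
  g2 <- tg_from_edges(4, c(1, 1), c(2, 3), c(0.5, 0.5))
  expect_equal(unname(participation_coefficient(
    g2, c(1L, 1L, 2L, 2L))[1]), 0.5)
  # degree 4: three edges inside, one outside
  g3 <- tg_from_edges(6, c(1, 1, 1, 1), c(2, 3, 4, 5))
  p3 <- participation_coefficient(g3, c(1L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(unname(p3[1]), 1 - (9 / 16 + 1 / 16))
  expect_equal(unname(p3[1]), 0.375)
  # invariant under global weight rescaling, bounded by 1 - 1/M
  g4 <- g3; g4$adj <- g3$adj * 7.3
  expect_equal(participation_coefficient(g4, c(1L, 1L, 1L, 1L, 2L, 2L)),
               p3)
  expect_true(all(p3 <= 1 - 1 / 2 + 1e-12))
})

test_that("hub classification applies the Z and P thresholds", {
  z <- c(a = 2.0, b = 2.0, c = 1.0, d = 1.5, e = 2.0)
  p <- c(a = 0.2, b = 0.5, c = 0.9, d = 0.1, e = 0.3)
  h <- classify_hubs(z, p)
  expect_equal(h$label,
               c("provincial", "connector", "non-hub",
                 "non-hub",      # Z = 1.5 boundary -> non-hub
                 "connector"))   # P = 0.3 boundary -> connector
})

test_that("planted hub roles are recovered end-to-end across seeds", {
  res <- vapply(1:8, function(s) {
    cfg <- synth_config(n_regions = 18, module_sizes = rep(6, 3),
                        fs = 200, duration = 40, noise_sd = 0.1, seed = s,
                        hub_spec = list(
                          list(node = 1, role = "provincial"),
                          list(node = 7, role = "connector")))
    g <- gen_coupled_sources(cfg)
    tg <- proportional_threshold(
      plv_static(instantaneous_phase(g$ts)), 0.35)
    part <- consensus_cluster(tg, n_runs_per_algo = 5, seed = s)
    h <- classify_hubs(within_module_zscore(tg, part),
                       participation_coefficient(tg, part))
    c(h$label[1] == "provincial", h$label[7] == "connector",
      h$P[7] > h$P[1])
  }, logical(3))
  expect_gte(mean(res[1, ]), 7 / 8)
  expect_gte(mean(res[2, ]), 7 / 8)
  expect_true(all(res[3, ]))
})
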