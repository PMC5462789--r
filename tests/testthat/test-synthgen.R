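test_that("generator config validation catches inconsistent inputs", {
  expect_error(synth_config(n_regions = 10, module_sizes = c(4, 4)),
               "sum to n_regions")
  expect_error(synth_config(kappa_within = 0.3, kappa_between = 0.5),
               "kappa")
  expect_error(synth_config(n_regions = 6, module_sizes = c(3, 3),
                            duration = 10,
                            regime_schedule = list(list(start = 5, end = 12))),
               "outside")
  expect_error(synth_config(n_regions = 6, module_sizes = c(3, 3),
                            duration = 10,
                            regime_schedule = list(
                              list(start = 0, end = 6),
                              list(start = 4, end = 10))),
               "overlap")
  expect_error(synth_config(n_regions = 6, module_sizes = c(3, 3),
                            hub_spec = list(list(node = 9,
                                                 role = "provincial"))),
               "out of range")
})

test_that("fully driven modules are perfectly phase locked", {
  cfg <- synth_config(n_regions = 12, module_sizes = c(4, 4, 4), fs = 200,
                      duration = 5, kappa_within = 1, kappa_between = 0,
                      noise_sd = 0, seed = 11)
  g <- gen_coupled_sources(cfg)
  plv <- plv_static(instantaneous_phase(g$ts))
  within <- rbind(c(1, 2), c(3, 4), c(5, 8), c(9, 12))
  expect_true(all(abs(plv[within] - 1) < 1e-6))
  # across modules the drivers are independent: no perfect locking
  expect_lt(plv[1, 5], 0.999)
})

test_that("the generator is deterministic given its seed", {
  cfg <- synth_config(n_regions = 6, module_sizes = c(3, 3), fs = 200,
                      duration = 2, seed = 42)
  a <- gen_coupled_sources(cfg)
  b <- gen_coupled_sources(cfg)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$truth$partition, b$truth$partition)
  cfg2 <- synth_config(n_regions = 6, module_sizes = c(3, 3), fs = 200,
                       duration = 2, seed = 43)
  expect_false(identical(gen_coupled_sources(cfg2)$ts$data, a$ts$data))
})

test_that("mean within-module PLV is non-decreasing in kappa_within", {
  kappas <- c(0, 0.25, 0.5, 0.75, 1)
  seeds <- 1:5
  curves <- vapply(seeds, function(s) {
    vapply(kappas, function(k) {
      cfg <- synth_config(n_regions = 6, module_sizes = c(3, 3), fs = 200,
                          duration = 10, kappa_within = k,
                          kappa_between = 0, noise_sd = 0, seed = s)
      plv <- plv_static(instantaneous_phase(gen_coupled_sources(cfg)$ts))
      mean(plv[rbind(c(1, 2), c(1, 3), c(2, 3),
                     c(4, 5), c(4, 6), c(5, 6))])
    }, 0)
  }, numeric(length(kappas)))
  means <- rowMeans(curves)
  seed_sd <- apply(curves, 1L, sd)
  tol <- 2 * max(seed_sd)
  expect_true(all(diff(means) > -tol))
  expect_gt(means[length(kappas)] - means[1], 0.5)  # strong overall rise
})

test_that("signal power stays inside the carrier band without noise", {
  cfg <- synth_config(n_regions = 4, module_sizes = c(2, 2), fs = 200,
                      duration = 20, noise_sd = 0, seed = 3)
  x <- gen_coupled_sources(cfg)$ts$data
  for (i in seq_len(nrow(x))) {
    sp <- Mod(fft(x[i, ]))^2
    f <- (seq_along(sp) - 1) * 200 / length(sp)
    half <- f <= 100
    frac_in <- sum(sp[half & f >= 14 & f <= 25]) / sum(sp[half])
    expect_gt(frac_in, 0.95)
  }
})

test_that("planted connector exceeds planted provincial in participation", {
  # kappa contrast 0.5 (0.55 within vs 0.05 between), default hub strengths
  hits <- vapply(1:10, function(s) {
    cfg <- synth_config(n_regions = 18, module_sizes = rep(6, 3), fs = 200,
                        duration = 20, noise_sd = 0.1, seed = s,
                        hub_spec = list(
                          list(node = 1, role = "provincial"),
                          list(node = 7, role = "connector")))
    g <- gen_coupled_sources(cfg)
    tg <- proportional_threshold(
      plv_static(instantaneous_phase(g$ts)), 0.35)
    p <- participation_coefficient(tg, g$truth$partition)
    p[7] > p[1]
  }, TRUE)
  expect_true(all(hits))
})

test_that("regime schedule switches hub weights at block boundaries", {
  # two nodes fully locked to their module driver in regime 1 only,
  # against an otherwise uncoupled background
  cfg <- synth_config(
    n_regions = 6, module_sizes = c(3, 3), fs = 200, duration = 8,
    noise_sd = 0, seed = 9, kappa_within = 0, kappa_between = 0,
    regime_schedule = list(
      list(start = 0, end = 4,
           hub_spec = list(
             list(node = 1, role = "provincial", strength = 1),
             list(node = 2, role = "provincial", strength = 1))),
      list(start = 4, end = 8, hub_spec = list())))
  g <- gen_coupled_sources(cfg)
  ph <- instantaneous_phase(g$ts)
  half <- function(idx) structure(
    list(phases = ph$phases[, idx], fs = 200, band = ph$band,
         labels = ph$labels), class = "phase_series")
  p1 <- plv_static(half(1:800))
  p2 <- plv_static(half(801:1600))
  expect_gt(p1[1, 2], 0.95)           # locked while the regime is active
  expect_gt(p1[1, 2] - p2[1, 2], 0.3) # and released afterwards
  roles <- gt_window_roles(g$truth, c(0, 4), 4)
  expect_equal(unname(roles[1, ]), c("provincial", "non-hub"))
  # theoretical coupling matrices reflect the regime weights
  expect_equal(g$truth$coupling_matrix_per_regime[[1]][1, 2], 1)
  expect_equal(g$truth$coupling_matrix_per_regime[[2]][1, 2], 0)
})

test_that("toy lead field has unit-norm rows, no dead sources, identity option", {
  lf <- gen_toy_leadfield(8, 24, seed = 4)
  expect_equal(dim(lf$gain), c(8, 24))
  expect_equal(sqrt(rowSums(lf$gain^2)), rep(1, 8))
  expect_true(all(colSums(abs(lf$gain)) > 0))
  expect_identical(lf$gain, gen_toy_leadfield(8, 24, seed = 4)$gain)
  expect_false(identical(lf$gain, gen_toy_leadfield(8, 24, seed = 5)$gain))
  expect_equal(gen_toy_leadfield(4, 4, identity = TRUE)$gain, diag(4))
  expect_error(gen_toy_leadfield(1, 4), "channels")
  expect_error(gen_toy_leadfield(8, 4), "n_sources")
})

test_that("scalp projection is X = G S + N with the requested noise level", {
  src <- region_ts(matrix(rnorm(4 * 100), 4), fs = 100)
  lf <- gen_toy_leadfield(4, 4, identity = TRUE)
  rec <- project_to_scalp(lf, src, noise_sd = 0)
  expect_equal(rec$data, unname(src$data), ignore_attr = TRUE)

  ones <- gen_toy_leadfield(2, 4, seed = 1)
  ones$gain <- matrix(1, 2, 4)
  rec2 <- project_to_scalp(ones, src, noise_sd = 0)
  expect_equal(rec2$data[1, ], colSums(src$data), ignore_attr = TRUE)

  big <- region_ts(matrix(rnorm(2 * 40000), 2), fs = 1000)
  lf2 <- gen_toy_leadfield(2, 2, identity = TRUE)
  rec3 <- project_to_scalp(lf2, big, noise_sd = 0.5, seed = 7)
  resid <- rec3$data - big$data
  expect_lt(abs(var(as.numeric(resid)) - 0.25) / 0.25, 0.05)
})
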