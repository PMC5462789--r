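# Synthetic generator for band-limited phase-coupled region signals with
# planted modules, hubs and piecewise-constant coupling regimes.

#' Configuration for the synthetic phase-coupling generator
#'
#' Builds and validates the configuration object consumed by
#' [gen_coupled_sources()]. Each region is an oscillation
#' \eqn{x_i(t) = a\,\cos\theta_i(t) + \epsilon} whose unwrapped phase is a
#' convex mixture of shared band-limited driver phases and a private phase,
#' so the phase-locking structure of the output is analytically controlled
#' by the mixture weights.
#'
#' @param n_regions number of regions (nodes).
#' @param module_sizes integer vector of module sizes; must sum to
#'   `n_regions`.
#' @param fs sampling rate in Hz.
#' @param duration signal length in seconds.
#' @param carrier_band numeric length-2, band edges in Hz; phases advance at
#'   the band's central frequency.
#' @param kappa_within coupling weight of a node on its own module's driver,
#'   in \[0, 1\].
#' @param kappa_between global coupling weight, in
#'   \[0, `kappa_within`\]; module drivers share a global driver with
#'   weight `kappa_between / kappa_within`, so two nodes of different
#'   modules share driver weight `kappa_between`.
#' @param hub_spec list of hub descriptions, each a list with elements
#'   `node` (index), `role` (`"provincial"` or `"connector"`) and optional
#'   `strength` (own-module driver weight; defaults to
#'   `kappa_within + hub_delta` for a provincial hub and
#'   `kappa_within + hub_delta/2` for a connector). A provincial hub keeps
#'   its remaining weight private; a connector hub spreads it equally over
#'   the other modules' drivers, so both hub types have elevated
#'   within-module degree while only the connector gains strong
#'   cross-module edges.
#' @param regime_schedule optional list of regimes, each a list with
#'   `start` and `end` in seconds and `hub_spec` (replacing the top-level
#'   hub list within that interval). Intervals must be non-overlapping and
#'   inside \[0, duration\]; time outside any regime uses the top-level
#'   `hub_spec`.
#' @param noise_sd standard deviation of additive Gaussian measurement
#'   noise, in signal units (oscillation amplitude is 1).
#' @param hub_delta elevation of a hub's own-module coupling over
#'   `kappa_within` (default 0.2).
#' @param phase_jitter_sd standard deviation of the stationary phase-jitter
#'   process, radians.
#' @param jitter_bandwidth_hz bandwidth of the phase jitter in Hz; sets how
#'   fast independent signals decorrelate. Defaults to a third of the
#'   carrier bandwidth, which keeps modulation sidebands inside the
#'   carrier band.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_regions = 68,
                         module_sizes = NULL,
                         fs = 1000,
                         duration = 40,
                         carrier_band = c(14, 25),
                         kappa_within = 0.55,
                         kappa_between = 0.05,
                         hub_spec = list(),
                         regime_schedule = NULL,
                         noise_sd = 0.1,
                         hub_delta = 0.2,
                         phase_jitter_sd = 1.5,
                         jitter_bandwidth_hz = NULL,
                         seed = 1L) {
  if (is.null(module_sizes)) {
    k <- max(1L, round(n_regions / 17))
    base <- n_regions %/% k
    module_sizes <- rep(base, k)
    module_sizes[seq_len(n_regions - base * k)] <-
      module_sizes[seq_len(n_regions - base * k)] + 1L
  }
  if (sum(module_sizes) != n_regions)
    stop("module_sizes must sum to n_regions")
  if (any(module_sizes < 1)) stop("module sizes must be positive")
  if (!(kappa_between >= 0 && kappa_within <= 1 &&
        kappa_between <= kappa_within))
    stop("need 0 <= kappa_between <= kappa_within <= 1")
  if (length(carrier_band) != 2 || diff(carrier_band) <= 0 ||
      carrier_band[1] <= 0)
    stop("carrier_band must be increasing positive band edges")
  if (carrier_band[2] >= fs / 2) stop("carrier_band exceeds Nyquist")
  if (duration <= 0 || fs <= 0) stop("fs and duration must be positive")
  if (is.null(jitter_bandwidth_hz))
    jitter_bandwidth_hz <- diff(carrier_band) / 3
  membership <- rep(seq_along(module_sizes), module_sizes)
  hub_spec <- lapply(hub_spec, validate_hub, n_regions = n_regions)
  if (!is.null(regime_schedule)) {
    regime_schedule <- lapply(regime_schedule, function(r) {
      if (is.null(r$start) || is.null(r$end) || r$start >= r$end)
        stop("regime must have start < end")
      if (r$start < 0 || r$end > duration)
        stop("regime outside [0, duration]")
      r$hub_spec <- lapply(r$hub_spec %||% list(), validate_hub,
                           n_regions = n_regions)
      r
    })
    ord <- order(vapply(regime_schedule, `[[`, 0, "start"))
    regime_schedule <- regime_schedule[ord]
    starts <- vapply(regime_schedule, `[[`, 0, "start")
    ends <- vapply(regime_schedule, `[[`, 0, "end")
    if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("regime intervals overlap")
  }
  structure(list(
    n_regions = as.integer(n_regions), module_sizes = as.integer(module_sizes),
    membership = membership, fs = fs, duration = duration,
    carrier_band = carrier_band, kappa_within = kappa_within,
    kappa_between = kappa_between, hub_spec = hub_spec,
    regime_schedule = regime_schedule, noise_sd = noise_sd,
    hub_delta = hub_delta, phase_jitter_sd = phase_jitter_sd,
    jitter_bandwidth_hz = jitter_bandwidth_hz, seed = as.integer(seed)
  ), class = "synth_config")
}

validate_hub <- function(h, n_regions) {
  if (is.null(h$node) || h$node < 1 || h$node > n_regions)
    stop("hub node index out of range")
  if (!h$role %in% c("provincial", "connector"))
    stop("hub role must be 'provincial' or 'connector'")
  h$node <- as.integer(h$node)
  h
}

#' Construct a region-level time-series object
#'
#' @param data numeric matrix, regions x samples.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2 band in Hz, or the string "broadband".
#' @param region_labels character vector of region names.
#' @return an object of class `region_ts`.
#' @export
region_ts <- function(data, fs, band = "broadband", region_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("region_ts: non-finite values")
  if (is.null(region_labels))
    region_labels <- rownames(data) %||% paste0("R", seq_len(nrow(data)))
  rownames(data) <- region_labels
  structure(list(data = data, fs = fs, band = band,
                 region_labels = region_labels),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("region_ts: %d regions x %d samples, fs = %g Hz, band = %s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.character(x$band)) x$band
              else paste0("[", x$band[1], ", ", x$band[2], "] Hz")))
  invisible(x)
}

# stationary band-limited phase jitter: white noise low-pass filtered to
# `bw` Hz (4th-order Butterworth, zero phase), rescaled to sd `sd_rad`.
# The steep filter keeps phase-modulation sidebands inside the carrier
# band.
phase_jitter <- function(n, fs, bw, sd_rad) {
  pad <- max(200L, round(2 * fs / bw))
  bf <- signal::butter(4, min(0.99, 2 * bw / fs), type = "low")
  x <- signal::filtfilt(bf, rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  x * (sd_rad / stats::sd(x))
}

# per-node driver mixing weights for one hub configuration;
# rows = nodes, cols = module drivers, last col = private weight
mixing_weights <- function(cfg, hub_spec) {
  m <- length(cfg$module_sizes)
  w <- matrix(0, cfg$n_regions, m)
  kw <- cfg$kappa_within
  for (i in seq_len(cfg$n_regions)) w[i, cfg$membership[i]] <- kw
  for (h in hub_spec) {
    s <- h$strength %||%
      min(1, kw + cfg$hub_delta / if (h$role == "connector") 2 else 1)
    own <- cfg$membership[h$node]
    w[h$node, ] <- 0
    w[h$node, own] <- s
    if (h$role == "connector" && m > 1)
      w[h$node, -own] <- (1 - s) / (m - 1)
  }
  cbind(w, pmax(0, 1 - rowSums(w)))
}

#' Generate phase-coupled region signals with planted ground truth
#'
#' Simulates band-limited oscillations whose pairwise phase locking follows
#' the planted module structure of a [synth_config()]. Each module has a
#' driver phase; module drivers share a global driver with weight
#' `kappa_between / kappa_within`, and each node mixes its module driver
#' with a private phase. Hubs get modified mixture weights (see
#' [synth_config()]), and a `regime_schedule` switches hub weights over
#' time, instantaneously at regime boundaries. All phases advance at the
#' band's central frequency with stationary band-limited jitter, so signal
#' power stays inside `carrier_band`.
#'
#' @param config a `synth_config`.
#' @return list with elements `ts` (a [region_ts()]), `phases` (regions x
#'   samples matrix of the noiseless unwrapped phases) and `truth`, a
#'   `ground_truth` object holding the planted `partition`, the
#'   per-interval hub roles (`regimes`), and per-interval theoretical
#'   coupling matrices (shared-driver weight products).
#' @export
gen_coupled_sources <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n_t <- round(cfg$duration * cfg$fs)
  m <- length(cfg$module_sizes)
  fc <- mean(cfg$carrier_band)
  trend <- 2 * pi * fc * (seq_len(n_t) - 1L) / cfg$fs

  with_seed(stage_seed(cfg$seed, "synthgen"), {
    jit <- function() phase_jitter(n_t, cfg$fs, cfg$jitter_bandwidth_hz,
                                   cfg$phase_jitter_sd)
    psi_g <- jit()
    beta <- if (cfg$kappa_within > 0) cfg$kappa_between / cfg$kappa_within else 0
    drivers <- vapply(seq_len(m),
                      function(k) beta * psi_g + (1 - beta) * jit(),
                      numeric(n_t))                       # n_t x m
    private <- vapply(seq_len(cfg$n_regions), function(i) jit(),
                      numeric(n_t))                       # n_t x R

    intervals <- regime_intervals(cfg)
    phases <- matrix(0, cfg$n_regions, n_t)
    coupling <- vector("list", length(intervals))
    for (k in seq_along(intervals)) {
      iv <- intervals[[k]]
      idx <- iv$from:iv$to
      w <- mixing_weights(cfg, iv$hub_spec)
      dev <- w[, seq_len(m), drop = FALSE] %*% t(drivers[idx, , drop = FALSE]) +
        w[, m + 1L] * t(private[idx, , drop = FALSE])
      phases[, idx] <- dev
      wd <- w[, seq_len(m), drop = FALSE]
      wg <- beta * rowSums(wd)         # effective weight on the global driver
      wl <- (1 - beta) * wd            # weights on module-local components
      cm <- wl %*% t(wl) + outer(wg, wg)
      diag(cm) <- 0
      coupling[[k]] <- cm
    }
    phases <- sweep(phases, 2L, trend, `+`)
    x <- cos(phases)
    if (cfg$noise_sd > 0)
      x <- x + matrix(rnorm(length(x), sd = cfg$noise_sd), nrow(x))
  })

  labels <- paste0("R", seq_len(cfg$n_regions))
  ts <- region_ts(x, cfg$fs, cfg$carrier_band, labels)
  truth <- structure(list(
    partition = stats::setNames(cfg$membership, labels),
    regimes = lapply(intervals, function(iv)
      list(start = iv$start, end = iv$end,
           roles = regime_roles(cfg, iv$hub_spec))),
    coupling_matrix_per_regime = coupling,
    config = cfg
  ), class = "ground_truth")
  list(ts = ts, phases = phases, truth = truth)
}

# split [0, duration] into maximal intervals of constant hub configuration
regime_intervals <- function(cfg) {
  n_t <- round(cfg$duration * cfg$fs)
  if (is.null(cfg$regime_schedule))
    return(list(list(start = 0, end = cfg$duration, from = 1L, to = n_t,
                     hub_spec = cfg$hub_spec)))
  cuts <- sort(unique(c(0, cfg$duration,
                        vapply(cfg$regime_schedule, `[[`, 0, "start"),
                        vapply(cfg$regime_schedule, `[[`, 0, "end"))))
  out <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    s <- cuts[k]; e <- cuts[k + 1L]
    if (e - s < 1 / cfg$fs) next
    hs <- cfg$hub_spec
    for (r in cfg$regime_schedule)
      if (r$start <= s && e <= r$end) hs <- r$hub_spec
    from <- floor(s * cfg$fs) + 1L
    to <- min(n_t, floor(e * cfg$fs))
    out[[length(out) + 1L]] <-
      list(start = s, end = e, from = from, to = to, hub_spec = hs)
  }
  out
}

regime_roles <- function(cfg, hub_spec) {
  roles <- rep("non-hub", cfg$n_regions)
  for (h in hub_spec) roles[h$node] <- h$role
  names(roles) <- paste0("R", seq_len(cfg$n_regions))
  roles
}

#' Planted node roles for a set of analysis windows
#'
#' Maps the ground-truth regime schedule onto sliding-window start times:
#' each window carries the role labels of the regime covering the majority
#' of its span.
#'
#' @param truth a `ground_truth` from [gen_coupled_sources()].
#' @param start_times window start times in seconds.
#' @param window window length in seconds.
#' @return character matrix, nodes x windows, of planted role labels.
#' @export
gt_window_roles <- function(truth, start_times, window) {
  regs <- truth$regimes
  vapply(start_times, function(s) {
    overlap <- vapply(regs, function(r)
      max(0, min(r$end, s + window) - max(r$start, s)), 0)
    regs[[which.max(overlap)]]$roles
  }, character(length(regs[[1]]$roles)))
}

#' Generate a toy lead-field matrix
#'
#' A smooth random gain matrix standing in for a biophysical forward model:
#' each channel's gain profile across sources is spatially smoothed noise,
#' row-normalized to unit norm.
#'
#' @param n_channels number of measurement channels (>= 2).
#' @param n_sources number of sources (>= `n_channels`); the
#'   under-determined case `n_channels < n_sources` is the norm.
#' @param sources_per_region sources grouped per region in the
#'   `source_to_region` map (default 1).
#' @param seed integer seed.
#' @param identity if `TRUE` (requires `n_channels == n_sources`), return
#'   the identity gain matrix.
#' @return object of class `lead_field` with elements `gain`
#'   (channels x sources), `channel_labels`, `source_to_region`.
#' @export
gen_toy_leadfield <- function(n_channels, n_sources,
                              sources_per_region = 1L, seed = 1L,
                              identity = FALSE) {
  if (n_channels < 2) stop("need at least 2 channels")
  if (n_sources < n_channels) stop("need n_sources >= n_channels")
  if (identity) {
    if (n_channels != n_sources)
      stop("identity lead field needs n_channels == n_sources")
    g <- diag(n_channels)
  } else {
    g <- with_seed(stage_seed(seed, "leadfield"), {
      raw <- matrix(rnorm(n_channels * n_sources), n_channels)
      # smooth along the source axis so nearby sources load similarly
      k <- max(3L, round(n_sources / 8))
      sm <- t(apply(raw, 1L, function(r) {
        f <- as.numeric(stats::filter(r, rep(1 / k, k), sides = 2L))
        f[is.na(f)] <- r[is.na(f)]
        f
      }))
      sm + 0.1 * raw
    })
    g <- g / sqrt(rowSums(g^2))
    zero_cols <- colSums(abs(g)) == 0
    if (any(zero_cols)) g[1L, zero_cols] <- 1e-6
  }
  s2r <- rep(seq_len(ceiling(n_sources / sources_per_region)),
             each = sources_per_region)[seq_len(n_sources)]
  structure(list(gain = g,
                 channel_labels = paste0("CH", seq_len(n_channels)),
                 source_to_region = s2r),
            class = "lead_field")
}

#' Project source signals to the scalp through a lead field
#'
#' Forward model `X = G S + N` with i.i.d. Gaussian sensor noise.
#'
#' @param lf a `lead_field`.
#' @param src a [region_ts()] holding source signals (rows must match the
#'   lead field's source count).
#' @param noise_sd sensor noise standard deviation (same units as the
#'   projected signal, nominally microvolts).
#' @param seed integer seed for the noise.
#' @return object of class `scalp_rec` with elements `data`
#'   (channels x samples), `fs`, `channel_labels`.
#' @export
project_to_scalp <- function(lf, src, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(lf, "lead_field"), inherits(src, "region_ts"))
  if (ncol(lf$gain) != nrow(src$data))
    stop("lead field source count does not match source signals")
  x <- lf$gain %*% src$data
  if (noise_sd > 0)
    x <- x + with_seed(stage_seed(seed, "scalpnoise"),
                       matrix(rnorm(length(x), sd = noise_sd), nrow(x)))
  structure(list(data = x, fs = src$fs, channel_labels = lf$channel_labels),
            class = "scalp_rec")
}
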