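#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif cor sd filter fft wilcox.test chisq.test
#'   binom.test quantile median
#' @importFrom utils head tail combn
NULL

# Derive a per-stage RNG seed from a global seed so that toggling one stage
# never shifts another stage's random stream. Kept below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 131L + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones, keep DC and (for even n) Nyquist.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal: need at least 2 samples")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# round-half-up to the nearest multiple of `unit` (base round() is
# round-half-even, which is the wrong convention here)
round_half_up <- function(x, unit = 1) floor(x / unit + 0.5) * unit

`%||%` <- function(a, b) if (is.null(a)) b else a
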