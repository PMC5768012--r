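#' Uniformly sampled respiratory signal
#'
#' @param times sample times in seconds (uniform).
#' @param amplitudes signal amplitude in arbitrary units (e.g. bellows
#'   pressure); inhale is high, exhale is low.
#' @return A `breathing_trace` object.
#' @export
breathing_trace <- function(times, amplitudes) {
  stopifnot(length(times) == length(amplitudes), length(times) >= 2L)
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6)
    stop("breathing trace must be uniformly sampled", call. = FALSE)
  structure(list(times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes)),
            class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf("breathing_trace: %d samples over %.1f s (%.1f Hz)\n",
              length(x$times), diff(range(x$times)),
              1 / mean(diff(x$times))))
  invisible(x)
}

trace_rate_hz <- function(trace) 1 / mean(diff(trace$times))

#' Generate a synthetic breathing trace
#'
#' Cycles follow the classic raised-cosine-power respiratory model
#' `a(t) = A_i * cos(pi (t - t_i) / T_i)^(2n)` within each breathing cycle
#' `i`, giving a sharp inhale peak and a flat end-exhale dwell for `n > 1`.
#' Cycle periods and amplitudes are jittered multiplicatively by
#' `variability` (Gaussian, truncated at 2.5 sd); with `variability = 0` the
#' trace is exactly periodic. Deterministic for a fixed seed.
#'
#' @param period_s mean breathing period in seconds (typical clinical range
#'   2.7-6.6 s, average 5 s).
#' @param amplitude peak amplitude in arbitrary units.
#' @param exponent_n cosine power `n` (cycle shape); default 2.
#' @param variability coefficient of variation of period and amplitude.
#' @param duration_s trace length in seconds; must cover >= 2 periods.
#' @param sample_rate_hz sampling rate, >= 10 Hz.
#' @param seed integer seed.
#' @return A [breathing_trace()].
#' @export
generate_breathing_trace <- function(period_s = 5, amplitude = 1,
                                     exponent_n = 2, variability = 0.1,
                                     duration_s = 120, sample_rate_hz = 25,
                                     seed = 1L) {
  stopifnot(period_s > 0, sample_rate_hz >= 10)
  if (duration_s < 2 * period_s)
    stop("duration must cover at least 2 breathing periods", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    n_cycles <- ceiling(duration_s / period_s * (1 + 3 * variability)) + 2L
    jitter <- function(k) {
      e <- stats::rnorm(k)
      e[e > 2.5] <- 2.5
      e[e < -2.5] <- -2.5
      pmax(0.2, 1 + variability * e)
    }
    periods <- period_s * jitter(n_cycles)
    amps <- amplitude * jitter(n_cycles)
    starts <- c(0, cumsum(periods))
    times <- seq(0, duration_s, by = 1 / sample_rate_hz)
    cyc <- findInterval(times, starts, rightmost.closed = FALSE)
    cyc[cyc < 1L] <- 1L
    cyc[cyc > n_cycles] <- n_cycles
    tau <- (times - starts[cyc]) / periods[cyc]
    sig <- amps[cyc] * cos(pi * tau)^(2 * exponent_n)
    breathing_trace(times, sig)
  })
}
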