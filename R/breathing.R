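#' Decimating moving-average filter
#'
#' Smooths a breathing trace with a block-mean filter of size `window`: one
#' output sample per non-overlapping block of `window` input samples (output
#' length `floor(n / window)`), each output amplitude the block mean and each
#' output time the block-center time. A trailing partial block is dropped.
#'
#' @param trace a [breathing_trace()].
#' @param window positive integer block size; default 50.
#' @return A [breathing_trace()] of length `floor(n / window)`.
#' @export
smooth_trace <- function(trace, window = 50L) {
  stopifnot(inherits(trace, "breathing_trace"))
  window <- as.integer(window)
  stopifnot(window >= 1L)
  n <- length(trace$amplitudes)
  if (n < window)
    stop("trace shorter than the smoothing window", call. = FALSE)
  nb <- n %/% window
  idx <- seq_len(nb * window)
  block <- matrix(trace$amplitudes[idx], nrow = window)
  tblock <- matrix(trace$times[idx], nrow = window)
  if (nb == 1L) {
    return(structure(list(times = colMeans(tblock),
                          amplitudes = colMeans(block)),
                     class = "breathing_trace"))
  }
  breathing_trace(colMeans(tblock), colMeans(block))
}

#' One breathing period delimited by consecutive peaks
#'
#' @param start,end 1-based sample indices of the delimiting peaks.
#' @param duration_s period length in seconds.
#' @return A `period_segment` list.
#' @export
period_segment <- function(start, end, duration_s) {
  stopifnot(end > start, duration_s > 0)
  structure(list(start = as.integer(start), end = as.integer(end),
                 duration_s = duration_s),
            class = "period_segment")
}

#' Segment a breathing trace into peak-to-peak periods
#'
#' Peaks are local maxima lying above the trace mean, at least
#' `min_separation_s` apart (the higher peak wins a conflict); a plateau
#' counts as a peak at its first sample. Consecutive peaks delimit the
#' returned period segments.
#'
#' @param trace a (smoothed) [breathing_trace()].
#' @param min_separation_s minimum peak separation in seconds; default 1.
#' @return list of [period_segment()]s.
#' @export
segment_periods <- function(trace, min_separation_s = 1.0) {
  stopifnot(inherits(trace, "breathing_trace"))
  x <- trace$amplitudes
  n <- length(x)
  i <- 2:(n - 1)
  is_peak <- c(FALSE, x[i] > x[i - 1] & x[i] >= x[i + 1], FALSE)
  is_peak <- is_peak & x > mean(x)
  peaks <- which(is_peak)
  if (length(peaks) >= 2L) {
    # enforce minimum separation, keeping the larger peak
    ord <- peaks[order(x[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (all(abs(trace$times[p] - trace$times[kept]) >= min_separation_s))
        kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  if (length(peaks) < 2L) stop("no periods detected", call. = FALSE)
  lapply(seq_len(length(peaks) - 1L), function(s) {
    period_segment(peaks[s], peaks[s + 1L],
                   trace$times[peaks[s + 1L]] - trace$times[peaks[s]])
  })
}

#' 8-phase breathing probability density function
#'
#' @param weights 8 non-negative weights ordered by phase label 0%, 12.5%,
#'   ..., 87.5%; must sum to 1 within 1e-9 (renormalized exactly).
#' @return A `phase_pdf` object (named numeric vector of length 8).
#' @export
phase_pdf <- function(weights) {
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 8L)
  if (any(weights < 0)) stop("phase weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("phase weights must sum to 1", call. = FALSE)
  weights <- weights / sum(weights)
  names(weights) <- paste0(phase_labels(), "%")
  structure(weights, class = "phase_pdf")
}

#' @export
print.phase_pdf <- function(x, ...) {
  cat("phase_pdf:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Amplitude-bin one breathing period into an 8-phase PDF
#'
#' The amplitude range of the period is split into 5 equal levels. The top
#' level maps to phase 0% (maximum inhale) and the bottom level to phase 50%
#' (end exhale); each of the 3 intermediate levels maps to one phase per
#' limb: 12.5/25/37.5% on the descending (exhaling) limb and 87.5/75/62.5%
#' on the ascending (inhaling) limb. Each phase weight is the fraction of
#' the period's samples in that state, so the weights estimate the fraction
#' of breathing time spent in each amplitude-binned 4D phase.
#'
#' @param trace a [breathing_trace()].
#' @param segment a [period_segment()] within the trace.
#' @return A [phase_pdf()].
#' @export
amplitude_bin_pdf <- function(trace, segment) {
  stopifnot(inherits(trace, "breathing_trace"),
            inherits(segment, "period_segment"))
  if (segment$end > length(trace$amplitudes))
    stop("segment exceeds the trace", call. = FALSE)
  idx <- segment$start:(segment$end - 1L)
  x <- trace$amplitudes[idx]
  rng <- range(x)
  if (diff(rng) <= 0) stop("flat segment", call. = FALSE)
  h <- diff(rng) / 5
  lev <- pmin(4L, pmax(0L, as.integer(floor((rng[2] - x) / h))))
  imin <- which.min(x)
  descending <- seq_along(x) <= imin
  phase <- integer(length(x))
  phase[lev == 0L] <- 1L                         # 0% max inhale
  phase[lev == 4L] <- 5L                         # 50% end exhale
  mid <- lev >= 1L & lev <= 3L
  phase[mid & descending] <- lev[mid & descending] + 1L   # 12.5/25/37.5%
  phase[mid & !descending] <- 9L - lev[mid & !descending] # 87.5/75/62.5%
  phase_pdf(tabulate(phase, 8L) / length(x))
}

#' Average per-period PDFs into a patient PDF
#'
#' Element-wise mean of the per-period phase PDFs, renormalized to sum 1.
#' This average weights the dose on each phase during accumulation.
#'
#' @param pdfs non-empty list of [phase_pdf()]s.
#' @return A [phase_pdf()].
#' @export
average_pdfs <- function(pdfs) {
  if (length(pdfs) == 0L) stop("no PDFs to average", call. = FALSE)
  m <- do.call(rbind, lapply(pdfs, unclass))
  w <- colMeans(m)
  phase_pdf(w / sum(w))
}

#' Breathing trace to patient-specific phase PDF
#'
#' Convenience pipeline: decimating moving average (window `window`), peak
#' detection and period segmentation, per-period amplitude binning, then
#' averaging across periods.
#'
#' @param trace a raw [breathing_trace()].
#' @param window moving-average block size; default 50.
#' @param min_separation_s minimum peak separation for period detection.
#' @return A [phase_pdf()].
#' @export
trace_to_pdf <- function(trace, window = 50L, min_separation_s = 1.0) {
  sm <- smooth_trace(trace, window)
  segs <- segment_periods(sm, min_separation_s)
  pdfs <- list()
  for (s in segs) {
    p <- tryCatch(amplitude_bin_pdf(sm, s), error = function(e) NULL)
    if (!is.null(p)) pdfs[[length(pdfs) + 1L]] <- p
  }
  if (length(pdfs) == 0L) stop("no usable breathing periods", call. = FALSE)
  average_pdfs(pdfs)
}
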