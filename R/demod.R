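# Passive homodyne demodulation of the 3x3-coupler outputs: channel
# equalization, quadrant-aware arctangent phase recovery, phase unwrapping.

#' Equalize the three coupler channels
#'
#' Estimates each channel's offset `C_k` and amplitude `A_k` and rescales so
#' the channels swing over roughly \[-1, 1\], the normalization the
#' arctangent combination assumes. The default estimator is the half-range
#' rule `C = (max + min)/2`, `A = (max - min)/2`, valid whenever the phase
#' sweeps at least one full fringe; a robust percentile variant (0.5% /
#' 99.5%) is available against outliers.
#'
#' @param record A [coupler_record()]. Each channel must traverse at least
#'   one fringe: a channel whose peak-to-peak range is below
#'   `underrun_frac` times the largest channel's range signals that the pad
#'   saw no modulation and raises a degenerate-channel error.
#' @param method `"minmax"` (default) or `"percentile"`.
#' @param probs Lower/upper probabilities for the percentile method.
#' @param underrun_frac Fringe-underrun threshold, fraction of the largest
#'   channel's peak-to-peak range.
#' @return A list with components `record` (the equalized
#'   [coupler_record()]) and `report` (an `equalization_report` holding
#'   `C_hat`, `A_hat` and the method tag).
#' @examples
#' ph <- phase_series(seq(0, 4 * pi, length.out = 1000), fs = 100)
#' eq <- equalize(make_coupler_record(ph, coupler_params(C = c(2, 2, 2))))
#' eq$report
#' @export
equalize <- function(record, method = c("minmax", "percentile"),
                     probs = c(0.005, 0.995), underrun_frac = 0.1) {
  stopifnot(inherits(record, "coupler_record"))
  method <- match.arg(method)
  bounds <- apply(record$u, 2L, function(ch) {
    if (method == "minmax") range(ch)
    else stats::quantile(ch, probs, names = FALSE)
  })
  ptp <- bounds[2L, ] - bounds[1L, ]
  if (any(ptp < underrun_frac * max(ptp)) || max(ptp) == 0)
    fv_stop("demod", "degenerate-channel",
            sprintf("channel peak-to-peak ranges (%s) indicate fringe underrun",
                    paste(signif(ptp, 4), collapse = ", ")))
  C_hat <- (bounds[2L, ] + bounds[1L, ]) / 2
  A_hat <- ptp / 2
  u <- sweep(sweep(record$u, 2L, C_hat, "-"), 2L, A_hat, "/")
  list(
    record = coupler_record(u, record$fs, record$t0),
    report = structure(list(C_hat = C_hat, A_hat = A_hat, method = method),
                       class = "equalization_report")
  )
}

#' Demodulate equalized coupler outputs to wrapped phase
#'
#' Combines the three equalized outputs by the passive-homodyne arctangent
#' rule `atan2(sqrt(3) * (u2 - u3), u2 + u3 - 2 * u1)`. The two-argument
#' arctangent is used so the full fringe quadrant is recovered (a principal
#' -branch arctan would fold half the fringe and defeat unwrapping). The
#' result carries the true phase up to a constant offset.
#'
#' At a singular sample where numerator and denominator both vanish the
#' previous sample's value is emitted and a singular-point warning is
#' raised.
#'
#' @param record An equalized [coupler_record()].
#' @return A wrapped [phase_series()] with values in `(-pi, pi]`.
#' @export
demodulate <- function(record) {
  stopifnot(inherits(record, "coupler_record"))
  num <- sqrt(3) * (record$u[, 2L] - record$u[, 3L])
  den <- record$u[, 2L] + record$u[, 3L] - 2 * record$u[, 1L]
  eps <- 1e-12 * max(1, max(abs(record$u)))
  wrapped <- atan2(num, den)
  sing <- which(abs(num) < eps & abs(den) < eps)
  if (length(sing)) {
    fv_warn("demod", "singular-point",
            sprintf("%d singular sample(s); previous value emitted",
                    length(sing)))
    for (i in sing) wrapped[i] <- if (i > 1L) wrapped[i - 1L] else 0
  }
  phase_series(wrapped, record$fs, record$t0)
}

#' Unwrap a wrapped phase series
#'
#' Adjusts successive differences by multiples of `2*pi` so that no
#' sample-to-sample jump exceeds `pi` in magnitude; the first sample is
#' unchanged. Valid whenever the true phase changes by less than `pi` per
#' sample, which holds with a wide margin at the default sampling rate.
#'
#' @param wrapped A [phase_series()] with wrapped values.
#' @return The unwrapped [phase_series()].
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(inherits(wrapped, "phase_series"))
  x <- wrapped$values
  if (length(x) > 1L) {
    d <- diff(x)
    adj <- -2 * pi * round(d / (2 * pi))
    x <- x + c(0, cumsum(adj))
  }
  phase_series(x, wrapped$fs, wrapped$t0)
}

#' Demodulate and unwrap in one step
#'
#' Convenience wrapper: [equalize()] (optional), [demodulate()], then
#' [unwrap_phase()].
#'
#' @param record A [coupler_record()].
#' @param equalize_first Run channel equalization before demodulation.
#' @param ... Passed to [equalize()].
#' @return An unwrapped [phase_series()].
#' @export
recover_phase <- function(record, equalize_first = TRUE, ...) {
  if (equalize_first) record <- equalize(record, ...)$record
  unwrap_phase(demodulate(record))
}

#' @export
print.equalization_report <- function(x, ...) {
  cat("Channel equalization (", x$method, ")\n", sep = "")
  for (k in 1:3)
    cat(sprintf("  u%d: C_hat = %.6g, A_hat = %.6g\n",
                k, x$C_hat[k], x$A_hat[k]))
  invisible(x)
}
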