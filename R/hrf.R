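#' Canonical double-gamma hemodynamic response function
#'
#' The BOLD impulse response is modelled as the difference of two gamma-density
#' shaped lobes — a positive peak near 5 s and a later undershoot — and
#' peak-normalized to a maximum of 1:
#' \deqn{h(t) = g(t; a_1, b_1) - \frac{1}{r}\, g(t; a_2, b_2),}
#' where each lobe's shape/scale is parameterized by its delay and dispersion
#' (`a = delay/dispersion`, `b = 1/dispersion`) and `r` is the peak-to-undershoot
#' ratio.
#'
#' @param peak_delay Delay of the positive lobe (s), default 6.
#' @param undershoot_delay Delay of the undershoot (s), default 16.
#' @param peak_dispersion,undershoot_dispersion Lobe dispersions (s), default 1.
#' @param undershoot_ratio Relative undershoot amplitude (1/r in the formula is
#'   `undershoot_ratio`); 0 gives a single nonnegative gamma lobe. Default 1/6.
#' @param length Support of the sampled curve (s), default 32.
#' @param dt Sampling interval (s).
#' @return An `hrf` object: list with `values` (sampled curve, max 1), `time`
#'   and `dt`.
#' @export
#' @examples
#' h <- canonical_hrf(dt = 0.1)
#' h$time[which.max(h$values)]  # peaks near 5 s
canonical_hrf <- function(peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6, length = 32, dt = 0.5) {
  assert_scalar_num(peak_delay, "peak_delay", positive = TRUE)
  assert_scalar_num(undershoot_delay, "undershoot_delay", positive = TRUE)
  assert_scalar_num(peak_dispersion, "peak_dispersion", positive = TRUE)
  assert_scalar_num(undershoot_dispersion, "undershoot_dispersion", positive = TRUE)
  assert_scalar_num(undershoot_ratio, "undershoot_ratio", nonneg = TRUE)
  assert_scalar_num(length, "length", positive = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)
  if (dt > length) stop("`dt` must not exceed `length`.", call. = FALSE)
  tt <- seq(0, length, by = dt)
  lobe <- function(delay, disp) {
    shape <- delay / disp
    stats::dgamma(tt, shape = shape, scale = disp)
  }
  h <- lobe(peak_delay, peak_dispersion) -
    undershoot_ratio * lobe(undershoot_delay, undershoot_dispersion)
  h <- h / max(h)
  structure(list(values = h, time = tt, dt = dt,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               peak_dispersion = peak_dispersion,
                               undershoot_dispersion = undershoot_dispersion,
                               undershoot_ratio = undershoot_ratio,
                               length = length)),
            class = "hrf")
}

#' @export
print.hrf <- function(x, ...) {
  cat(sprintf("<hrf> %d samples, dt = %g s, peak at %g s\n",
              length(x$values), x$dt, x$time[which.max(x$values)]))
  invisible(x)
}

#' @exportS3Method
tidy.hrf <- function(x, ...) tibble(time = x$time, value = x$values)

#' @exportS3Method
autoplot.hrf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since event (s)", y = "response (normalized)")
}

#' Convolve neural signals with a hemodynamic response
#'
#' Forward model mapping latent neural series to BOLD: each region's signal is
#' causally convolved with an HRF sampled at the series' interval. Per-region
#' HRFs (a list) emulate inter-regional hemodynamic variability.
#'
#' @param neural A [neural_ts()].
#' @param hrf An `hrf` object or list of one per region; resampled internally
#'   to the series interval if needed.
#' @return A [bold_ts()] of the same length.
#' @export
convolve_hrf <- function(neural, hrf) {
  stopifnot(inherits(neural, "neural_ts"))
  d <- ncol(neural$values)
  hrfs <- if (inherits(hrf, "hrf")) rep(list(hrf), d) else hrf
  stopifnot(length(hrfs) == d)
  out <- neural$values
  for (j in seq_len(d)) {
    h <- resample_hrf(hrfs[[j]], neural$dt)
    full <- stats::convolve(neural$values[, j], rev(h), type = "open")
    out[, j] <- full[seq_len(nrow(neural$values))]
  }
  bold_ts(out, tr = neural$dt, regions = neural$regions)
}

resample_hrf <- function(hrf, dt) {
  stopifnot(inherits(hrf, "hrf"))
  if (isTRUE(all.equal(hrf$dt, dt))) return(hrf$values)
  tt <- seq(0, max(hrf$time), by = dt)
  stats::approx(hrf$time, hrf$values, xout = tt, rule = 2)$y
}
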