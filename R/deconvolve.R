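#' Detect pseudo-events in a resting-state series
#'
#' Blind deconvolution treats suprathreshold excursions of the standardized
#' BOLD signal as pseudo-events from which the subject's hemodynamic response
#' can be estimated without task timing. An index is an event if it is a local
#' maximum of the standardized series and exceeds `threshold_k` standard
#' deviations above the mean.
#'
#' @param x Numeric vector (single-region series), length >= 10.
#' @param threshold_k Threshold in SD units, > 0. Default 1.
#' @return Integer vector of event indices (possibly empty; a constant series
#'   yields no events).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200); x[c(50, 120)] <- 6
#' detect_pseudo_events(x, threshold_k = 2)
detect_pseudo_events <- function(x, threshold_k = 1) {
  x <- as.numeric(x)
  if (length(x) < 10L) stop("series must have at least 10 samples.", call. = FALSE)
  assert_scalar_num(threshold_k, "threshold_k", positive = TRUE)
  if (!all(is.finite(x))) stop("series must be finite.", call. = FALSE)
  s <- sd(x)
  if (s == 0) return(integer(0))
  z <- (x - mean(x)) / s
  n <- length(z)
  i <- 2:(n - 1)
  peaks <- i[z[i] > z[i - 1] & z[i] >= z[i + 1] & z[i] > threshold_k]
  as.integer(peaks)
}

#' Estimate the hemodynamic response from event-locked BOLD
#'
#' Least-squares fit of basis-function amplitudes to the BOLD series given
#' pseudo-event indices: regressors are the event train convolved with a
#' canonical double-gamma response and its temporal derivative (by default)
#' over a configurable lag window. The fitted amplitudes reconstruct the
#' subject- and region-specific HRF sampled at the series interval.
#'
#' @param x Numeric vector, the BOLD series.
#' @param events Integer event indices from [detect_pseudo_events()]; at least
#'   3 and at least as many as basis functions.
#' @param tr Sampling interval (s).
#' @param window Lag window in seconds over which the response is modelled,
#'   default 0 to 24 s.
#' @param use_derivative Include the temporal-derivative basis (default TRUE).
#' @return An `hrf` object (peak-normalized if nonzero) with attribute
#'   `amplitudes` holding the fitted basis weights.
#' @export
estimate_hrf <- function(x, events, tr, window = c(0, 24),
                         use_derivative = TRUE) {
  x <- as.numeric(x)
  assert_scalar_num(tr, "tr", positive = TRUE)
  n_basis <- if (use_derivative) 2L else 1L
  if (length(events) < max(3L, n_basis)) {
    stop(sprintf("need at least %d events to fit %d basis functions; got %d.",
                 max(3L, n_basis), n_basis, length(events)), call. = FALSE)
  }
  if (any(events < 1L | events > length(x))) {
    stop("event indices out of bounds.", call. = FALSE)
  }
  can <- canonical_hrf(length = window[2], dt = tr)
  basis <- list(can$values)
  if (use_derivative) {
    basis <- c(basis, list(c(diff(can$values), 0) / tr))
  }
  train <- numeric(length(x))
  train[events] <- 1
  X <- vapply(basis, function(b) {
    full <- stats::convolve(train, rev(b), type = "open")
    full[seq_along(x)]
  }, numeric(length(x)))
  fit <- stats::lm.fit(cbind(1, X), x)
  amp <- fit$coefficients[-1]
  amp[is.na(amp)] <- 0
  h <- rowSums(vapply(seq_along(basis), function(k) amp[k] * basis[[k]],
                      numeric(length(can$values))))
  peak <- max(abs(h))
  out <- structure(list(values = if (peak > 0) h / peak else h,
                        time = can$time, dt = tr,
                        params = list(window = window,
                                      use_derivative = use_derivative)),
                   class = "hrf")
  attr(out, "amplitudes") <- amp
  out
}

#' Wiener deconvolution of a BOLD series
#'
#' Frequency-domain inverse filter recovering the latent neural signal from a
#' BOLD series and an HRF:
#' \deqn{\hat X(f) = \frac{Y(f)\, H^*(f)}{|H(f)|^2 + \lambda}.}
#' The regularizer \eqn{\lambda} trades noise amplification against fidelity;
#' `lambda = NULL` picks it from the high-frequency power of the observed
#' series (a data-driven default). The series is zero-padded to the full
#' linear-convolution length before the FFT, so circular wrap-around matches
#' the causal convolution model; the first and last HRF-length samples remain
#' the least reliable and should be trimmed in downstream comparisons.
#'
#' @param y Numeric vector, observed series.
#' @param hrf Numeric vector (sampled HRF at the series interval) or an `hrf`
#'   object.
#' @param lambda Regularization, >= 0, or `NULL` for the data-driven default.
#' @param tr Sampling interval, required when `hrf` is an `hrf` object with a
#'   different `dt`.
#' @return Numeric vector, the deconvolved series (same length as `y`), with
#'   attribute `lambda` recording the value used.
#' @export
wiener_deconvolve <- function(y, hrf, lambda = NULL, tr = NULL) {
  y <- as.numeric(y)
  h <- if (inherits(hrf, "hrf")) {
    resample_hrf(hrf, if (is.null(tr)) hrf$dt else tr)
  } else as.numeric(hrf)
  if (all(h == 0)) stop("`hrf` must be nonzero.", call. = FALSE)
  n <- length(y)
  nh <- length(h)
  # zero-pad to the linear-convolution length n + nh
  yp <- c(y, numeric(nh))
  np <- length(yp)
  H <- fft(c(h, numeric(np - nh)))
  Y <- fft(yp)
  if (is.null(lambda)) {
    lambda <- default_wiener_lambda(Y, H)
  }
  assert_scalar_num(lambda, "lambda", nonneg = TRUE)
  if (lambda == 0 && any(Mod(H) < .Machine$double.eps^0.5)) {
    stop(paste("lambda = 0 is ill-posed: |H(f)| has zeros;",
               "supply a positive lambda."), call. = FALSE)
  }
  X <- Y * Conj(H) / (Mod(H)^2 + lambda)
  x <- Re(fft(X, inverse = TRUE)) / np
  out <- x[seq_len(n)]
  attr(out, "lambda") <- lambda
  out
}

# noise-power heuristic: ratio of upper-quartile-frequency power to total,
# scaled by the peak of |H|^2 so the regularizer is on the filter's scale
default_wiener_lambda <- function(Y, H) {
  p <- Mod(Y)^2
  n <- length(p)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f) / n  # folded frequency in cycles/sample
  hf <- p[f > 0.375]
  lam <- (if (length(hf)) median(hf) else 0) / max(median(p), .Machine$double.eps)
  max(lam * max(Mod(H)^2) * 0.01, 1e-8)
}

#' Blind deconvolution of a multi-region BOLD matrix
#'
#' The full blind-deconvolution chain applied region-wise: standardize,
#' detect pseudo-events, estimate the region's HRF from the event-locked
#' signal, then Wiener-deconvolve with it. Regions with too few events fall
#' back to the canonical HRF (recorded in the result).
#'
#' @param bold A [bold_ts()].
#' @param threshold_k Event threshold in SD units, default 1.
#' @param lambda Wiener regularizer; `NULL` for data-driven.
#' @param window HRF lag window (s), default `c(0, 24)`.
#' @return A `deconvolution_result`: list with `neural` (a [neural_ts()]),
#'   `hrfs` (per-region `hrf` objects), `events` (per-region indices),
#'   `lambda` (per-region values used) and `fallback` (logical per region).
#' @export
deconvolve_bold <- function(bold, threshold_k = 1, lambda = NULL,
                            window = c(0, 24)) {
  stopifnot(inherits(bold, "bold_ts"))
  d <- ncol(bold$values)
  vals <- standardize_columns(bold$values)
  hrfs <- vector("list", d)
  events <- vector("list", d)
  lambdas <- numeric(d)
  fallback <- logical(d)
  out <- vals
  for (j in seq_len(d)) {
    ev <- detect_pseudo_events(vals[, j], threshold_k = threshold_k)
    events[[j]] <- ev
    hrfs[[j]] <- if (length(ev) >= 3L) {
      estimate_hrf(vals[, j], ev, tr = bold$tr, window = window)
    } else {
      fallback[j] <- TRUE
      canonical_hrf(length = window[2], dt = bold$tr)
    }
    x <- wiener_deconvolve(vals[, j], hrfs[[j]], lambda = lambda, tr = bold$tr)
    lambdas[j] <- attr(x, "lambda")
    out[, j] <- x
  }
  structure(
    list(neural = neural_ts(out, dt = bold$tr, regions = bold$regions),
         hrfs = hrfs, events = events, lambda = lambdas,
         fallback = fallback, threshold_k = threshold_k),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf(
    "<deconvolution_result> %d regions, %d time points; events/region: %s\n",
    ncol(x$neural$values), nrow(x$neural$values),
    paste(lengths(x$events), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method
glance.deconvolution_result <- function(x, ...) {
  tibble(
    region = x$neural$regions,
    n_events = lengths(x$events),
    hrf_peak_s = vapply(x$hrfs, function(h) h$time[which.max(h$values)],
                        numeric(1)),
    lambda = x$lambda,
    canonical_fallback = x$fallback
  )
}
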