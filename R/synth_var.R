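#' Specify a (time-varying) vector autoregressive generator
#'
#' A `var_spec` describes the generative model used for synthetic neural
#' signals: a lag-`p` vector autoregression whose coefficient matrices may
#' change over time,
#' \deqn{y_t = \sum_{k=1}^p A_k(t)\, y_{t-k} + e_t,\qquad e_t \sim N(0,
#'   \mathrm{diag}(\sigma^2)).}
#' Coefficients are supplied as a function of the time index returning a
#' `d x d x p` array (or `d x d` matrix for `p = 1`), or as a single constant
#' array. Helpers [coef_constant()], [coef_sinusoid()] and [coef_step()] build
#' the trajectory shapes a tracking filter has to handle.
#'
#' @param n_regions Number of regions `d`.
#' @param order Autoregressive order `p`.
#' @param coef_fun Function `(t) -> d x d x p` array, or a constant array.
#' @param innovation_sd Innovation standard deviation, length 1 or `d`.
#' @param length Number of samples to generate.
#' @param dt Sampling interval in seconds.
#' @param regions Optional region labels.
#'
#' @return A `var_spec` object.
#' @export
#' @examples
#' A <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
#' spec <- var_spec(2, 1, coef_constant(A), innovation_sd = 1,
#'                  length = 200, dt = 1)
#' y <- generate_tv_var(spec, seed = 1)
var_spec <- function(n_regions, order, coef_fun, innovation_sd = 1,
                     length = 1000L, dt = 1, regions = NULL) {
  d <- assert_count(n_regions, "n_regions")
  p <- assert_count(order, "order")
  len <- assert_count(length, "length", min = p + 1L)
  assert_scalar_num(dt, "dt", positive = TRUE)
  if (!is.function(coef_fun)) {
    const <- as_coef_array(coef_fun, d, p)
    coef_fun <- function(t) const
  }
  sdv <- rep_len(as.numeric(innovation_sd), d)
  if (any(!is.finite(sdv)) || any(sdv < 0)) {
    stop("`innovation_sd` must be nonnegative and finite.", call. = FALSE)
  }
  if (is.null(regions)) regions <- paste0("R", seq_len(d))
  structure(
    list(n_regions = d, order = p, coef_fun = coef_fun,
         innovation_sd = sdv, length = len, dt = dt, regions = regions),
    class = "var_spec"
  )
}

as_coef_array <- function(A, d, p) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  if (!is.array(A) || !identical(dim(A), c(d, d, p))) {
    stop(sprintf("coefficients must be a %d x %d x %d array.", d, d, p),
         call. = FALSE)
  }
  A
}

#' Coefficient trajectory shapes
#'
#' Builders for the three trajectory regimes used in simulations: constant
#' coefficients, a sinusoidally varying entry, and a step change. Each returns
#' a function of the time index suitable for [var_spec()]'s `coef_fun`.
#'
#' @param base `d x d` matrix (or `d x d x p` array) of baseline coefficients.
#' @param target Integer pair `c(row, col)`: the entry (target region, source
#'   region) that varies; lag 1 is modulated.
#' @param amplitude Peak deviation from the baseline entry.
#' @param period Period of the sinusoid in samples.
#' @param at Sample index at which the step occurs.
#' @param delta Added to the target entry from `at` onwards.
#' @return A function `(t) -> coefficient array`.
#' @export
coef_constant <- function(base) {
  force(base)
  function(t) base
}

#' @rdname coef_constant
#' @export
coef_sinusoid <- function(base, target, amplitude, period) {
  force(base); force(target); force(amplitude); force(period)
  function(t) {
    A <- if (is.matrix(base)) array(base, dim = c(dim(base), 1L)) else base
    A[target[1], target[2], 1] <- A[target[1], target[2], 1] +
      amplitude * sin(2 * pi * t / period)
    A
  }
}

#' @rdname coef_constant
#' @export
coef_step <- function(base, target, at, delta) {
  force(base); force(target); force(at); force(delta)
  function(t) {
    A <- if (is.matrix(base)) array(base, dim = c(dim(base), 1L)) else base
    if (t >= at) A[target[1], target[2], 1] <- A[target[1], target[2], 1] + delta
    A
  }
}

#' Spectral radius of the VAR companion matrix
#'
#' Stability of a lag-`p` VAR is governed by the companion form: the model is
#' stationary iff all eigenvalues lie strictly inside the unit circle.
#'
#' @param A `d x d x p` coefficient array (or `d x d` matrix).
#' @return The largest eigenvalue modulus.
#' @export
companion_spectral_radius <- function(A) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  d <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[seq_len(d), (k - 1) * d + seq_len(d)] <- A[, , k]
  if (p > 1) {
    comp[d + seq_len(d * (p - 1)), seq_len(d * (p - 1))] <-
      diag(d * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a time-varying vector autoregression
#'
#' Generates a length-`T` multi-region series from the model in [var_spec()].
#' The first `p` samples are drawn from the innovation distribution. Before
#' simulating, the companion-matrix spectral radius is checked at every time
#' index; a non-stationary specification is refused with the first violating
#' index named.
#'
#' @param spec A [var_spec()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A [neural_ts()].
#' @export
generate_tv_var <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "var_spec"))
  d <- spec$n_regions; p <- spec$order; Tn <- spec$length
  coefs <- lapply(seq_len(Tn), function(t) {
    as_coef_array(spec$coef_fun(t), d, p)
  })
  for (t in seq_len(Tn)) {
    if (companion_spectral_radius(coefs[[t]]) >= 1) {
      stop(sprintf(
        "non-stationary specification: companion spectral radius >= 1 at time index %d",
        t), call. = FALSE)
    }
  }
  with_local_seed(seed, {
    y <- matrix(0, Tn, d)
    innov <- matrix(rnorm(Tn * d), Tn, d) %*% diag(spec$innovation_sd, d)
    y[seq_len(p), ] <- innov[seq_len(p), , drop = FALSE]
    for (t in (p + 1):Tn) {
      A <- coefs[[t]]
      acc <- innov[t, ]
      for (k in seq_len(p)) acc <- acc + A[, , k] %*% y[t - k, ]
      y[t, ] <- acc
    }
    neural_ts(y, dt = spec$dt, regions = spec$regions)
  })
}
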