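#' Configuration for the dynamic MVAR estimator
#'
#' The dynamic multivariate autoregressive (dMVAR) model treats the stacked
#' lag coefficient matrices as a latent state evolving by a random walk and
#' estimates them recursively with a Kalman filter — a filter-based,
#' time-varying form of Granger causality. The adaptation constant `c` scales
#' the state-noise covariance `c * I` and governs how fast coefficients may
#' drift: small `c` approaches a static least-squares VAR fit, larger `c`
#' tracks faster changes at the price of noisier estimates.
#'
#' @param order Autoregressive order `p` (default 1, giving one coefficient
#'   per directed pair per time point; for `p > 1` the reported connectivity
#'   is the sum over lags).
#' @param adaptation State-noise scale `c` > 0, default 1e-3 (on standardized
#'   data).
#' @param initial_state_variance Prior variance of each coefficient, default 10.
#' @param burn_in Samples dropped from the start of the output; `NULL` means
#'   `max(50, 5%)` of the series length.
#' @param connections Data frame with columns `source`, `target` (region
#'   labels) selecting the directed connections to report; `NULL` reports all
#'   ordered pairs (excluding self-connections).
#' @param innovation_memory Exponential-window weight for the recursive
#'   observation-noise estimate, in (0, 1); default 0.05.
#' @return A `dmvar_config` list.
#' @export
dmvar_config <- function(order = 1L, adaptation = 1e-3,
                         initial_state_variance = 10, burn_in = NULL,
                         connections = NULL, innovation_memory = 0.05) {
  p <- assert_count(order, "order")
  assert_scalar_num(adaptation, "adaptation", positive = TRUE)
  assert_scalar_num(initial_state_variance, "initial_state_variance",
                    positive = TRUE)
  if (!is.null(burn_in)) burn_in <- assert_count(burn_in, "burn_in", min = 0L)
  assert_scalar_num(innovation_memory, "innovation_memory", positive = TRUE)
  if (innovation_memory >= 1) {
    stop("`innovation_memory` must be in (0, 1).", call. = FALSE)
  }
  if (!is.null(connections)) {
    connections <- as_tibble(connections)
    stopifnot(all(c("source", "target") %in% names(connections)))
  }
  structure(list(order = p, adaptation = adaptation,
                 initial_state_variance = initial_state_variance,
                 burn_in = burn_in, connections = connections,
                 innovation_memory = innovation_memory),
            class = "dmvar_config")
}

#' The seven directed connections of the arbitration analysis
#'
#' Three arbitration-system connections (vlPFC/FPC onto posterolateral
#' putamen), two within the habitual system (SMA onto putamen) and two within
#' the goal-directed system (caudate onto OFC), using the labels of
#' [default_rois()].
#'
#' @return A tibble with columns `source`, `target`, `system`.
#' @export
analyzed_connections <- function() {
  tibble(
    source = c("L_vlPFC", "R_vlPFC", "R_FPC",
               "L_SMA", "R_SMA", "L_caudate", "R_caudate"),
    target = c("L_putamen_A", "L_putamen_B", "R_putamen",
               "L_putamen_A", "R_putamen", "OFC", "OFC"),
    system = c("arbitration", "arbitration", "arbitration",
               "habitual", "habitual", "goal_directed", "goal_directed")
  )
}

#' Estimate dynamic effective connectivity by Kalman-filtered dMVAR
#'
#' Fits the time-varying VAR
#' \deqn{y_t = \sum_{k=1}^p A_k(t)\, y_{t-k} + e_t}
#' by casting the stacked, vectorized coefficient matrices as the state of a
#' linear-Gaussian state-space model with random-walk dynamics
#' (\eqn{\theta_t = \theta_{t-1} + w_t}, \eqn{cov(w) = c I}) and running the
#' standard Kalman predict/update recursion. The observation matrix at time
#' `t` is built from the `p` most recent lagged observations; the observation
#' noise covariance is estimated recursively from the innovations with an
#' exponential window. The dynamic effective connectivity (DEC) of connection
#' source `j` to target `i` at time `t` is \eqn{\sum_k A_k(t)[i, j]}: negative
#' values indicate a putatively inhibitory directed influence, positive values
#' an excitatory one. The filter is deterministic given its inputs.
#'
#' Inputs are standardized per region (done with a warning if not already),
#' so coefficients are dimensionless and invariant to the original units.
#'
#' @param series A [neural_ts()] or [bold_ts()].
#' @param config A [dmvar_config()].
#' @return A `dec_trajectory`: list with `values` (time x connection matrix,
#'   burn-in dropped), `connections` (tibble: source, target, label), `config`
#'   and `burn_in`.
#' @export
#' @examples
#' y <- generate_tv_var(var_spec(2, 1, matrix(c(0.4, 0.3, 0, 0.4), 2, 2),
#'                               length = 400, dt = 1), seed = 2)
#' fit <- fit_dmvar_kalman(y, dmvar_config())
#' head(tidy(fit))
fit_dmvar_kalman <- function(series, config = dmvar_config()) {
  stopifnot(inherits(config, "dmvar_config"))
  y <- series$values
  d <- ncol(y)
  Tn <- nrow(y)
  p <- config$order
  burn <- if (is.null(config$burn_in)) max(50L, ceiling(0.05 * Tn)) else config$burn_in
  if (!all(is.finite(y))) stop("series contains non-finite values.", call. = FALSE)
  if (Tn < p + burn + 10L) {
    stop(sprintf("series too short: need at least p + burn_in + 10 = %d samples, got %d.",
                 p + burn + 10L, Tn), call. = FALSE)
  }
  mu <- colMeans(y)
  sdv <- apply(y, 2, sd)
  if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 1e-6)) {
    warning("standardizing series per region before dMVAR fitting.")
    y <- standardize_columns(y)
  }

  m <- d * p          # regressor length per target region
  ns <- d * m         # state dimension
  theta <- numeric(ns)
  P <- diag(config$initial_state_variance, ns)
  Rm <- diag(1, d)    # recursive observation-noise estimate
  alpha <- config$innovation_memory
  cI <- config$adaptation

  coef_path <- matrix(NA_real_, Tn, ns)
  idx <- seq_len(m)
  for (t in (p + 1):Tn) {
    x <- as.vector(t(y[t - seq_len(p), , drop = FALSE]))  # lag-1 block first
    # predict
    P <- P + diag(cI, ns)
    # C = I_d (x) x'; exploit the block structure instead of forming C
    # S = C P C' + R ; K = P C' S^-1
    PCt <- matrix(NA_real_, ns, d)
    for (i in seq_len(d)) {
      cols <- (i - 1L) * m + idx
      PCt[, i] <- P[, cols, drop = FALSE] %*% x
    }
    CPCt <- matrix(NA_real_, d, d)
    for (i in seq_len(d)) {
      CPCt[i, ] <- crossprod(x, PCt[(i - 1L) * m + idx, , drop = FALSE])
    }
    S <- CPCt + Rm
    pred <- vapply(seq_len(d), function(i) {
      sum(theta[(i - 1L) * m + idx] * x)
    }, numeric(1))
    innov <- y[t, ] - pred
    K <- PCt %*% solve(S)
    theta <- theta + as.vector(K %*% innov)
    # Joseph-free covariance update (I - KC) P, exploiting C's structure
    KC <- matrix(0, ns, ns)
    for (i in seq_len(d)) {
      cols <- (i - 1L) * m + idx
      KC[, cols] <- tcrossprod(K[, i], x)
    }
    P <- P - KC %*% P
    P <- (P + t(P)) / 2
    # recursive innovation-based noise estimate, floored for stability
    Rm <- (1 - alpha) * Rm + alpha * tcrossprod(innov)
    diag(Rm) <- pmax(diag(Rm), 1e-6)
    coef_path[t, ] <- theta
  }

  labels <- series$regions
  conn <- config$connections
  if (is.null(conn)) {
    grid <- expand.grid(target = seq_len(d), source = seq_len(d))
    grid <- grid[grid$target != grid$source, ]
    conn <- tibble(source = labels[grid$source], target = labels[grid$target])
  }
  si <- match(conn$source, labels)
  ti <- match(conn$target, labels)
  if (anyNA(si) || anyNA(ti)) {
    bad <- unique(c(conn$source[is.na(si)], conn$target[is.na(ti)]))
    stop(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  # DEC(j -> i, t) = sum_k A_k(t)[i, j]; state is grouped per target region,
  # within a group lag-major over sources
  keep <- (max(p + 1L, burn + 1L)):Tn
  vals <- matrix(NA_real_, length(keep), nrow(conn))
  for (cc in seq_len(nrow(conn))) {
    pos <- (ti[cc] - 1L) * m + (seq_len(p) - 1L) * d + si[cc]
    vals[, cc] <- if (p == 1L) coef_path[keep, pos] else
      rowSums(coef_path[keep, pos, drop = FALSE])
  }
  conn$label <- paste(conn$source, conn$target, sep = "->")
  colnames(vals) <- conn$label
  structure(list(values = vals, connections = conn, config = config,
                 burn_in = burn, dt = if (inherits(series, "bold_ts"))
                   series$tr else series$dt),
            class = "dec_trajectory")
}

#' @export
print.dec_trajectory <- function(x, ...) {
  cat(sprintf("<dec_trajectory> %d time points x %d connections (burn-in %d dropped)\n",
              nrow(x$values), ncol(x$values), x$burn_in))
  invisible(x)
}

#' @exportS3Method
tidy.dec_trajectory <- function(x, ...) {
  tibble(
    time = rep((x$burn_in + seq_len(nrow(x$values)) - 1) * x$dt,
               times = ncol(x$values)),
    connection = rep(colnames(x$values), each = nrow(x$values)),
    dec = as.vector(x$values)
  )
}

#' @exportS3Method
autoplot.dec_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$time, .data$dec)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~connection) +
    ggplot2::labs(x = "time (s)", y = "directed coefficient")
}

#' Track a known time-varying coefficient
#'
#' Convenience wrapper for simulation studies: fits the dMVAR filter and
#' correlates the estimated trajectory of one connection with its known
#' ground-truth trajectory after burn-in. If the truth is constant the
#' correlation is undefined and the status reports the degenerate case.
#'
#' @param series A [neural_ts()] generated with known coefficients.
#' @param truth Numeric vector, the true coefficient at every time index of
#'   `series`.
#' @param connection Length-2 character: `c(source, target)` labels.
#' @param config A [dmvar_config()].
#' @return A list with `correlation` (NA when degenerate), `status`
#'   (`"ok"` or `"degenerate-truth"`), `estimate` and `truth` (aligned
#'   post-burn-in vectors).
#' @export
track_tv_coefficient <- function(series, truth, connection,
                                 config = dmvar_config()) {
  stopifnot(length(truth) == nrow(series$values))
  cfg <- config
  cfg$connections <- tibble(source = connection[1], target = connection[2])
  fit <- fit_dmvar_kalman(series, cfg)
  est <- fit$values[, 1]
  tru <- truth[fit$burn_in + seq_along(est)]
  if (sd(tru) == 0) {
    return(list(correlation = NA_real_, status = "degenerate-truth",
                estimate = est, truth = tru))
  }
  list(correlation = cor(est, tru), status = "ok", estimate = est, truth = tru)
}

#' Least-squares VAR fit (static oracle)
#'
#' Full-sample ordinary least-squares fit of a constant-coefficient VAR(p),
#' the static limit the Kalman filter approaches as the adaptation constant
#' shrinks. Used for cross-checking, not for dynamic estimation.
#'
#' @param series A [neural_ts()] or [bold_ts()].
#' @param order Lag order.
#' @return `d x d x p` coefficient array (`[i, j, k]` = effect of region `j`
#'   at lag `k` on region `i`).
#' @export
fit_var_ols <- function(series, order = 1L) {
  y <- series$values
  p <- assert_count(order, "order")
  Tn <- nrow(y); d <- ncol(y)
  X <- do.call(cbind, lapply(seq_len(p), function(k) {
    y[(p - k + 1):(Tn - k), , drop = FALSE]
  }))
  Y <- y[(p + 1):Tn, , drop = FALSE]
  B <- qr.solve(X, Y)  # (d*p) x d
  A <- array(NA_real_, c(d, d, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(k - 1) * d + seq_len(d), , drop = FALSE])
  dimnames(A) <- list(series$regions, series$regions, NULL)
  A
}

#' Anti-aliased temporal resampling
#'
#' Resamples a multi-region series to a new sampling interval, mirroring the
#' robustness check of comparing connectivity across acquisition rates. When
#' downsampling, a zero-phase Butterworth low-pass at 80% of the target
#' Nyquist frequency is applied first (forward-backward filtering, so no
#' phase distortion), then the series is interpolated with a natural spline
#' on the new time grid. Resampling to the same interval is the identity;
#' upsampling beyond 10x is refused.
#'
#' @param series A [neural_ts()] or [bold_ts()].
#' @param target_dt New sampling interval (s).
#' @return A series of the same class at `target_dt`.
#' @export
resample_series <- function(series, target_dt) {
  assert_scalar_num(target_dt, "target_dt", positive = TRUE)
  dt <- if (inherits(series, "bold_ts")) series$tr else series$dt
  ratio <- dt / target_dt
  if (ratio > 10) {
    stop("refusing to upsample by more than 10x (extrapolation risk).",
         call. = FALSE)
  }
  if (isTRUE(all.equal(ratio, 1))) return(series)
  n <- nrow(series$values)
  t_old <- (seq_len(n) - 1) * dt
  t_new <- seq(0, t_old[n], by = target_dt)
  out <- apply(series$values, 2, function(col) {
    if (target_dt > dt) {
      # anti-alias before decimation; cutoff as fraction of current Nyquist
      bf <- signal::butter(4, 0.8 * dt / target_dt)
      col <- signal::filtfilt(bf, col)
    }
    stats::spline(t_old, col, xout = t_new, method = "natural")$y
  })
  if (inherits(series, "bold_ts")) {
    bold_ts(out, tr = target_dt, regions = series$regions)
  } else {
    neural_ts(out, dt = target_dt, regions = series$regions)
  }
}
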