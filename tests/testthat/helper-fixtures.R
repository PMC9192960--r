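# shared simulation fixtures; everything is generated in code at test time

white_noise_ts <- function(n = 1000, d = 2, dt = 1, seed = 1) {
  set.seed(seed)
  neural_ts(matrix(rnorm(n * d), n, d), dt = dt)
}

# 2-region VAR with a single directed coupling a: R1 -> R2, diagonal zero.
# Innovation SDs are chosen so both channels have unit variance, making the
# coupling coefficient identical on the raw and standardized scales.
unit_variance_coupled_spec <- function(a = 0.6, length = 5000, dt = 1) {
  A <- matrix(0, 2, 2)
  A[2, 1] <- a
  var_spec(2, 1, coef_constant(A), innovation_sd = c(1, sqrt(1 - a^2)),
           length = length, dt = dt)
}

# spike train convolved with an HRF, for deconvolution round trips
spike_bold <- function(n = 500, n_spikes = 25, tr = 2, seed = 3) {
  set.seed(seed)
  h <- canonical_hrf(dt = tr)$values
  nh <- length(h)
  x <- numeric(n)
  # events away from the edges, where the inverse filter is reliable
  x[sample((nh + 1):(n - nh - 1), n_spikes)] <- rexp(n_spikes) + 1
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  list(x = x, y = y, h = h, interior = (nh + 1):(n - nh))
}
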