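#' Summarize a DEC trajectory per connection
#'
#' Reduces a connectivity trajectory to the study's dependent variables: the
#' arithmetic mean (direction and magnitude of the influence) and the sample
#' standard deviation (its variability; denominator `n - 1`) of each directed
#' connection over time.
#'
#' @param traj A `dec_trajectory` from [fit_dmvar_kalman()], or a time x
#'   connection matrix.
#' @param subject_id Optional subject identifier column to prepend.
#' @return A tibble with columns `connection`, `dec_mean`, `dec_sd` (and
#'   `subject_id` if supplied).
#' @export
#' @examples
#' summarize_dec(matrix(c(-1, 0, 1, 2, 2, 2), 3, 2,
#'                      dimnames = list(NULL, c("a->b", "b->a"))))
summarize_dec <- function(traj, subject_id = NULL) {
  vals <- if (inherits(traj, "dec_trajectory")) traj$values else as.matrix(traj)
  if (nrow(vals) < 2L) {
    stop("trajectory has fewer than 2 time points; SD is undefined.",
         call. = FALSE)
  }
  out <- tibble(
    connection = colnames(vals) %||% paste0("C", seq_len(ncol(vals))),
    dec_mean = unname(colMeans(vals)),
    dec_sd = unname(apply(vals, 2, sd))
  )
  if (!is.null(subject_id)) out <- dplyr::bind_cols(
    tibble(subject_id = subject_id), out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DVARS: spatial SD of successive difference images
#'
#' For each successive pair of volumes, the spatial standard deviation of the
#' voxelwise difference image; the subject-level scalar is the mean over
#' pairs. Accepts a 4D array (x, y, z, time) or a time x voxel/region matrix.
#'
#' @param x 4D array or numeric matrix (rows = time).
#' @return A list with `series` (length `T - 1`) and `value` (subject scalar).
#' @export
compute_dvars <- function(x) {
  if (is.array(x) && length(dim(x)) == 4) {
    dims <- dim(x)
    x <- t(matrix(x, prod(dims[1:3]), dims[4]))
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 volumes.", call. = FALSE)
  d <- diff(x)
  series <- apply(d, 1, sd)
  list(series = series, value = mean(series))
}

#' Flag high-motion subjects
#'
#' Excludes subjects whose motion index exceeds the cohort mean plus two
#' cohort standard deviations (strict inequality), computed once over the
#' pooled dataset (patients and controls together). A zero-variance cohort
#' yields no exclusions.
#'
#' @param data A data frame with one row per subject.
#' @param dvars Column holding the motion index (tidy-eval), default `dvars`.
#' @return The input with a logical `excluded_motion` column appended.
#' @export
#' @examples
#' flag_high_motion(data.frame(dvars = c(1, 1, 1, 1, 10)))
flag_high_motion <- function(data, dvars = dvars) {
  data <- as_tibble(data)
  if (nrow(data) < 3L) stop("need at least 3 subjects.", call. = FALSE)
  v <- dplyr::pull(data, {{ dvars }})
  if (any(!is.finite(v))) stop("motion values must be finite.", call. = FALSE)
  s <- sd(v)
  thr <- mean(v) + 2 * s
  data$excluded_motion <- if (s == 0) rep(FALSE, length(v)) else v > thr
  data
}
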