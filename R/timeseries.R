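#' Multi-region time-series containers
#'
#' `neural_ts()` wraps a time-by-region matrix of latent neural signals with
#' its sampling interval; `bold_ts()` does the same for observed BOLD signals
#' sampled at the scanner repetition time (TR). Both are light S3 objects used
#' throughout the pipeline; `tidy()` converts either to a long tibble for
#' plotting and joins.
#'
#' @param values Numeric matrix, time points in rows, regions in columns.
#' @param dt,tr Sampling interval in seconds (TR for BOLD).
#' @param regions Character vector of region labels; defaults to `R1..Rd`.
#'
#' @return An object of class `neural_ts` or `bold_ts` with fields `values`,
#'   `dt` (or `tr`) and `regions`.
#' @export
#' @examples
#' x <- neural_ts(matrix(rnorm(20), 10, 2), dt = 2)
#' tidy(x)
neural_ts <- function(values, dt, regions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_scalar_num(dt, "dt", positive = TRUE)
  if (anyNA(values) || !all(is.finite(values))) {
    stop("`values` must be finite with no missing entries.", call. = FALSE)
  }
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(values)))
  stopifnot(length(regions) == ncol(values))
  colnames(values) <- regions
  structure(list(values = values, dt = dt, regions = regions),
            class = "neural_ts")
}

#' @rdname neural_ts
#' @export
bold_ts <- function(values, tr, regions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_scalar_num(tr, "tr", positive = TRUE)
  if (!all(is.finite(values))) {
    stop("`values` must be finite.", call. = FALSE)
  }
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(values)))
  stopifnot(length(regions) == ncol(values))
  colnames(values) <- regions
  structure(list(values = values, tr = tr, regions = regions),
            class = "bold_ts")
}

#' @export
print.neural_ts <- function(x, ...) {
  cat(sprintf("<neural_ts> %d time points x %d regions, dt = %g s\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d volumes x %d regions, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' @export
dim.neural_ts <- function(x) dim(x$values)

#' @export
dim.bold_ts <- function(x) dim(x$values)

ts_to_tibble <- function(values, dt) {
  tibble(
    time = rep((seq_len(nrow(values)) - 1) * dt, times = ncol(values)),
    region = rep(colnames(values), each = nrow(values)),
    value = as.vector(values)
  )
}

#' @exportS3Method
tidy.neural_ts <- function(x, ...) ts_to_tibble(x$values, x$dt)

#' @exportS3Method
tidy.bold_ts <- function(x, ...) ts_to_tibble(x$values, x$tr)

#' @exportS3Method
autoplot.neural_ts <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)")
}

#' @exportS3Method
autoplot.bold_ts <- autoplot.neural_ts

#' Write / read a region-by-time matrix as TSV
#'
#' Plain-text interchange for region time series: one column per region, one
#' row per time point, sampling interval recorded in a header comment.
#'
#' @param x A `neural_ts` or `bold_ts`.
#' @param path Output file path.
#' @return `write_ts_tsv()` returns `path` invisibly; `read_ts_tsv()` returns
#'   a `neural_ts`.
#' @export
write_ts_tsv <- function(x, path) {
  dt <- if (inherits(x, "bold_ts")) x$tr else x$dt
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_seconds=%.10g", dt), con)
  write.table(x$values, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ts_tsv
#' @export
read_ts_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  dt <- if (grepl("^# dt_seconds=", header)) {
    as.numeric(sub("^# dt_seconds=", "", header))
  } else 1
  dat <- read.delim(path, comment.char = "#", check.names = FALSE)
  neural_ts(as.matrix(dat), dt = dt, regions = colnames(dat))
}

standardize_columns <- function(values) {
  mu <- colMeans(values)
  sdv <- apply(values, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(values, 2, mu, "-"), 2, sdv, "/")
}
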