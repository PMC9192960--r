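#' Design of a synthetic case-control cohort
#'
#' Describes a two-group resting-state study with a known connectivity ground
#' truth: every subject has a true mean coefficient on one target directed
#' connection; patients' truth differs from controls' by `group_dec_offset`
#' in expectation, and the (YBOCS-like) symptom score is a linear function of
#' the subject's true coefficient plus noise, clipped to the instrument range
#' 0-40. Covariates are drawn from plausible demographic marginals, all
#' overridable: age Normal(30, 10) truncated at 18, gender Bernoulli(0.5),
#' motion (DVARS) LogNormal, medication Bernoulli within patients.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_regions Number of regions in each subject's network, >= 2.
#' @param target_connection Integer pair `c(source, target)` region indices of
#'   the connection carrying the group effect.
#' @param base_coef Controls' mean true coefficient on the target connection.
#' @param group_dec_offset Patients' mean true coefficient minus controls'.
#' @param between_subject_sd SD of the subject-level true coefficient.
#' @param self_coef Diagonal (self-lag) coefficient shared by all regions.
#' @param symptom_slope Symptom units per unit of true coefficient.
#' @param symptom_intercept Symptom score at zero coefficient (patients).
#' @param symptom_noise_sd Residual symptom SD.
#' @param control_symptom_mean,control_symptom_sd Controls' symptom marginals
#'   (controls' scores are unrelated to connectivity).
#' @param medication_fraction Proportion of patients medicated, in \[0, 1\].
#' @param age_mean,age_sd,age_min Age distribution (years).
#' @param dvars_meanlog,dvars_sdlog DVARS LogNormal parameters.
#' @param tr Sampling interval of the generated series (s); 2.0 and 0.72
#'   emulate the two acquisition regimes studied.
#' @param n_timepoints Series length per subject.
#' @param dec_noise_sd SD of the summary-level measurement noise added to the
#'   truth when series are not generated (see [generate_cohort()]).
#' @param seed Integer seed; the whole cohort is reproducible given the seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_patients = 43L, n_controls = 24L,
                          n_regions = 3L, target_connection = c(1L, 2L),
                          base_coef = 0.2, group_dec_offset = -0.2,
                          between_subject_sd = 0.15, self_coef = 0.3,
                          symptom_slope = 0, symptom_intercept = 24,
                          symptom_noise_sd = 4,
                          control_symptom_mean = 1, control_symptom_sd = 1,
                          medication_fraction = 1 / 3,
                          age_mean = 30, age_sd = 10, age_min = 18,
                          dvars_meanlog = 0, dvars_sdlog = 0.3,
                          tr = 2, n_timepoints = 400L,
                          dec_noise_sd = 0.05, seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  n_controls <- assert_count(n_controls, "n_controls")
  n_regions <- assert_count(n_regions, "n_regions", min = 2L)
  assert_scalar_num(tr, "tr", positive = TRUE)
  assert_scalar_num(medication_fraction, "medication_fraction", nonneg = TRUE)
  if (medication_fraction > 1) {
    stop("`medication_fraction` must lie in [0, 1].", call. = FALSE)
  }
  assert_scalar_num(between_subject_sd, "between_subject_sd", nonneg = TRUE)
  assert_scalar_num(symptom_noise_sd, "symptom_noise_sd", nonneg = TRUE)
  stopifnot(length(target_connection) == 2,
            all(target_connection >= 1),
            all(target_connection <= n_regions),
            target_connection[1] != target_connection[2])
  structure(as.list(environment()), class = "cohort_design")
}

#' Generate a synthetic cohort with known connectivity ground truth
#'
#' Draws per-subject true coefficients, covariates and symptom scores per the
#' design, and (optionally) a neural time series per subject from a
#' constant-coefficient VAR whose target-connection entry equals the
#' subject's truth. Symptom scores outside 0-40 are clipped (count recorded
#' in `attr(, "n_clipped")`). With `generate_series = FALSE` only the
#' summary-level observations are produced: observed connection means equal
#' truth plus Gaussian measurement noise (`dec_noise_sd`), which is the fast
#' path for Monte-Carlo calibration of the statistics layer.
#'
#' @param design A [cohort_design()].
#' @param generate_series Also simulate per-subject series (default TRUE).
#' @return A list of class `synthetic_cohort`:
#'   * `cohort` — tibble, one row per subject: `subject_id`, `group`, `age`,
#'     `gender`, `medicated`, `dvars`, `ybocs`, `madrs`, `hama`, the true
#'     target coefficient `dec_true`, and observed summary columns
#'     `dec_obs_1..3` (target connection first, then two null connections);
#'   * `series` — named list of [neural_ts()] (or `NULL`);
#'   * `truth` — per-subject `d x d` true coefficient matrices.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_design(n_patients = 4, n_controls = 3,
#'                                         n_timepoints = 120))
#' cohort$cohort
generate_cohort <- function(design, generate_series = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design$n_regions
  n <- design$n_patients + design$n_controls
  with_local_seed(design$seed, {
    group <- rep(c("patient", "control"),
                 c(design$n_patients, design$n_controls))
    is_pat <- group == "patient"
    mu <- design$base_coef + ifelse(is_pat, design$group_dec_offset, 0)
    dec_true <- rnorm(n, mu, design$between_subject_sd)
    # keep every subject's VAR stationary
    cap <- 0.95 - design$self_coef
    dec_true <- pmin(pmax(dec_true, -cap), cap)

    age <- pmax(design$age_min, rnorm(n, design$age_mean, design$age_sd))
    gender <- rbinom(n, 1, 0.5)
    dvars <- rlnorm(n, design$dvars_meanlog, design$dvars_sdlog)
    medicated <- ifelse(is_pat, rbinom(n, 1, design$medication_fraction), 0L)

    raw_ybocs <- ifelse(
      is_pat,
      design$symptom_intercept + design$symptom_slope * dec_true +
        rnorm(n, 0, design$symptom_noise_sd),
      rnorm(n, design$control_symptom_mean, design$control_symptom_sd))
    ybocs <- pmin(pmax(raw_ybocs, 0), 40)
    n_clipped <- sum(raw_ybocs != ybocs)
    madrs <- pmin(pmax(ifelse(is_pat, rnorm(n, 15, 9), rnorm(n, 1.2, 1.2)),
                       0), 60)
    hama <- pmin(pmax(ifelse(is_pat, rnorm(n, 12, 5), rnorm(n, 1.5, 1.5)),
                      0), 56)

    # observed summary-level connection means: target + two null connections
    dec_obs <- cbind(
      dec_true + rnorm(n, 0, design$dec_noise_sd),
      rnorm(n, 0, design$dec_noise_sd),
      rnorm(n, 0, design$dec_noise_sd)
    )

    cohort <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, age = age, gender = gender,
      medicated = as.integer(medicated), dvars = dvars,
      ybocs = ybocs, madrs = madrs, hama = hama,
      dec_true = dec_true,
      dec_obs_1 = dec_obs[, 1], dec_obs_2 = dec_obs[, 2],
      dec_obs_3 = dec_obs[, 3]
    )

    truth <- lapply(seq_len(n), function(i) {
      A <- diag(design$self_coef, d)
      A[design$target_connection[2], design$target_connection[1]] <- dec_true[i]
      A
    })
    names(truth) <- cohort$subject_id

    series <- NULL
    if (generate_series) {
      series <- lapply(seq_len(n), function(i) {
        spec <- var_spec(d, 1L, coef_constant(truth[[i]]),
                         innovation_sd = 1, length = design$n_timepoints,
                         dt = design$tr)
        generate_tv_var(spec, seed = sample.int(.Machine$integer.max, 1))
      })
      names(series) <- cohort$subject_id
    }
    out <- structure(list(cohort = cohort, series = series, truth = truth,
                          design = design),
                     class = "synthetic_cohort")
    attr(out, "n_clipped") <- n_clipped
    if (n_clipped > 0) {
      message(sprintf("%d symptom score(s) clipped to the 0-40 range.",
                      n_clipped))
    }
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d controls, %d regions%s\n",
              sum(x$cohort$group == "patient"),
              sum(x$cohort$group == "control"),
              x$design$n_regions,
              if (is.null(x$series)) " (summary-level only)" else
                sprintf(", T = %d at TR = %g s", x$design$n_timepoints,
                        x$design$tr)))
  invisible(x)
}

#' Write a cohort table as TSV
#'
#' @param cohort A `synthetic_cohort` or its `cohort` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  tab <- if (inherits(cohort, "synthetic_cohort")) cohort$cohort else cohort
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
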