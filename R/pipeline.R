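#' Run the full dynamic-connectivity analysis end to end
#'
#' Orchestrates the chain: generate (or ingest) region time series per
#' subject, optionally convolve to BOLD and blind-deconvolve back (exercising
#' the hemodynamic stage), fit the Kalman dMVAR, summarize each connection's
#' mean and SD, apply the motion exclusion rule, and run the statistics layer
#' (MANCOVA, post-hoc group regressions, symptom regression, medication
#' interaction where both strata exist). Every intermediate can be persisted
#' to `output_dir` as TSV/JSON.
#'
#' @param design A [cohort_design()] (synthetic mode), or `NULL` when
#'   `series` and `cohort` are supplied directly.
#' @param series Named list of [neural_ts()]/[bold_ts()] per subject
#'   (ignored in synthetic mode).
#' @param cohort Subject table (one row per subject) matching `series`.
#' @param config A [dmvar_config()]; its `connections` defaults to all
#'   ordered pairs of the series' regions.
#' @param hemodynamics Convolve the synthetic neural series with a canonical
#'   hemodynamic response and blind-deconvolve before fitting (default TRUE in
#'   synthetic mode); exercises the full observation model.
#' @param target_label Connection label (see `dec_trajectory` columns) whose
#'   summary feeds the group and symptom models; default is the design's
#'   target connection.
#' @param output_dir Directory for intermediates; `NULL` keeps everything in
#'   memory.
#' @param seed Seed for the synthetic stages; defaults to the design's.
#' @return A `pipeline_result` list: `cohort` (analysis-ready tibble with
#'   DEC summaries and exclusion flags), `summaries`, `stats` (list:
#'   `mancova`, `posthoc`, `symptom`, `medication`), `config`, `seed`.
#' @export
run_pipeline <- function(design = NULL, series = NULL, cohort = NULL,
                         config = dmvar_config(), hemodynamics = TRUE,
                         target_label = NULL, output_dir = NULL,
                         seed = NULL) {
  if (!is.null(design)) {
    stopifnot(inherits(design, "cohort_design"))
    if (!is.null(seed)) design$seed <- as.integer(seed)
    syn <- generate_cohort(design, generate_series = TRUE)
    series <- syn$series
    cohort <- syn$cohort
    tgt <- design$target_connection
    if (is.null(target_label)) {
      target_label <- paste0("R", tgt[1], "->R", tgt[2])
    }
  } else {
    if (is.null(series) || is.null(cohort)) {
      stop("supply either `design` or both `series` and `cohort`.",
           call. = FALSE)
    }
    cohort <- as_tibble(cohort)
  }
  stopifnot(length(series) == nrow(cohort))
  run_seed <- seed %||% (if (!is.null(design)) design$seed else NA_integer_)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_tsv(cohort, file.path(output_dir, "cohort.tsv"))
  }

  summaries <- purrr::imap_dfr(series, function(s, id) {
    x <- s
    if (hemodynamics) {
      bold <- convolve_hrf(if (inherits(s, "bold_ts"))
        neural_ts(s$values, dt = s$tr, regions = s$regions) else s,
        canonical_hrf(dt = if (inherits(s, "bold_ts")) s$tr else s$dt))
      x <- deconvolve_bold(bold)$neural
    }
    x$values <- standardize_columns(x$values)
    traj <- suppressWarnings(fit_dmvar_kalman(x, config))
    if (!is.null(output_dir)) {
      utils::write.table(
        traj$values, file.path(output_dir, paste0("dec_", id, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    summarize_dec(traj, subject_id = id)
  })

  if (is.null(target_label)) target_label <- summaries$connection[1]
  if (!target_label %in% summaries$connection) {
    stop(sprintf("target connection '%s' not among fitted connections.",
                 target_label), call. = FALSE)
  }

  wide <- summaries |>
    dplyr::filter(.data$connection == target_label) |>
    dplyr::select("subject_id", target_dec_mean = "dec_mean",
                  target_dec_sd = "dec_sd")
  analysis <- dplyr::left_join(cohort, wide, by = "subject_id") |>
    flag_high_motion()
  kept <- dplyr::filter(analysis, !.data$excluded_motion)

  # outcomes for the omnibus test: the target plus up to two other connections
  other <- setdiff(unique(summaries$connection), target_label)
  dv_conns <- c(target_label, head(other, 2))
  dv_wide <- summaries |>
    dplyr::filter(.data$connection %in% dv_conns) |>
    dplyr::select("subject_id", "connection", "dec_mean") |>
    tidyr::pivot_wider(names_from = "connection", values_from = "dec_mean")
  kept <- dplyr::left_join(kept, dv_wide, by = "subject_id")

  two_groups <- length(unique(kept$group)) == 2
  stats_out <- list(mancova = NULL, posthoc = NULL, symptom = NULL,
                    medication = NULL)
  if (two_groups) {
    # the omnibus test needs enough residual df; small smoke-test cohorts
    # still get the per-connection regressions
    if (nrow(kept) > length(dv_conns) + 5) {
      stats_out$mancova <- mancova_pillai(
        kept, dv_conns, "group", c("age", "gender", "dvars"))
    }
    stats_out$posthoc <- posthoc_group_regressions(
      kept, dv_conns, group = "group")
  }
  patients <- dplyr::filter(kept, .data$group == "patient")
  if (nrow(patients) > length(dv_conns) + 2) {
    stats_out$symptom <- symptom_regression(patients, "ybocs", dv_conns)
    if (length(unique(patients$medicated)) == 2) {
      stats_out$medication <- medication_interaction(
        patients, "ybocs", target_label)
    }
  }

  result <- structure(
    list(cohort = analysis, summaries = summaries, stats = stats_out,
         config = config, target = target_label, seed = run_seed),
    class = "pipeline_result")
  if (!is.null(output_dir)) {
    utils::write.table(analysis, file.path(output_dir, "analysis_ready.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      stats_report_json(result),
      file.path(output_dir, "stats_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

stats_report_json <- function(x) {
  st <- x$stats
  list(
    seed = x$seed,
    target_connection = x$target,
    n_subjects = nrow(x$cohort),
    n_excluded_motion = sum(x$cohort$excluded_motion),
    mancova = if (!is.null(st$mancova)) as.list(glance(st$mancova)),
    posthoc = if (!is.null(st$posthoc)) st$posthoc,
    symptom = if (!is.null(st$symptom)) st$symptom,
    medication = if (!is.null(st$medication)) st$medication$model
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects (%d excluded for motion), target %s\n",
              nrow(x$cohort), sum(x$cohort$excluded_motion), x$target))
  if (!is.null(x$stats$mancova)) {
    m <- x$stats$mancova
    cat(sprintf("  MANCOVA: Pillai = %.3f, F(%d, %d) = %.3f, p = %.3f\n",
                m$pillai, m$df_hyp, m$df_err, m$f, m$p))
  }
  invisible(x)
}

#' Formatted study report tables
#'
#' Builds a demographics comparison table (group means/SDs with pooled t or
#' continuity-corrected chi-squared tests, the shape of a clinical Table 1)
#' and, when group statistics exist, an effect-size table (Cohen's d with CI
#' per connection).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return A list of tibbles: `demographics`, `effect_sizes` (NULL for a
#'   single-group cohort).
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  tab <- result$cohort
  if (nrow(tab) == 0) stop("empty cohort.", call. = FALSE)
  groups <- unique(tab$group)
  demo_rows <- purrr::map_dfr(c("age", "dvars", "ybocs", "madrs", "hama"),
    function(v) {
      if (!v %in% names(tab)) return(NULL)
      if (length(groups) == 2) {
        g1 <- tab[[v]][tab$group == groups[1]]
        g2 <- tab[[v]][tab$group == groups[2]]
        tt <- pooled_t_from_summary(mean(g1), sd(g1), length(g1),
                                    mean(g2), sd(g2), length(g2))
        tibble(variable = v,
               group1 = sprintf("%.2f (%.2f)", mean(g1), sd(g1)),
               group2 = sprintf("%.2f (%.2f)", mean(g2), sd(g2)),
               statistic = tt$t, df = as.numeric(tt$df), p = tt$p)
      } else {
        g1 <- tab[[v]]
        tibble(variable = v,
               group1 = sprintf("%.2f (%.2f)", mean(g1), sd(g1)),
               group2 = NA_character_, statistic = NA_real_,
               df = NA_real_, p = NA_real_)
      }
    })
  if ("gender" %in% names(tab) && length(groups) == 2) {
    cnt <- table(tab$group, tab$gender)
    if (all(dim(cnt) == c(2, 2)) && all(rowSums(cnt) > 0) &&
        all(colSums(cnt) > 0)) {
      ch <- yates_chi2(cnt[1, 2], cnt[1, 1], cnt[2, 2], cnt[2, 1])
      demo_rows <- dplyr::bind_rows(demo_rows, tibble(
        variable = "gender(female)",
        group1 = as.character(cnt[1, 2]), group2 = as.character(cnt[2, 2]),
        statistic = ch$chisq, df = as.numeric(ch$df), p = ch$p))
    }
  }
  effects <- NULL
  if (!is.null(result$stats$posthoc)) {
    ns <- table(tab$group)
    effects <- purrr::pmap_dfr(result$stats$posthoc, function(...) {
      row <- list(...)
      es <- cohens_d_from_t(row$t, ns[[1]], ns[[2]])
      tibble(connection = row$connection, beta = row$estimate,
             t = row$t, df = row$df, p_bonferroni = row$p_bonferroni,
             d = es$d, d_ci_low = es$ci_low, d_ci_high = es$ci_high)
    })
  }
  list(demographics = demo_rows, effect_sizes = effects)
}
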