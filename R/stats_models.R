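#' One-factor MANCOVA with Pillai's trace
#'
#' Tests an omnibus group difference on a set of connectivity outcomes,
#' adjusting for covariates: the group term's hypothesis/error SSCP matrices
#' are formed with the covariates partialled out (covariates entered before
#' group, so the group test is covariate-adjusted), and Pillai's trace
#' \eqn{V = \mathrm{tr}[H (H + E)^{-1}]} is converted to an F approximation.
#' For a two-level factor with `q` outcomes the error df is
#' `n - rank(design) - q + 1`.
#'
#' @param data Data frame, one row per subject.
#' @param outcomes Character vector naming the outcome (dependent) columns.
#' @param group Name of the grouping column (2 levels).
#' @param covariates Character vector of covariate columns (may be empty).
#' @return A `mancova_result`: one-row tibble with `pillai`, `f`, `df_hyp`,
#'   `df_err`, `p`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' df <- data.frame(y1 = rnorm(40), y2 = rnorm(40), y3 = rnorm(40),
#'                  group = rep(c("a", "b"), 20), age = rnorm(40, 30, 8),
#'                  gender = rbinom(40, 1, 0.5), dvars = rlnorm(40))
#' mancova_pillai(df, c("y1", "y2", "y3"), "group",
#'                c("age", "gender", "dvars"))
mancova_pillai <- function(data, outcomes, group,
                           covariates = character()) {
  data <- as.data.frame(data)
  stopifnot(all(c(outcomes, group, covariates) %in% names(data)))
  data <- data[complete.cases(data[, c(outcomes, group, covariates)]), ]
  n <- nrow(data)
  q <- length(outcomes)
  if (n <= length(covariates) + q + 2) {
    stop("too few subjects for the requested design.", call. = FALSE)
  }
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) stop("`group` must have exactly 2 levels.", call. = FALSE)
  X_cov <- cbind(`(Intercept)` = 1,
                 as.matrix(data[, covariates, drop = FALSE]))
  X_full <- cbind(X_cov, group = as.numeric(g == levels(g)[2]))
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    drop_cols <- colnames(X_full)[setdiff(seq_len(ncol(X_full)),
                                          qr_full$pivot[seq_len(qr_full$rank)])]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(drop_cols, collapse = ", ")), call. = FALSE)
  }
  Y <- as.matrix(data[, outcomes, drop = FALSE])
  res_full <- Y - X_full %*% qr.coef(qr_full, Y)
  res_red <- Y - X_cov %*% qr.coef(qr(X_cov), Y)
  E <- crossprod(res_full)
  H <- crossprod(res_red) - E
  V <- sum(diag(H %*% solve(H + E)))
  # F approximation; s = min(q, hypothesis df) = 1 for a 2-level factor
  s <- 1
  df_hyp <- q
  df_err <- n - ncol(X_full) - q + 1
  f <- (V / s) / ((s - V) / s) * df_err / df_hyp
  structure(
    tibble(pillai = V, f = f, df_hyp = df_hyp, df_err = df_err,
           p = pf(f, df_hyp, df_err, lower.tail = FALSE), n = n),
    class = c("mancova_result", class(tibble())))
}

#' @exportS3Method
glance.mancova_result <- function(x, ...) as_tibble(unclass(x))

# backquote non-syntactic column names for formula interfaces
bq <- function(x) ifelse(make.names(x) == x, x, sprintf("`%s`", x))

ols_term_tibble <- function(fit, term, m = 1L) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm) && sprintf("`%s`", term) %in% rownames(sm)) {
    rownames(sm)[rownames(sm) == sprintf("`%s`", term)] <- term
  }
  if (!term %in% rownames(sm)) {
    stop(sprintf("term `%s` absent from the fitted model (degenerate design?).",
                 term), call. = FALSE)
  }
  tibble(
    term = term,
    estimate = sm[term, "Estimate"],
    std_error = sm[term, "Std. Error"],
    t = sm[term, "t value"],
    df = fit$df.residual,
    p = sm[term, "Pr(>|t|)"],
    p_bonferroni = pmin(1, m * sm[term, "Pr(>|t|)"])
  )
}

#' Post-hoc covariate-adjusted group regressions
#'
#' One ordinary least-squares model per connection:
#' `dec ~ group + age + gender + dvars` (covariates configurable). The group
#' coefficient is the covariate-adjusted group difference; its p-value is
#' Bonferroni-corrected over the connection family.
#'
#' @param data Data frame, one row per subject.
#' @param outcomes Character vector of connection-summary columns.
#' @param group Grouping column (2 levels; the reported coefficient is for the
#'   second level relative to the first).
#' @param covariates Covariate columns, default `age`, `gender`, `dvars`.
#' @param family_size Bonferroni family size `m`; defaults to
#'   `length(outcomes)`.
#' @return A tibble, one row per connection: `connection`, `estimate`,
#'   `std_error`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
posthoc_group_regressions <- function(data, outcomes, group = "group",
                                      covariates = c("age", "gender", "dvars"),
                                      family_size = NULL) {
  data <- as.data.frame(data)
  stopifnot(all(c(outcomes, group, covariates) %in% names(data)))
  m <- family_size %||% length(outcomes)
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) {
    stop("`group` must take exactly 2 values (degenerate design).",
         call. = FALSE)
  }
  data$.group <- as.numeric(g == levels(g)[2])
  purrr::map_dfr(outcomes, function(conn) {
    fml <- stats::reformulate(c(".group", bq(covariates)), response = bq(conn))
    fit <- lm(fml, data = data)
    dplyr::bind_cols(tibble(connection = conn),
                     ols_term_tibble(fit, ".group", m = m)[-1])
  })
}

#' Symptom-severity regression on connection means
#'
#' Multiple linear regression of a symptom score on the mean connectivity of
#' a set of connections (all entered together), with Bonferroni correction
#' over the connection family.
#'
#' @param data Data frame, one row per subject (typically patients only).
#' @param symptom Name of the symptom-score column.
#' @param connections Character vector of connection-summary columns.
#' @param family_size Bonferroni family size; defaults to
#'   `length(connections)`.
#' @return A tibble, one row per connection coefficient.
#' @export
symptom_regression <- function(data, symptom, connections,
                               family_size = NULL) {
  data <- as.data.frame(data)
  stopifnot(all(c(symptom, connections) %in% names(data)))
  if (nrow(data) <= 4) stop("need more than 4 subjects.", call. = FALSE)
  m <- family_size %||% length(connections)
  X <- as.matrix(data[, connections, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(connections) + 1) {
    stop("connection regressors are collinear.", call. = FALSE)
  }
  fit <- lm(stats::reformulate(bq(connections), response = bq(symptom)),
            data = data)
  purrr::map_dfr(connections, function(conn) {
    dplyr::bind_cols(tibble(connection = conn),
                     ols_term_tibble(fit, conn, m = m)[-1])
  })
}

#' Medication-moderation model for a symptom-connectivity association
#'
#' Fits `symptom ~ dec * medicated` (main effects plus interaction) and, in
#' addition, the within-stratum Pearson correlation between connectivity and
#' symptom score for the medicated and unmedicated subgroups separately
#' (Fisher-z intervals via [pearson_test()]).
#'
#' @param data Data frame with the symptom, connectivity and medication
#'   columns; both strata must be non-empty.
#' @param symptom,dec,medicated Column names (medication binary).
#' @return A list with `model` (tibble of all four coefficients) and `strata`
#'   (tibble of per-stratum correlation inference).
#' @export
medication_interaction <- function(data, symptom, dec,
                                   medicated = "medicated") {
  data <- as.data.frame(data)
  stopifnot(all(c(symptom, dec, medicated) %in% names(data)))
  med <- as.numeric(data[[medicated]] != 0)
  if (length(unique(med)) < 2) {
    stop("both medication strata must be non-empty.", call. = FALSE)
  }
  data$.med <- med
  fml <- stats::as.formula(paste(bq(symptom), "~", bq(dec), "*", ".med"))
  fit <- lm(fml, data = data)
  sm <- summary(fit)$coefficients
  model <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    t = sm[, "t value"],
    df = fit$df.residual,
    p = sm[, "Pr(>|t|)"]
  )
  strata <- purrr::map_dfr(c(medicated = 1, unmedicated = 0), function(lvl) {
    sub <- data[data$.med == lvl, ]
    if (nrow(sub) < 4) {
      # too few subjects for correlation inference in this stratum
      return(tibble(r = NA_real_, n = nrow(sub), t = NA_real_, p = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, degenerate = TRUE))
    }
    r <- cor(sub[[dec]], sub[[symptom]])
    pearson_test(r, nrow(sub))
  }, .id = "stratum")
  list(model = model, strata = strata)
}
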