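#' Classify treatment response and remission
#'
#' Evaluated at each patient's last recorded assessment: response is a
#' reduction of the HRSD-17 sum score by at least 50% relative to
#' baseline (the first assessment); remission is a final sum score of 7
#' or lower.
#'
#' @inheritParams write_cohort
#' @return A tibble with one row per patient: `patient_id`,
#'   `n_assessments`, `baseline_sum`, `last_sum`, `responder`, `remitter`.
#'   A baseline sum of 0 makes response undefined; `responder` is `NA`
#'   for such patients and a warning is raised.
#' @examples
#' classify_outcomes(simulate_cohort(n_patients = 20, seed = 1))
#' @export
classify_outcomes <- function(cohort) {
  ss <- sum_scores(cohort)
  out <- ss |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$week, .by_group = TRUE) |>
    dplyr::summarise(
      n_assessments = dplyr::n(),
      baseline_sum = dplyr::first(.data$sum_score),
      last_sum = dplyr::last(.data$sum_score),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      responder = dplyr::if_else(.data$baseline_sum > 0,
                                 .data$last_sum <= 0.5 * .data$baseline_sum,
                                 NA),
      remitter = .data$last_sum <= 7
    )
  if (anyNA(out$responder)) {
    warning(sum(is.na(out$responder)),
            " patient(s) with baseline sum 0: response undefined", call. = FALSE)
  }
  out
}

#' Network density versus treatment outcome
#'
#' Summarizes each patient's symptom network density as the mean of the
#' off-diagonal DTW distances among the included item trajectories — a
#' shorter mean distance means denser, more synchronous symptom dynamics —
#' and compares it between responders and non-responders and between
#' remitters and non-remitters.  By default the mean distances are first
#' adjusted by taking the residuals of a single ordinary least-squares
#' regression (all patients pooled) on the number of assessments and the
#' baseline HRSD-17 sum score; groups are then compared with the Wilcoxon
#' rank-sum test (exact for small samples without ties, otherwise the
#' normal approximation with tie correction).
#'
#' @inheritParams write_cohort
#' @param adjust Residualize on number of assessments and baseline sum
#'   (default `TRUE`).  A covariate that is constant across patients is
#'   dropped from the regression with a warning.
#' @param exclude_all_zero Drop items scoring 0 throughout follow-up
#'   before averaging (default `TRUE`; such items only contribute
#'   zero-distance pairs).
#' @param window Sakoe-Chiba band half-width.
#' @return A `density_comparison` with `data` (tibble: `patient_id`,
#'   `mean_distance`, `residual`, `n_assessments`, `baseline_sum`,
#'   `responder`, `remitter`), `tests` (tibble: `contrast`, `statistic`,
#'   `p.value`, group medians and sizes), and `fit`, the adjustment
#'   regression (or `NULL`).
#' @examples
#' dc <- density_comparison(simulate_cohort(n_patients = 40, seed = 2))
#' glance(dc)
#' @export
density_comparison <- function(cohort, adjust = TRUE, exclude_all_zero = TRUE,
                               window = 2) {
  mats <- cohort_distance_matrices(cohort, window = window,
                                   exclude_all_zero = exclude_all_zero)
  mean_d <- vapply(mats, function(m) {
    d <- unclass(m)
    if (nrow(d) < 2) return(NA_real_)
    mean(d[upper.tri(d)])
  }, double(1))
  outcomes <- classify_outcomes(cohort)
  data <- outcomes |>
    dplyr::mutate(mean_distance = mean_d[.data$patient_id]) |>
    dplyr::filter(!is.na(.data$mean_distance))

  fit <- NULL
  if (adjust) {
    covs <- c("n_assessments", "baseline_sum")
    constant <- vapply(covs, function(v) var(data[[v]]) < 1e-12, logical(1))
    if (any(constant)) {
      warning("constant covariate(s) dropped from adjustment: ",
              paste(covs[constant], collapse = ", "), call. = FALSE)
      covs <- covs[!constant]
    }
    if (length(covs) > 0) {
      fit <- lm(stats::reformulate(covs, "mean_distance"), data = data)
      data$residual <- unname(residuals(fit))
    } else {
      data$residual <- data$mean_distance - mean(data$mean_distance)
    }
  } else {
    data$residual <- data$mean_distance
  }

  tests <- dplyr::bind_rows(
    density_test(data, "responder"),
    density_test(data, "remitter")
  )
  structure(
    list(data = dplyr::relocate(data, "patient_id", "mean_distance", "residual"),
         tests = tests, fit = fit, adjust = adjust,
         exclude_all_zero = exclude_all_zero),
    class = "density_comparison"
  )
}

density_test <- function(data, group) {
  g <- data[[group]]
  x <- data$residual[!is.na(g) & g]       # outcome reached
  y <- data$residual[!is.na(g) & !g]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble::tibble(contrast = group, statistic = NA_real_, p.value = NA_real_,
                          n_yes = length(x), n_no = length(y),
                          median_yes = NA_real_, median_no = NA_real_))
  }
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble::tibble(
    contrast = group,
    statistic = unname(wt$statistic),
    p.value = wt$p.value,
    n_yes = length(x), n_no = length(y),
    median_yes = median(x), median_no = median(y)
  )
}

#' @export
print.density_comparison <- function(x, ...) {
  cat("Network density (mean DTW distance) vs outcome",
      if (x$adjust) "(adjusted)" else "(unadjusted)", "\n")
  print(x$tests)
  invisible(x)
}

#' @describeIn density_comparison Per-patient densities as a tibble.
#' @param x A `density_comparison`.
#' @param ... Unused.
#' @method tidy density_comparison
#' @export
tidy.density_comparison <- function(x, ...) x$data

#' @describeIn density_comparison The rank-test results, one row per
#'   contrast.
#' @method glance density_comparison
#' @export
glance.density_comparison <- function(x, ...) x$tests

#' Per-item linear mixed trajectory models
#'
#' Fits, for each HRSD-17 item, a linear mixed model of the (rescaled)
#' item score on time with a fixed intercept, a fixed slope per 2-week
#' interval, and a patient-level random intercept (REML).  The eight
#' items with a 0-2 range are doubled before fitting so that all
#' trajectories live on the common 0-4 scale.
#'
#' @inheritParams write_cohort
#' @param items Item numbers to fit (default all 17).
#' @return A tibble with one row per item: `item`, `label`, `intercept`
#'   (baseline level on the 0-4 scale), `slope` (change per 2-week
#'   interval), their standard errors, and `sd_intercept` /
#'   `sd_residual`, the random-effect and residual standard deviations.
#'   An item with no within-patient variance is flagged (`degenerate`)
#'   and fitted by ordinary least squares on the patient means (slope 0).
#' @examples
#' item_trajectory_models(simulate_cohort(n_patients = 30, seed = 3),
#'                        items = c(1, 7))
#' @export
item_trajectory_models <- function(cohort, items = 1:17) {
  catalog <- hrsd_items()
  purrr::map_dfr(items, function(k) {
    scale_fac <- if (catalog$max_score[k] == 2) 2 else 1
    df <- tibble::tibble(
      patient_id = cohort$patient_id,
      interval = cohort$week / 2,
      y = cohort[[item_cols()[k]]] * scale_fac
    )
    within_var <- df |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(v = var(.data$y), .groups = "drop")
    if (all(within_var$v < 1e-12, na.rm = TRUE)) {
      return(tibble::tibble(
        item = k, label = catalog$label[k],
        intercept = mean(df$y), slope = 0,
        se_intercept = NA_real_, se_slope = NA_real_,
        sd_intercept = sd(tapply(df$y, df$patient_id, mean)),
        sd_residual = 0, degenerate = TRUE
      ))
    }
    fit <- lme4::lmer(y ~ interval + (1 | patient_id), data = df, REML = TRUE)
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    tibble::tibble(
      item = k, label = catalog$label[k],
      intercept = unname(fe["(Intercept)"]), slope = unname(fe["interval"]),
      se_intercept = se[1], se_slope = se[2],
      sd_intercept = vc$sdcor[vc$grp == "patient_id"],
      sd_residual = vc$sdcor[vc$grp == "Residual"],
      degenerate = FALSE
    )
  })
}

#' Cronbach's alpha of the HRSD-17 at one visit
#'
#' `alpha = k/(k-1) * (1 - sum(var(item_i)) / var(total))` with sample
#' variances (n - 1 denominator).  In the source setting alpha is low at
#' baseline and rises during admission, reflecting the heterogeneity of
#' depressive symptoms early in treatment.
#'
#' @param x A patients x items numeric matrix of scores at a single
#'   visit, or a cohort tibble together with `week`.
#' @param week Visit week to extract when `x` is a cohort tibble
#'   (default 0, baseline); only patients assessed at that week enter.
#' @return A scalar; errors when the total-score variance is zero.
#' @examples
#' cronbach_alpha(simulate_cohort(n_patients = 50, seed = 4), week = 0)
#' @export
cronbach_alpha <- function(x, week = 0) {
  if (is.data.frame(x)) {
    rows <- x[x$week == week, , drop = FALSE]
    x <- as.matrix(rows[, item_cols()])
  }
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 patients and 2 items", call. = FALSE)
  k <- ncol(x)
  item_var <- apply(x, 2, var)
  total_var <- var(rowSums(x))
  if (total_var < 1e-12) stop("zero total-score variance: alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}
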