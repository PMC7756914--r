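#' The planted five-cluster structure of the generator
#'
#' Item groups whose trajectories share a latent factor in
#' [simulate_cohort()]: core symptoms (depressed mood, work and
#' interests), the three insomnia items, distress (guilt, psychic
#' anxiety), somatic (general somatic, genital symptoms), and inner
#' turmoil (the remaining eight items).
#'
#' @return A named list of integer item vectors.
#' @export
cluster_map <- function() {
  list(
    core = c(1L, 7L),
    sleep = c(4L, 5L, 6L),
    distress = c(2L, 10L),
    somatic = c(13L, 14L),
    turmoil = c(3L, 8L, 9L, 11L, 12L, 15L, 16L, 17L)
  )
}

# Internal generator constants, fixed once by calibrating against the
# cohort summary targets (baseline sum 20.7 +/- 4.6, mean 5.8 / median 5
# assessments, ~66% responders) and the requirement that the planted
# five-cluster structure be identifiable from raw-score DTW distances.
# Item means are on the latent 0-4 scale (0-2 items are halved on
# output); fluctuation amplitudes are doubled for 0-2 items so their
# observed dynamics match the 0-4 items, and raised for the large
# turmoil cluster whose shared factor must bind items of both types.
sim_constants <- function() {
  mu <- c(1.497, 1.836, 1.243, 2.204, 2.147, 2.091, 1.441, 1.243, 1.300,
          1.893, 1.356, 2.486, 2.712, 2.656, 1.187, 2.430, 2.373)
  amp <- rep(0.95, 17)
  amp[c(4L, 5L, 6L, 12L, 13L, 14L, 16L, 17L)] <- 1.90
  amp[cluster_map()$turmoil] <- amp[cluster_map()$turmoil] * 1.2
  list(
    item_mean = mu,
    fluct_amp = amp,
    decline_mult = c(core = 1.2, sleep = 1.0, distress = 1.1,
                     somatic = 0.8, turmoil = 0.95),
    decline_q = 0.55,               # front-loading of the decline profile
    ar_rho = 0.6,                   # AR(1) memory of latent fluctuations
    sigma_cluster = 1.0,            # marginal SD of cluster factor paths
    sigma_common = 0.12,            # marginal SD of the patient-level factor
    sigma_severity = 0.21,          # SD of the patient severity multiplier
    R_fast = 1.25, R_fast_sd = 0.20,  # total decline potential by propensity
    R_slow = 0.25, R_slow_sd = 0.15,
    p_fast = 0.72,                  # planted fast-response propensity
    nb_size = 2.5, nb_mu = 3.95     # shifted negative binomial for T
  )
}

default_zero_inflation <- function() {
  c(0.00, 0.05, 0.04, 0.08, 0.06, 0.10, 0.00, 0.04, 0.04, 0.02,
    0.03, 0.06, 0.04, 0.08, 0.04, 0.10, 0.12)
}

# AR(1) fluctuation path of length n anchored at 0 (baseline reflects
# severity only; trajectories diverge from the first follow-up on).
ar1_path <- function(n, rho, sigma) {
  x <- numeric(n)
  if (n > 1) {
    e <- rnorm(n - 1)
    w <- sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1] + w * e[t - 1]
  }
  sigma * x
}

#' Simulate an HRSD-17-like longitudinal cohort
#'
#' Generates a seeded synthetic cohort of depressed inpatients assessed
#' biweekly with the HRSD-17, with known latent structure standing in for
#' non-public clinical data.  Per patient, the number of assessments T is
#' drawn from a shifted negative binomial truncated to 2-17 (mean about
#' 5.8, median 5); a severity multiplier and a total decline potential
#' `R` (larger for patients with a planted fast-response propensity)
#' shape a front-loaded declining trend shared by all items,
#' `m_c(t) = max(0, 1 - d_c R (1 - 0.55^t))`, with mild cluster-specific
#' multipliers `d_c` (core symptoms steepest).  Five latent cluster
#' factors — first-order autoregressive fluctuation paths anchored at 0
#' at baseline, one per group of [cluster_map()] — and a patient-level
#' common factor drive the item trajectories.  The item score at each
#' visit is the trend plus `loading` times the item's own cluster factor,
#' `cross_loading` times the mean of the other factors, the common
#' factor, and noise; the latent value is rounded and clipped into the
#' item's range (0-2 items are generated on the 0-4 scale and halved).
#' With probability `zero_inflation[j]` an item's trajectory is
#' identically 0 (highest for weight loss and insight).
#'
#' `synchrony_gain` links trajectory synchrony to treatment response: for
#' fast-propensity patients it shifts latent variance from the cluster-
#' specific factors to the shared common factor, making their item
#' trajectories more synchronous and hence their mean within-patient DTW
#' distance shorter.  At `synchrony_gain = 0` the variance mix is
#' identical in both propensity groups (outcome labels can still relate
#' to network density through the bounded scale: a recovered patient's
#' items are compressed against the floor).  Realized responder/remitter
#' labels always come from [classify_outcomes()] applied to the
#' generated sums, keeping them consistent with the operational outcome
#' definitions.
#'
#' @param n_patients Number of patients (default 255).
#' @param seed Integer seed; same seed, same cohort.  `NULL` uses the
#'   current RNG state.
#' @param loading Item loading on its own cluster factor (default 0.8).
#' @param cross_loading Loading on the mean of the other four factors
#'   (default 0.1).
#' @param synchrony_gain Response-linked synchrony strength (default
#'   0.75; 0 removes the planted link).
#' @param noise_sd SD of the item-level measurement noise on the latent
#'   0-4 scale (default 0.22).
#' @param zero_inflation Per-item probability of an identically-zero
#'   trajectory, length 17.
#' @return A cohort tibble (`patient_id`, `week`, `item_1` ...
#'   `item_17`) with attribute `truth`: a list with `items` (tibble of
#'   planted cluster labels), `patients` (tibble of planted propensities,
#'   decline potentials, severities, T), and `config`.  Retrieve it with
#'   [cohort_truth()].
#' @examples
#' cohort <- simulate_cohort(n_patients = 20, seed = 42)
#' calibration_report(cohort)
#' @export
simulate_cohort <- function(n_patients = 255, seed = NULL,
                            loading = 0.8, cross_loading = 0.1,
                            synchrony_gain = 0.75, noise_sd = 0.22,
                            zero_inflation = default_zero_inflation()) {
  stopifnot(n_patients >= 1, loading >= 0, cross_loading >= 0,
            synchrony_gain >= 0, noise_sd >= 0)
  if (length(zero_inflation) != 17 || any(zero_inflation < 0 | zero_inflation > 1)) {
    stop("`zero_inflation` must be 17 probabilities", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  cst <- sim_constants()
  cmap <- cluster_map()
  item_cluster <- integer(17)
  for (c in seq_along(cmap)) item_cluster[cmap[[c]]] <- c
  maxes <- item_max()

  # T: shifted negative binomial truncated to 2..17
  pmf <- stats::dnbinom(0:15, size = cst$nb_size, mu = cst$nb_mu)
  pmf <- pmf / sum(pmf)
  T_p <- sample(2:17, n_patients, replace = TRUE, prob = pmf)

  fast <- rbinom(n_patients, 1, cst$p_fast) == 1
  R_p <- pmax(rnorm(n_patients,
                    ifelse(fast, cst$R_fast, cst$R_slow),
                    ifelse(fast, cst$R_fast_sd, cst$R_slow_sd)), 0)
  sev <- pmax(1 + cst$sigma_severity * rnorm(n_patients), 0.3)

  rows <- vector("list", n_patients)
  ids <- sprintf("P%03d", seq_len(n_patients))
  for (i in seq_len(n_patients)) {
    Ti <- T_p[i]
    tt <- 0:(Ti - 1)
    # response-linked variance mix between shared and specific components
    g <- if (fast[i]) synchrony_gain else 0
    idio <- 1 / sqrt(1 + g)
    shared <- sqrt(1 + g)
    fl <- vapply(1:5,
                 function(c) ar1_path(Ti, cst$ar_rho, cst$sigma_cluster * idio),
                 double(Ti))                       # Ti x 5 cluster factors
    u <- ar1_path(Ti, cst$ar_rho, cst$sigma_common * shared)

    zero_item <- runif(17) < zero_inflation
    scores <- matrix(0L, Ti, 17)
    for (j in 1:17) {
      if (zero_item[j]) next
      c_j <- item_cluster[j]
      profile <- pmax(1 - cst$decline_mult[c_j] * R_p[i] * (1 - cst$decline_q^tt), 0)
      trend <- cst$item_mean[j] * sev[i] * profile
      others <- rowMeans(fl[, -c_j, drop = FALSE])
      y <- trend + cst$fluct_amp[j] *
        (loading * fl[, c_j] + cross_loading * others + u) +
        rnorm(Ti, 0, noise_sd)
      if (maxes[j] == 2) y <- y / 2
      scores[, j] <- pmin(pmax(as.integer(round(y)), 0L), maxes[j])
    }
    rows[[i]] <- tibble::tibble(
      patient_id = ids[i],
      week = 2L * tt,
      !!!setNames(as.data.frame(scores), item_cols())
    )
  }
  cohort <- dplyr::bind_rows(rows)

  truth <- list(
    items = tibble::tibble(
      item = 1:17,
      cluster = names(cmap)[item_cluster],
      cluster_id = item_cluster
    ),
    patients = tibble::tibble(
      patient_id = ids,
      fast_propensity = fast,
      decline_potential = R_p,
      severity = sev,
      n_assessments = T_p
    ),
    config = list(
      n_patients = n_patients, seed = seed, loading = loading,
      cross_loading = cross_loading, synchrony_gain = synchrony_gain,
      noise_sd = noise_sd, zero_inflation = zero_inflation
    )
  )
  attr(cohort, "truth") <- truth
  cohort
}

#' Ground truth of a simulated cohort
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return The `truth` list (planted item clusters, patient propensities,
#'   generator configuration).
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("`cohort` carries no ground truth (not simulated?)", call. = FALSE)
  truth
}

#' Calibration report of a cohort against the target summaries
#'
#' Summarizes a (typically simulated) cohort with the statistics used to
#' calibrate the generator: baseline sum mean and SD, assessment-count
#' distribution, responder and remitter proportions, and per-item rates
#' of identically-zero trajectories.
#'
#' @inheritParams write_cohort
#' @return A tibble with columns `metric`, `value`, and `target` (`NA`
#'   where no target is defined).  With a single patient the SD rows are
#'   `NA` (degenerate).
#' @export
calibration_report <- function(cohort) {
  ss <- sum_scores(cohort)
  base <- ss |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(b = .data$sum_score[which.min(.data$week)],
                     n = dplyr::n(), .groups = "drop")
  out <- suppressWarnings(classify_outcomes(cohort))
  mats <- split_patients(cohort)
  zero_rate <- rowMeans(vapply(mats, function(m) colSums(abs(m)) == 0, logical(17)))

  tibble::tibble(
    metric = c("n_patients", "baseline_sum_mean", "baseline_sum_sd",
               "assessments_mean", "assessments_median",
               "responder_prop", "remitter_prop",
               paste0("all_zero_rate_", item_cols())),
    value = unname(c(nrow(base), mean(base$b), sd(base$b),
                     mean(base$n), median(base$n),
                     mean(out$responder, na.rm = TRUE), mean(out$remitter),
                     zero_rate)),
    target = c(255, 20.7, 4.6, 5.8, 5, 0.663, 0.502, rep(NA_real_, 17))
  )
}
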