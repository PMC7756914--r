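#' Idiographic report for one patient
#'
#' Runs the full within-patient pipeline: DTW distance matrix over the
#' included items, Ward.D2 cluster tree cut into `k` groups, and the
#' symptom network with centrality statistics.  Patients with fewer than
#' 3 included items get the distance matrix only, with clustering and
#' network flagged as unavailable rather than failing a cohort run.
#'
#' @inheritParams patient_distance_matrix
#' @param k Cluster count for the report cut (default 3, a readability
#'   convention, not an inferential choice).
#' @param similarity Edge-weight transform for the network, see
#'   [build_network()].
#' @return A `patient_report`: list with `patient_id`, `distance_matrix`,
#'   `tree`, `clusters` (tibble or `NULL`), `network` (or `NULL`), and
#'   `note` (why parts were skipped, if so).
#' @examples
#' cohort <- simulate_cohort(n_patients = 3, seed = 5)
#' rep <- analyze_patient(cohort, patient = "P001")
#' rep$clusters
#' @export
analyze_patient <- function(cohort, patient = NULL, window = 2, k = 3,
                            exclude_all_zero = TRUE,
                            similarity = c("minmax", "inverse")) {
  similarity <- match.arg(similarity)
  D <- suppressWarnings(patient_distance_matrix(
    cohort, patient = patient, window = window,
    exclude_all_zero = exclude_all_zero
  ))
  res <- list(patient_id = attr(D, "patient_id"), distance_matrix = D,
              tree = NULL, clusters = NULL, network = NULL, note = NULL)
  if (length(attr(D, "items")) < 3) {
    res$note <- "insufficient items: fewer than 3 non-zero trajectories"
  } else {
    res$tree <- ward_cluster(D)
    res$clusters <- cut_tree(res$tree, k = min(k, nrow(D)))
    res$network <- tryCatch(build_network(D, similarity = similarity),
                            warning = function(w) {
                              res$note <<- conditionMessage(w)
                              suppressWarnings(build_network(D, similarity = similarity))
                            })
  }
  structure(res, class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("Idiographic DTW report, patient ", x$patient_id, "\n", sep = "")
  cat("  items included: ", length(attr(x$distance_matrix, "items")),
      " (", attr(x$distance_matrix, "n_pairs"), " pairs)\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  if (!is.null(x$clusters)) {
    cat("  clusters (k = ", max(x$clusters$cluster), "):\n", sep = "")
    print(x$clusters, n = 5)
  }
  invisible(x)
}

#' Nomothetic report for a cohort
#'
#' Runs the cohort-level pipeline: assessment-weighted mean distance
#' matrix, Ward.D2 tree with scree/elbow selection of the cluster count
#' (overridable via `k`), cluster labels, symptom network with
#' centralities, the density-versus-outcome comparison, and optionally
#' the Distatis compromise over all per-patient matrices and the per-item
#' mixed trajectory models.
#'
#' @inheritParams write_cohort
#' @param window Sakoe-Chiba band half-width.
#' @param k Cluster count; `NULL` (default) uses the elbow rule.
#' @param k_max Scree depth for the elbow rule.
#' @param exclude_all_zero Apply the all-zero item exclusion when
#'   averaging the cohort matrix (default `FALSE`, so all 136 pairs are
#'   supported by every patient) and within the density comparison
#'   (always applied there by its own default).
#' @param distatis Also run [distatis()] on the full per-patient matrices
#'   (computed without the exclusion, so they are conformable).
#' @param trajectories Also fit [item_trajectory_models()].
#' @param adjust_density Adjust densities for number of assessments and
#'   baseline sum, see [density_comparison()].
#' @param similarity Edge-weight transform for the network.
#' @return A `cohort_report`: list with `distance_matrix`, `tree`,
#'   `scree`, `k`, `clusters`, `network`, `density`, and (optionally)
#'   `distatis`, `trajectories`.
#' @examples
#' rep <- analyze_cohort(simulate_cohort(n_patients = 25, seed = 6))
#' rep$k
#' @export
analyze_cohort <- function(cohort, window = 2, k = NULL, k_max = 8,
                           exclude_all_zero = FALSE, distatis = FALSE,
                           trajectories = FALSE, adjust_density = TRUE,
                           similarity = c("minmax", "inverse")) {
  similarity <- match.arg(similarity)
  Dbar <- cohort_distance(cohort, window = window,
                          exclude_all_zero = exclude_all_zero)
  tree <- ward_cluster(Dbar)
  scree <- scree_and_elbow(tree, k_max = k_max)
  k_used <- if (!is.null(k)) as.integer(k) else scree$k_star
  clusters <- if (!is.na(k_used)) cut_tree(tree, k_used) else NULL
  net <- build_network(Dbar, similarity = similarity)
  dens <- density_comparison(cohort, adjust = adjust_density, window = window)

  res <- list(
    distance_matrix = Dbar, tree = tree, scree = scree,
    k = k_used, k_source = if (!is.null(k)) "manual" else "elbow",
    clusters = clusters, network = net, density = dens
  )
  if (isTRUE(distatis)) {
    mats <- cohort_distance_matrices(cohort, window = window,
                                     exclude_all_zero = FALSE)
    res$distatis <- distatis(mats)
  }
  if (isTRUE(trajectories)) {
    res$trajectories <- item_trajectory_models(cohort)
  }
  structure(res, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Nomothetic DTW report (", length(attr(x$distance_matrix, "weights")),
      " patients)\n", sep = "")
  cat("  clusters: k = ", x$k, " (", x$k_source, ")\n", sep = "")
  if (!is.null(x$clusters)) {
    grp <- split(x$clusters$item, x$clusters$cluster)
    for (g in names(grp)) {
      cat("    ", g, ": items ", paste(grp[[g]], collapse = ", "), "\n", sep = "")
    }
  }
  cat("  density vs outcome:\n")
  print(x$density$tests)
  invisible(x)
}
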