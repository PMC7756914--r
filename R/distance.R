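#' Per-patient DTW distance matrix over HRSD-17 items
#'
#' Computes the DTW distance between every unordered pair of the patient's
#' item trajectories, yielding the symmetric distance matrix at the heart
#' of the idiographic analysis: with all 17 items included it holds
#' (17^2 - 17) / 2 = 136 distinct pairwise distances.  Items scoring 0 at
#' every visit can be excluded beforehand: such items are trivially
#' distance 0 from one another and would cluster together for absence
#' alone.  Exclusion never changes the distance between two retained
#' items.
#'
#' @param cohort A cohort tibble (see [read_cohort()]), or a T x K numeric
#'   matrix of scores (visits in rows, items in columns) for direct use.
#' @param patient Patient id to extract when `cohort` is a tibble; may be
#'   omitted if the tibble holds a single patient.
#' @param window Sakoe-Chiba band half-width in visits (default 2).
#' @param exclude_all_zero Drop items whose trajectory is identically 0
#'   (default `TRUE`, mirroring the idiographic analysis; cohort-level
#'   aggregation and Distatis use `FALSE` so all matrices are conformable).
#' @param normalize Use length-normalized DTW distances.
#' @return A `dtw_distmat`: the symmetric distance matrix with zero
#'   diagonal over the included items, with attributes `items` (included
#'   item numbers), `patient_id`, `n_visits`, and `n_pairs`.  Fewer than 3
#'   included items triggers a degenerate-matrix warning (clustering and
#'   networks need at least 3 nodes).
#' @examples
#' cohort <- simulate_cohort(n_patients = 2, seed = 1)
#' D <- patient_distance_matrix(cohort, patient = unique(cohort$patient_id)[1])
#' attr(D, "n_pairs")
#' @export
patient_distance_matrix <- function(cohort, patient = NULL, window = 2,
                                    exclude_all_zero = TRUE, normalize = FALSE) {
  if (is.matrix(cohort)) {
    scores <- cohort
    if (is.null(colnames(scores))) colnames(scores) <- paste0("item_", seq_len(ncol(scores)))
    pid <- patient %||% NA_character_
  } else {
    if (is.null(patient)) {
      ids <- unique(cohort$patient_id)
      if (length(ids) != 1) stop("`patient` must be given for a multi-patient cohort", call. = FALSE)
      patient <- ids
    }
    scores <- patient_matrix(cohort, patient)
    pid <- patient
  }
  if (nrow(scores) < 2) stop("patient needs at least 2 assessments", call. = FALSE)

  item_no <- as.integer(sub("item_", "", colnames(scores)))
  if (exclude_all_zero) {
    keep <- colSums(abs(scores)) > 0
    scores <- scores[, keep, drop = FALSE]
    item_no <- item_no[keep]
  }
  K <- ncol(scores)
  storage.mode(scores) <- "double"
  D <- .cpp_dtw_pairwise(scores, as.numeric(window))
  if (normalize) D <- D / (2 * nrow(scores))
  dimnames(D) <- list(colnames(scores), colnames(scores))
  out <- structure(
    D,
    items = item_no,
    patient_id = pid,
    n_visits = nrow(scores),
    n_pairs = as.integer(K * (K - 1L) / 2L),
    window = window,
    class = c("dtw_distmat", "matrix", "array")
  )
  if (K < 3) {
    warning("only ", K, " item(s) included for patient ", pid,
            ": clustering and network analysis need at least 3", call. = FALSE)
  }
  out
}

#' DTW distance matrices for every patient in a cohort
#'
#' @inheritParams patient_distance_matrix
#' @return A named list of `dtw_distmat` objects, one per patient.
#' @export
cohort_distance_matrices <- function(cohort, window = 2,
                                     exclude_all_zero = FALSE, normalize = FALSE) {
  mats <- split_patients(cohort)
  purrr::imap(mats, function(m, id) {
    suppressWarnings(patient_distance_matrix(
      m, patient = id, window = window,
      exclude_all_zero = exclude_all_zero, normalize = normalize
    ))
  })
}

#' @describeIn patient_distance_matrix Long tibble of the unordered item
#'   pairs and their distances.
#' @param x A `dtw_distmat`.
#' @param ... Unused.
#' @method tidy dtw_distmat
#' @export
tidy.dtw_distmat <- function(x, ...) {
  items <- attr(x, "items")
  K <- length(items)
  if (K < 2) return(tibble::tibble(item_a = integer(), item_b = integer(), distance = double()))
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    item_a = items[idx[, 1]],
    item_b = items[idx[, 2]],
    distance = x[idx]
  )
}

#' @export
print.dtw_distmat <- function(x, ...) {
  cat("DTW distance matrix (", length(attr(x, "items")), " items, ",
      attr(x, "n_pairs"), " pairs", sep = "")
  if (!is.na(attr(x, "patient_id"))) cat(", patient ", attr(x, "patient_id"), sep = "")
  cat(")\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Assessment-weighted mean distance matrix of a cohort
#'
#' Aggregates per-patient DTW distance matrices into the nomothetic cohort
#' matrix: each pair's mean distance across patients, weighted by each
#' patient's number of assessments, over the patients whose matrix
#' contains that pair.  The number of patients supporting each pair is
#' recorded; with `exclude_all_zero = FALSE` every patient supports every
#' pair.
#'
#' @param cohort A cohort tibble, or a list of `dtw_distmat` objects (in
#'   which case `weights` must be supplied).
#' @param weights Per-patient weights; defaults to the number of
#'   assessments T_p when `cohort` is a tibble.
#' @inheritParams patient_distance_matrix
#' @return A `cohort_distmat`: the weighted mean distance matrix with
#'   attributes `support` (patients per pair), `weights`, and `items`.
#'   A pair supported by no patient is `NA` and flagged by a warning.
#' @examples
#' cohort <- simulate_cohort(n_patients = 10, seed = 1)
#' Dbar <- cohort_distance(cohort)
#' @export
cohort_distance <- function(cohort, window = 2, exclude_all_zero = FALSE,
                            normalize = FALSE, weights = NULL) {
  if (is.list(cohort) && !is.data.frame(cohort)) {
    mats <- cohort
    if (is.null(weights)) stop("`weights` required when passing a list of matrices", call. = FALSE)
  } else {
    mats <- cohort_distance_matrices(cohort, window = window,
                                     exclude_all_zero = exclude_all_zero,
                                     normalize = normalize)
    if (is.null(weights)) {
      weights <- vapply(split_patients(cohort), nrow, integer(1))
    }
  }
  if (length(mats) == 0) stop("empty cohort", call. = FALSE)
  if (length(weights) != length(mats)) stop("one weight per patient required", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)

  all_items <- sort(unique(unlist(lapply(mats, attr, "items"))))
  K <- length(all_items)
  num <- matrix(0, K, K)
  den <- matrix(0, K, K)
  sup <- matrix(0L, K, K)
  for (p in seq_along(mats)) {
    it <- attr(mats[[p]], "items")
    pos <- match(it, all_items)
    num[pos, pos] <- num[pos, pos] + weights[p] * unclass(mats[[p]])
    den[pos, pos] <- den[pos, pos] + weights[p]
    sup[pos, pos] <- sup[pos, pos] + 1L
  }
  D <- num / den
  D[den == 0] <- NA_real_
  diag(D) <- 0
  diag(sup) <- length(mats)
  nm <- paste0("item_", all_items)
  dimnames(D) <- dimnames(sup) <- list(nm, nm)
  if (anyNA(D)) {
    warning("some item pairs are supported by no patient; entries set to NA", call. = FALSE)
  }
  structure(
    D,
    items = all_items,
    patient_id = NA_character_,
    n_visits = NA_integer_,
    n_pairs = as.integer(K * (K - 1L) / 2L),
    window = window,
    support = sup,
    weights = weights,
    class = c("cohort_distmat", "dtw_distmat", "matrix", "array")
  )
}

#' @export
print.cohort_distmat <- function(x, ...) {
  cat("Cohort weighted mean DTW distance matrix (", length(attr(x, "items")),
      " items, ", length(attr(x, "weights")), " patients)\n", sep = "")
  print(round(unclass(x), 2))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
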