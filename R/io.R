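#' Read a longitudinal HRSD-17 cohort from CSV
#'
#' Reads a long-format cohort table with one row per visit and columns
#' `patient_id`, `week`, and `item_1` ... `item_17`, validates it, sorts
#' visits by week within patient, and drops patients with fewer than two
#' assessments (a single assessment carries no trajectory information);
#' the number dropped is reported with a message.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict If `TRUE` (default), an out-of-range item score is an
#'   error naming the offending row; if `FALSE`, scores are clipped into
#'   the item's catalog range with a warning.
#' @return A validated cohort tibble with columns `patient_id` (character),
#'   `week` (integer), and `item_1` ... `item_17` (integer).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(n_patients = 4, seed = 1), path)
#' read_cohort(path)
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(raw, strict = strict, drop_single = TRUE)
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort tibble as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(
    dplyr::select(cohort, "patient_id", "week", dplyr::all_of(item_cols())),
    path
  )
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a long-format cohort table: the
#' required columns exist, weeks are non-negative and unique within
#' patient, and every item score is an integer within its catalog range
#' (0-4 for nine items, 0-2 for eight).  Rows are sorted by patient and
#' week.
#'
#' @inheritParams write_cohort
#' @param strict Out-of-range handling as in [read_cohort()].
#' @param drop_single Drop patients with fewer than two visits (with a
#'   message); if `FALSE`, such patients are an error.
#' @return The validated, sorted cohort tibble.
#' @export
validate_cohort <- function(cohort, strict = TRUE, drop_single = TRUE) {
  needed <- c("patient_id", "week", item_cols())
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort <- tibble::as_tibble(cohort)
  cohort$patient_id <- as.character(cohort$patient_id)
  if (anyNA(cohort$week) || any(cohort$week < 0)) {
    stop("`week` must be non-negative and non-missing", call. = FALSE)
  }
  cohort$week <- as.integer(cohort$week)

  dup <- duplicated(cohort[c("patient_id", "week")])
  if (any(dup)) {
    stop("duplicated (patient_id, week) rows: ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }

  maxes <- item_max()
  for (k in 1:17) {
    col <- item_cols()[k]
    v <- cohort[[col]]
    if (anyNA(v)) stop("missing scores in ", col, call. = FALSE)
    bad <- which(v < 0 | v > maxes[k] | v != round(v))
    if (length(bad) > 0) {
      if (strict) {
        stop("score out of range in column ", col, ", row(s) ",
             paste(utils::head(bad, 5), collapse = ", "),
             " (allowed 0-", maxes[k], ")", call. = FALSE)
      }
      warning("clipping ", length(bad), " out-of-range score(s) in ", col, call. = FALSE)
      v <- pmin(pmax(round(v), 0), maxes[k])
    }
    cohort[[col]] <- as.integer(v)
  }

  cohort <- dplyr::arrange(cohort, .data$patient_id, .data$week)
  n_visits <- table(cohort$patient_id)
  singles <- names(n_visits)[n_visits < 2]
  if (length(singles) > 0) {
    if (!drop_single) {
      stop(length(singles), " patient(s) have a single assessment", call. = FALSE)
    }
    message("dropped ", length(singles),
            " patient(s) with a single assessment (no trajectory)")
    cohort <- dplyr::filter(cohort, !(.data$patient_id %in% singles))
  }
  cohort
}

# T x 17 integer score matrix for one patient, rows ordered by week.
patient_matrix <- function(cohort, patient) {
  rows <- cohort[cohort$patient_id == patient, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown patient_id: ", patient, call. = FALSE)
  rows <- rows[order(rows$week), , drop = FALSE]
  m <- as.matrix(rows[, item_cols()])
  rownames(m) <- rows$week
  colnames(m) <- item_cols()
  m
}

# Named list of score matrices, one per patient, in first-appearance order.
split_patients <- function(cohort) {
  ids <- unique(cohort$patient_id)
  setNames(lapply(ids, function(id) patient_matrix(cohort, id)), ids)
}

#' Per-visit HRSD-17 sum scores
#'
#' @inheritParams write_cohort
#' @return A tibble with `patient_id`, `week`, and `sum_score` (0-52).
#' @export
sum_scores <- function(cohort) {
  tibble::tibble(
    patient_id = cohort$patient_id,
    week = cohort$week,
    sum_score = rowSums(as.matrix(cohort[, item_cols()]))
  )
}
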