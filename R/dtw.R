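#' Dynamic time warping alignment of two item-score series
#'
#' Aligns two equal-length time series with dynamic time warping under the
#' symmetric step pattern with slope constraint P = 0 (diagonal steps weigh
#' the local cost twice, horizontal and vertical steps once) and a
#' Sakoe-Chiba band that restricts matched indices to `|i - j| <= window`.
#' The local cost is the absolute score difference.  Both endpoints are
#' anchored, so the warping path starts at (1, 1) and ends at (T, T).
#'
#' With biweekly visits the default `window = 2` lets scores be matched at
#' most two visits (four weeks) apart.  The accumulated cost is the DTW
#' distance; dividing it by the summed series lengths gives the
#' length-normalized distance, which is also returned.
#'
#' @param x,y Numeric vectors of equal length `T >= 2`, typically integer
#'   HRSD-17 item scores at consecutive biweekly visits.
#' @param window Non-negative band half-width in visits; `Inf` disables the
#'   band.  At `window = 0` the path is forced onto the diagonal and the
#'   distance equals `sum(2 * abs(x - y))`.
#' @return An object of class `dtw_alignment`: a list with `distance`,
#'   `normalized_distance` (`distance / (length(x) + length(y))`), and
#'   `path`, a two-column integer matrix of 1-based aligned index pairs.
#'   Ties in the backtracking are broken deterministically, preferring
#'   diagonal, then vertical, then horizontal steps.
#' @examples
#' a <- dtw_align(c(4, 3, 1, 0), c(4, 4, 3, 1))
#' a$distance
#' tidy(a)
#' @seealso [dtw_distance()] for the distance only,
#'   [brute_force_align()] for the exhaustive-enumeration reference.
#' @export
dtw_align <- function(x, y, window = 2) {
  check_series(x, y, window)
  res <- .cpp_dtw_align(as.numeric(x), as.numeric(y), as.numeric(window))
  new_alignment(res$distance, res$path, length(x), length(y), window)
}

#' Dynamic time warping distance between two series
#'
#' The accumulated cost of [dtw_align()] without path recovery; used in the
#' inner loop of per-patient distance matrices.
#'
#' @inheritParams dtw_align
#' @param normalize If `TRUE`, return the length-normalized distance
#'   `d / (length(x) + length(y))` instead of the accumulated cost.
#' @return A non-negative scalar; 0 exactly when `x` and `y` are identical.
#' @examples
#' dtw_distance(c(0, 0, 0), c(1, 1, 1))                   # 6
#' dtw_distance(c(0, 0, 0), c(1, 1, 1), normalize = TRUE) # 1
#' @export
dtw_distance <- function(x, y, window = 2, normalize = FALSE) {
  check_series(x, y, window)
  d <- .cpp_dtw_cost(as.numeric(x), as.numeric(y), as.numeric(window))
  if (normalize) d / (length(x) + length(y)) else d
}

#' Exhaustive-enumeration DTW reference implementation
#'
#' Enumerates every anchored monotone warping path inside the Sakoe-Chiba
#' band, costs each with the symmetric P = 0 step weights, and returns the
#' minimum.  This is an independent reference for [dtw_align()]: the two
#' must agree on every input.  Enumeration is exponential, so series are
#' limited to `length(x) * length(y) <= 64`.
#'
#' @inheritParams dtw_align
#' @return A `dtw_alignment`, as from [dtw_align()].
#' @export
brute_force_align <- function(x, y, window = 2) {
  check_series(x, y, window)
  if (length(x) * length(y) > 64) {
    stop("series too long for exhaustive enumeration (length(x) * length(y) must be <= 64)",
         call. = FALSE)
  }
  n <- length(x); m <- length(y)
  cost <- function(i, j) abs(x[i] - y[j])
  best <- list(d = Inf, path = NULL)
  # depth-first enumeration over steps {(1,1),(1,0),(0,1)}
  recurse <- function(i, j, acc, path) {
    if (acc >= best$d) return(invisible())
    if (i == n && j == m) {
      best <<- list(d = acc, path = path)
      return(invisible())
    }
    if (i < n && j < m && abs(i + 1 - (j + 1)) <= window) {
      recurse(i + 1, j + 1, acc + 2 * cost(i + 1, j + 1), rbind(path, c(i + 1, j + 1)))
    }
    if (i < n && abs(i + 1 - j) <= window) {
      recurse(i + 1, j, acc + cost(i + 1, j), rbind(path, c(i + 1, j)))
    }
    if (j < m && abs(i - (j + 1)) <= window) {
      recurse(i, j + 1, acc + cost(i, j + 1), rbind(path, c(i, j + 1)))
    }
  }
  recurse(1, 1, 2 * cost(1, 1), matrix(c(1, 1), 1, 2))
  if (!is.finite(best$d)) stop("no feasible warping path inside the band", call. = FALSE)
  new_alignment(best$d, best$path, n, m, window)
}

check_series <- function(x, y, window) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("series must be numeric vectors", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("series must have equal length (items within one patient share visits); got ",
         length(x), " and ", length(y), call. = FALSE)
  }
  if (length(x) < 2) {
    stop("series must have at least 2 assessments", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("series must not contain missing values", call. = FALSE)
  if (length(window) != 1 || is.na(window) || window < 0) {
    stop("`window` must be a single non-negative number (or Inf)", call. = FALSE)
  }
  invisible(TRUE)
}

new_alignment <- function(distance, path, n, m, window) {
  colnames(path) <- c("i", "j")
  structure(
    list(
      distance = distance,
      normalized_distance = distance / (n + m),
      path = path,
      n = n, m = m, window = window
    ),
    class = "dtw_alignment"
  )
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("DTW alignment (symmetric P0, band width ", format(x$window), ")\n", sep = "")
  cat("  series lengths: ", x$n, " x ", x$m, "\n", sep = "")
  cat("  distance: ", format(x$distance),
      "  (normalized: ", format(x$normalized_distance), ")\n", sep = "")
  cat("  path length: ", nrow(x$path), "\n", sep = "")
  invisible(x)
}

#' @describeIn dtw_align Tidy the warping path into a tibble with columns
#'   `step`, `i`, `j`.
#' @param x A `dtw_alignment`.
#' @param ... Unused.
#' @method tidy dtw_alignment
#' @export
tidy.dtw_alignment <- function(x, ...) {
  tibble::tibble(
    step = seq_len(nrow(x$path)),
    i = x$path[, "i"],
    j = x$path[, "j"]
  )
}

#' @describeIn dtw_align One-row summary with `distance`,
#'   `normalized_distance`, `path_length`, and `window`.
#' @method glance dtw_alignment
#' @export
glance.dtw_alignment <- function(x, ...) {
  tibble::tibble(
    distance = x$distance,
    normalized_distance = x$normalized_distance,
    path_length = nrow(x$path),
    window = x$window
  )
}
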