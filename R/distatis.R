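#' Distatis compromise analysis of a set of distance matrices
#'
#' Distatis generalizes classical multidimensional scaling to a collection
#' of distance matrices over the same objects (here: one DTW distance
#' matrix per patient over the 17 HRSD items).  Each matrix is converted
#' to a double-centered cross-product matrix `S_p = -1/2 J D_p J` with
#' `J = I - 11'/n`, normalized by its first eigenvalue, and the matrices
#' are compared through their RV coefficients
#' `RV_pq = trace(S_p S_q) / sqrt(trace(S_p^2) trace(S_q^2))`.  The first
#' eigenvector of the RV matrix, rescaled to sum 1, weights the matrices
#' into the compromise `S+ = sum alpha_p S_p`, whose eigendecomposition
#' yields the compromise factor scores `F = V diag(sqrt(lambda))` on which
#' the items are plotted.  Only non-negative eigenvalues are projected;
#' trailing negative ones (DTW dissimilarities need not be Euclidean) are
#' reported but never enter `F`.
#'
#' @param matrices A list of conformable symmetric distance matrices (all
#'   over the same item set), e.g. from
#'   [cohort_distance_matrices()] with `exclude_all_zero = FALSE`.
#' @param square_distances Double-center the squared distances instead of
#'   the distances as given (the textbook MDS treatment).  Default
#'   `FALSE`: supplied dissimilarities are centered as-is.
#' @return A `distatis_fit` with elements `alpha` (compromise weights,
#'   non-negative, summing to 1), `rv` (the K x K RV matrix),
#'   `eigenvalues` (all eigenvalues of the compromise, non-increasing),
#'   `factor_scores` (items x retained components), `compromise`, and
#'   `items`.  Matrices with zero total variance (all distances equal)
#'   are excluded with a warning.
#' @examples
#' D <- matrix(c(0, 2, 2, 0), 2, 2)
#' f <- distatis(list(D, D, D))
#' f$alpha  # uniform 1/3
#' @seealso [congruence_coefficient()] to compare two factor solutions.
#' @export
distatis <- function(matrices, square_distances = FALSE) {
  if (!is.list(matrices) || length(matrices) < 1) {
    stop("`matrices` must be a non-empty list of distance matrices", call. = FALSE)
  }
  items <- attr(matrices[[1]], "items") %||% seq_len(nrow(matrices[[1]]))
  n <- nrow(matrices[[1]])
  cross <- vector("list", length(matrices))
  keep <- logical(length(matrices))
  for (p in seq_along(matrices)) {
    d <- as_distmat(matrices[[p]])
    if (nrow(d) != n) stop("all matrices must share the same item set", call. = FALSE)
    if (square_distances) d <- d^2
    S <- double_center(d)
    l1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
    if (l1 < 1e-12) {
      keep[p] <- FALSE
      next
    }
    cross[[p]] <- S / l1
    keep[p] <- TRUE
  }
  if (!all(keep)) {
    warning(sum(!keep), " matrix/matrices with zero variance excluded from Distatis",
            call. = FALSE)
  }
  cross <- cross[keep]
  K <- length(cross)
  if (K < 1) stop("no matrix with non-zero variance", call. = FALSE)

  rv <- diag(1, K)
  tr <- vapply(cross, function(S) sum(S * S), double(1))
  if (K > 1) {
    for (p in 1:(K - 1)) {
      for (q in (p + 1):K) {
        rv[p, q] <- rv[q, p] <- sum(cross[[p]] * cross[[q]]) / sqrt(tr[p] * tr[q])
      }
    }
  }
  if (K == 1) {
    alpha <- 1
  } else {
    v1 <- eigen(rv, symmetric = TRUE)$vectors[, 1]
    if (sum(v1 >= 0) < sum(v1 < 0)) v1 <- -v1   # fix the sign indeterminacy
    alpha <- v1 / sum(v1)
  }

  compromise <- Reduce(`+`, purrr::map2(cross, alpha, `*`))
  eig <- eigen(compromise, symmetric = TRUE)
  pos <- which(eig$values > 1e-12)
  F_scores <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), length(pos))
  rownames(F_scores) <- rownames(matrices[[1]]) %||% paste0("item_", items)
  colnames(F_scores) <- paste0("F", seq_along(pos))

  structure(
    list(alpha = alpha, rv = rv, eigenvalues = eig$values,
         factor_scores = F_scores, compromise = compromise,
         items = items, n_matrices = K, square_distances = square_distances),
    class = "distatis_fit"
  )
}

double_center <- function(d) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  S <- -0.5 * J %*% d %*% J
  (S + t(S)) / 2
}

#' @export
print.distatis_fit <- function(x, ...) {
  cat("Distatis compromise of", x$n_matrices, "distance matrices\n")
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 4), digits = 3), collapse = ", "), "\n")
  cat("  negative eigenvalues:", sum(x$eigenvalues < -1e-12),
      "(reported, not projected)\n")
  invisible(x)
}

#' @describeIn distatis Item factor scores as a tibble (`item`, `name`,
#'   `F1`, `F2`, ...).
#' @param x A `distatis_fit`.
#' @param ... Unused.
#' @method tidy distatis_fit
#' @export
tidy.distatis_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(item = x$items, name = rownames(x$factor_scores)),
    tibble::as_tibble(x$factor_scores)
  )
}

#' @describeIn distatis One-row summary: number of matrices, first two
#'   eigenvalues and their explained share, count of negative eigenvalues.
#' @method glance distatis_fit
#' @export
glance.distatis_fit <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble::tibble(
    n_matrices = x$n_matrices,
    lambda_1 = x$eigenvalues[1],
    lambda_2 = x$eigenvalues[2],
    prop_first_two = sum(x$eigenvalues[1:2]) / sum(pos),
    n_negative = sum(x$eigenvalues < -1e-12)
  )
}

#' Tucker congruence coefficient between two factor configurations
#'
#' `phi = sum(F1 * F2) / sqrt(sum(F1^2) * sum(F2^2))` over all entries: the
#' cosine between two factor solutions, in `[-1, 1]`, with 1 meaning
#' proportional configurations.  Used to check the stability of the
#' Distatis compromise across cohort split-halves.
#'
#' @param f1,f2 Numeric matrices (or vectors) of identical shape.
#' @return A scalar in `[-1, 1]`.
#' @examples
#' f <- matrix(rnorm(10), 5, 2)
#' congruence_coefficient(f, 2 * f)  # 1
#' @export
congruence_coefficient <- function(f1, f2) {
  f1 <- as.matrix(f1); f2 <- as.matrix(f2)
  if (!all(dim(f1) == dim(f2))) stop("factor blocks must have identical shape", call. = FALSE)
  n1 <- sum(f1^2); n2 <- sum(f2^2)
  if (n1 < 1e-300 || n2 < 1e-300) stop("zero-norm factor block", call. = FALSE)
  sum(f1 * f2) / sqrt(n1 * n2)
}
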