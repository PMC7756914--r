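#' Ward.D2 hierarchical clustering of symptom trajectories
#'
#' Agglomerative clustering of a DTW distance matrix with the Ward.D2
#' criterion: dissimilarities are squared before the Lance-Williams
#' update, and merge heights are reported on the original distance scale
#' (the square root of the merge criterion), so heights are non-decreasing
#' along the merge sequence.  Each item starts as its own cluster and the
#' two most similar clusters are joined at every step until one remains.
#'
#' @param D A symmetric distance matrix with zero diagonal (a
#'   [patient_distance_matrix()] / [cohort_distance()] result, a plain
#'   matrix, or a [stats::dist] object) over at least 3 items.
#' @return A `ward_tree`: the [stats::hclust] object with the item numbers
#'   carried along (attribute `items`).
#' @examples
#' D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- ward_cluster(D)
#' tr$height  # 1 and sqrt(33)
#' @seealso [cut_tree()], [scree_and_elbow()]
#' @export
ward_cluster <- function(D) {
  d <- as_distmat(D)
  if (nrow(d) < 3) stop("clustering needs at least 3 items", call. = FALSE)
  h <- hclust(as.dist(d), method = "ward.D2")
  structure(
    c(h, list(items = attr(D, "items") %||% seq_len(nrow(d)))),
    class = c("ward_tree", "hclust")
  )
}

as_distmat <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D)) stop("`D` must be a matrix or dist object", call. = FALSE)
  d <- unclass(D)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("`D` must be a symmetric square matrix", call. = FALSE)
  }
  if (any(d < 0)) stop("`D` must be non-negative", call. = FALSE)
  if (anyNA(d)) stop("`D` has missing entries (pairs with no support?)", call. = FALSE)
  d
}

#' Cut a cluster tree into k groups
#'
#' @param tree A `ward_tree` from [ward_cluster()].
#' @param k Number of groups, between 1 and the number of items.  Patient
#'   reports use k = 3 by convention (for readability, not inference); the
#'   cohort analysis chooses k with [scree_and_elbow()] or a manual
#'   override.
#' @return A tibble with columns `item` (item number), `name` (dendrogram
#'   label), and `cluster` (group id 1..k, numbered by first appearance in
#'   dendrogram leaf order).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (length(k) != 1 || is.na(k) || k < 1 || k > n) {
    stop("`k` must be between 1 and ", n, call. = FALSE)
  }
  raw <- cutree(tree, k = k)
  # renumber by dendrogram leaf order for stable, readable group ids
  leaf <- tree$order
  first <- raw[leaf][!duplicated(raw[leaf])]
  cl <- match(raw, first)
  tibble::tibble(
    item = tree$items %||% seq_len(n),
    name = tree$labels,
    cluster = cl
  )
}

#' Scree heights and automatic elbow selection of the cluster count
#'
#' Reads the merge heights of a Ward tree as a scree: `H_k` is the height
#' of the merge that reduces k + 1 clusters to k, a decreasing function of
#' k.  The elbow — where the downward curve levels off — is automated as
#' the k maximizing the discrete curvature
#' `c(k) = (H_(k-1) - H_k) - (H_k - H_(k+1))` over `2 <= k <= k_max - 1`.
#' A manual choice of k overrides the rule downstream.
#'
#' @param tree A `ward_tree`.
#' @param k_max Largest cluster count whose height enters the scree
#'   (default 8).
#' @return A `scree_elbow` list: `heights`, a tibble of `k` and `height`
#'   for k = 1..k_max; `k_star`, the selected count (`NA` when fewer than
#'   4 merges exist); `curvature`, the c(k) values.  A flat (all-equal
#'   curvature) scree selects the smallest candidate with a warning.
#' @examples
#' D <- cohort_distance(simulate_cohort(n_patients = 30, seed = 7))
#' scree_and_elbow(ward_cluster(D))$k_star
#' @export
scree_and_elbow <- function(tree, k_max = 8) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k_max > n - 1) k_max <- n - 1
  H_all <- rev(tree$height)           # H_all[k] = height of the merge making k clusters
  ks <- seq_len(min(k_max, length(H_all)))
  heights <- tibble::tibble(k = ks, height = H_all[ks])

  if (length(H_all) < 4 || k_max < 3) {
    return(structure(list(heights = heights, k_star = NA_integer_,
                          curvature = tibble::tibble(k = integer(), curvature = double())),
                     class = "scree_elbow"))
  }
  cand <- 2:(k_max - 1)
  curv <- (H_all[cand - 1] - H_all[cand]) - (H_all[cand] - H_all[cand + 1])
  if (diff(range(curv)) < 1e-12) {
    warning("scree is linear; elbow is ill-defined, taking the smallest candidate k",
            call. = FALSE)
  }
  k_star <- cand[which.max(curv)]
  structure(
    list(heights = heights, k_star = as.integer(k_star),
         curvature = tibble::tibble(k = cand, curvature = curv)),
    class = "scree_elbow"
  )
}

#' @export
print.scree_elbow <- function(x, ...) {
  cat("Scree of Ward merge heights (k = 1..", max(x$heights$k), ")\n", sep = "")
  cat("  elbow k* =", x$k_star, "\n")
  invisible(x)
}
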