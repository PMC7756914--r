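#' Symptom network from a DTW distance matrix
#'
#' Turns a distance matrix into a fully connected symptom network in which
#' a thicker edge means a shorter distance — a stronger longitudinal
#' covariation between the two symptom trajectories.  Edge weights map
#' distances to similarities; two transforms are available:
#' \describe{
#'   \item{`minmax`}{`s_ij = (d_max - d_ij) / (d_max - d_min)` over the
#'     off-diagonal entries, so the closest pair gets weight 1 and the
#'     farthest 0.  Invariant under affine transforms of the distances.}
#'   \item{`inverse`}{`s_ij = 1 / d_ij`, with exact-zero distances capped
#'     at the largest finite similarity observed.}
#' }
#' Two centrality statistics are computed per node: strength (degree
#' centrality), the sum of its edge weights; and closeness, the inverse of
#' its mean DTW distance to all other symptoms (the matrix is complete, so
#' no path search is involved).
#'
#' @param D A distance matrix as accepted by [ward_cluster()], over at
#'   least 3 items.
#' @param similarity Distance-to-weight transform, `"minmax"` (default) or
#'   `"inverse"`.
#' @return A `symptom_network` with `edges` (tibble: `item_a`, `item_b`,
#'   `distance`, `weight`) and `centrality` (tibble: `item`, `name`,
#'   `strength`, `closeness`).  If all off-diagonal distances are equal
#'   the min-max transform is undefined; uniform weights 1 are emitted
#'   with a warning.
#' @examples
#' D <- matrix(2, 4, 4); diag(D) <- 0
#' build_network(D)$centrality$closeness  # all 0.5
#' @export
build_network <- function(D, similarity = c("minmax", "inverse")) {
  similarity <- match.arg(similarity)
  d <- as_distmat(D)
  K <- nrow(d)
  if (K < 3) stop("network needs at least 3 items", call. = FALSE)
  items <- attr(D, "items") %||% seq_len(K)
  nms <- rownames(d) %||% paste0("item_", items)

  off <- d[upper.tri(d)]
  if (similarity == "minmax") {
    rng <- range(off)
    if (diff(rng) < 1e-12) {
      warning("all pairwise distances are equal; emitting uniform edge weights 1",
              call. = FALSE)
      s <- matrix(1, K, K)
    } else {
      s <- (rng[2] - d) / (rng[2] - rng[1])
    }
  } else {
    s <- 1 / d
    if (any(is.infinite(s[upper.tri(s)]))) {
      finite <- s[upper.tri(s)][is.finite(s[upper.tri(s)])]
      cap <- if (length(finite) > 0) max(finite) else 1
      s[is.infinite(s)] <- cap
    }
  }
  diag(s) <- 0

  idx <- which(upper.tri(d), arr.ind = TRUE)
  edges <- tibble::tibble(
    item_a = items[idx[, 1]],
    item_b = items[idx[, 2]],
    distance = d[idx],
    weight = s[idx]
  )
  centrality <- tibble::tibble(
    item = items,
    name = nms,
    strength = rowSums(s),
    closeness = 1 / (rowSums(d) / (K - 1))
  )
  structure(
    list(edges = edges, centrality = centrality, similarity = similarity,
         distance_matrix = d),
    class = "symptom_network"
  )
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("Symptom network (", nrow(x$centrality), " nodes, ",
      nrow(x$edges), " edges, ", x$similarity, " similarity)\n", sep = "")
  print(x$centrality)
  invisible(x)
}

#' @describeIn build_network Edge list as a tibble.
#' @param x A `symptom_network`.
#' @param ... Unused.
#' @method tidy symptom_network
#' @export
tidy.symptom_network <- function(x, ...) x$edges

#' @describeIn build_network One row per node with the centrality
#'   statistics.
#' @method glance symptom_network
#' @export
glance.symptom_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$centrality),
    n_edges = nrow(x$edges),
    mean_distance = mean(x$edges$distance),
    similarity = x$similarity
  )
}
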