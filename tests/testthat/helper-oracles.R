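# Independent reference implementations used to cross-check the package.

# Agglomerative Ward.D2 written from first principles: keep the full
# matrix of squared dissimilarities, at every step merge the pair with
# the smallest criterion (ties: lowest index pair) and recompute the
# merged cluster's criterion against every other cluster with the
# Lance-Williams update
#   d2(t,k) = [(ni+nk) d2(i,k) + (nj+nk) d2(j,k) - nk d2(i,j)] / (ni+nj+nk).
# Heights are reported on the original scale (square root).
naive_ward <- function(D) {
  n <- nrow(D)
  d2 <- unclass(D)^2
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(0)
  partitions <- list()
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_val <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        i <- active[b]; j <- active[a]
        if (d2[i, j] < best_val - 1e-12) {
          best_val <- d2[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_val))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      upd <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- upd
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
    lab <- integer(n)
    for (a in seq_along(active)) lab[members[[active[a]]]] <- a
    partitions[[length(partitions) + 1]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Random symmetric distance matrix with zero diagonal.
random_distmat <- function(n, max_d = 10) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.5, max_d)
  d <- d + t(d)
  dimnames(d) <- list(paste0("item_", 1:n), paste0("item_", 1:n))
  d
}

# Partition agreement up to relabeling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Small helper: one patient's cohort tibble from a T x 17 score matrix.
cohort_from_matrix <- function(scores, id = "P001") {
  df <- tibble::as_tibble(as.data.frame(scores))
  names(df) <- paste0("item_", 1:17)
  dplyr::bind_cols(
    tibble::tibble(patient_id = id, week = 2L * (seq_len(nrow(scores)) - 1L)),
    df
  )
}
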