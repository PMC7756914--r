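test_that("hand-computed three-item Ward tree is reproduced", {
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- ward_cluster(D)
  # Lance-Williams on squared distances: second merge at sqrt((2*25+2*25-1)/3)
  expect_equal(tr$height, c(1, sqrt(33)))
  cut2 <- cut_tree(tr, 2)
  expect_equal(cut2$cluster[cut2$name == "A"], cut2$cluster[cut2$name == "B"])
  expect_false(cut2$cluster[cut2$name == "C"] == cut2$cluster[cut2$name == "A"])
})

test_that("ward_cluster matches a from-scratch Lance-Williams agglomeration", {
  set.seed(421)
  for (r in 1:30) {
    D <- random_distmat(6)
    tr <- ward_cluster(D)
    ref <- naive_ward(D)
    expect_equal(tr$height, ref$heights, tolerance = 1e-10)
    expect_true(all(diff(tr$height) >= -1e-10))      # monotone merges
    for (k in c(2, 3, 4)) {
      expect_true(same_partition(cut_tree(tr, k)$cluster,
                                 ref$partitions[[6 - k]]))
    }
  }
})

test_that("cut_tree covers the degenerate cuts and validates k", {
  D <- random_distmat(5)
  tr <- ward_cluster(D)
  expect_equal(unique(cut_tree(tr, 1)$cluster), 1L)
  expect_equal(sort(cut_tree(tr, 5)$cluster), 1:5)
  expect_error(cut_tree(tr, 0), "between")
  expect_error(cut_tree(tr, 6), "between")
})

test_that("cluster partitions are invariant under rescaling the distances", {
  set.seed(422)
  D <- random_distmat(8)
  t1 <- ward_cluster(D)
  t2 <- ward_cluster(3.7 * D)
  for (k in 2:6) {
    expect_true(same_partition(cut_tree(t1, k)$cluster, cut_tree(t2, k)$cluster))
  }
  expect_equal(t2$height, 3.7 * t1$height)
})

test_that("scree elbow picks the maximal-curvature k on a frozen scree", {
  # direct evaluation: c(3) = (7-3) - (3-2.8) = 3.8 dominates
  H <- c(10, 7, 3, 2.8, 2.6, 2.5)
  tr <- structure(list(height = rev(H), labels = paste0("it", 1:7),
                       merge = NULL, order = 1:7),
                  class = c("ward_tree", "hclust"))
  se <- scree_and_elbow(tr, k_max = 6)
  expect_equal(se$k_star, 3L)
  expect_equal(se$heights$height, H)
})

test_that("a linear scree is flagged and small trees return no elbow", {
  H <- seq(12, 2, by = -2)
  tr <- structure(list(height = rev(H), labels = paste0("it", 1:7),
                       merge = NULL, order = 1:7),
                  class = c("ward_tree", "hclust"))
  expect_warning(se <- scree_and_elbow(tr, k_max = 6), "linear")
  expect_equal(se$k_star, 2L)
  tiny <- structure(list(height = c(1, 2, 3), labels = paste0("it", 1:4),
                         merge = NULL, order = 1:4),
                    class = c("ward_tree", "hclust"))
  expect_true(is.na(scree_and_elbow(tiny, k_max = 3)$k_star))
})

test_that("validation rejects malformed distance matrices", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_cluster(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(ward_cluster(neg), "non-negative")
  expect_error(ward_cluster(random_distmat(2)), "at least 3")
})
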