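test_that("a full 17-item patient yields 136 pairwise distances", {
  set.seed(411)
  scores <- sapply(item_max(), function(m) sample(0:m, 6, replace = TRUE))
  scores[scores == 0] <- 1                       # no all-zero items
  D <- patient_distance_matrix(cohort_from_matrix(scores), patient = "P001",
                               exclude_all_zero = TRUE)
  expect_equal(attr(D, "n_pairs"), 136L)
  expect_equal(nrow(tidy(D)), 136L)
  expect_true(isSymmetric(unclass(D)))
  expect_equal(diag(unclass(D)), setNames(rep(0, 17), paste0("item_", 1:17)))
})

test_that("all-zero exclusion drops items without touching remaining distances", {
  set.seed(412)
  scores <- sapply(item_max(), function(m) sample(1:m, 5, replace = TRUE))
  scores[, 16] <- 0                              # item 16 silent throughout
  co <- cohort_from_matrix(scores)
  D_ex <- patient_distance_matrix(co, "P001", exclude_all_zero = TRUE)
  D_all <- patient_distance_matrix(co, "P001", exclude_all_zero = FALSE)
  expect_equal(length(attr(D_ex, "items")), 16L)
  expect_equal(attr(D_ex, "n_pairs"), 120L)
  keep <- paste0("item_", setdiff(1:17, 16))
  expect_equal(unclass(D_ex), unclass(D_all)[keep, keep], ignore_attr = TRUE)
})

test_that("identical trajectories are at distance zero", {
  scores <- sapply(item_max(), function(m) rep(1L, 4))
  scores[, 1] <- c(1, 2, 3, 4); scores[, 2] <- c(1, 2, 3, 4)
  D <- patient_distance_matrix(cohort_from_matrix(scores), "P001",
                               exclude_all_zero = FALSE)
  expect_equal(unclass(D)["item_1", "item_2"], 0)
})

test_that("degenerate patients warn instead of failing", {
  scores <- matrix(0L, 3, 17)
  scores[, 1] <- c(1, 2, 1); scores[, 2] <- c(0, 1, 0)
  expect_warning(
    patient_distance_matrix(cohort_from_matrix(scores), "P001"),
    "at least 3"
  )
  rep <- suppressWarnings(analyze_patient(cohort_from_matrix(scores), "P001"))
  expect_null(rep$clusters)
  expect_match(rep$note, "insufficient items")
})

test_that("weighted cohort mean matches the direct formula", {
  m1 <- random_distmat(4); m2 <- random_distmat(4)
  a1 <- structure(m1, items = 1:4); a2 <- structure(m2, items = 1:4)
  Dbar <- cohort_distance(list(a1, a2), weights = c(4, 2))
  expect_equal(unclass(Dbar)[2, 3], (4 * m1[2, 3] + 2 * m2[2, 3]) / 6)
  # equal weights give the plain mean; a single matrix is returned as-is
  Deq <- cohort_distance(list(a1, a2), weights = c(1, 1))
  expect_equal(unclass(Deq)[1, 4], mean(c(m1[1, 4], m2[1, 4])))
  D1 <- cohort_distance(list(a1), weights = 3)
  expect_equal(unclass(D1), m1, ignore_attr = TRUE)
})

test_that("pair support tracks the exclusion and leaves shared pairs intact", {
  set.seed(413)
  s1 <- sapply(item_max(), function(m) sample(1:m, 4, replace = TRUE))
  s2 <- s1; s2[, 5] <- 0                        # patient 2 silent on item 5
  co <- dplyr::bind_rows(cohort_from_matrix(s1, "A"), cohort_from_matrix(s2, "B"))
  Dbar <- cohort_distance(co, exclude_all_zero = TRUE)
  sup <- attr(Dbar, "support")
  expect_equal(sup["item_5", "item_1"], 1L)
  expect_equal(sup["item_1", "item_2"], 2L)
  # per-patient matrices agree on shared pairs whether or not items are excluded
  m_ex <- cohort_distance_matrices(co, exclude_all_zero = TRUE)
  m_all <- cohort_distance_matrices(co, exclude_all_zero = FALSE)
  keep <- rownames(m_ex$B)
  expect_equal(unclass(m_ex$B), unclass(m_all$B)[keep, keep],
               ignore_attr = TRUE)
})
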