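test_that("candidate enumeration matches complete brute-force generation", {
  # 4 electrodes, all pairs: exactly the three unordered four-point splits
  c4 <- enumerate_candidates(NULL, rules = list(pair_mode = "all"),
                             n_electrodes = 4)
  expect_identical(nrow(c4), 3L)
  keys <- apply(as.matrix(c4[, 1:4]), 1, function(r)
    paste(sort(c(paste(sort(r[1:2]), collapse = "-"),
                 paste(sort(r[3:4]), collapse = "-"))), collapse = "|"))
  expect_identical(unname(sort(keys)), c("1-2|3-4", "1-3|2-4", "1-4|2-3"))

  # 16 electrodes, all pairs: count equals C(120, 2) minus sharing pairs
  arr <- edge_array()
  call <- enumerate_candidates(arr, rules = list(pair_mode = "all"))
  pairs <- utils::combn(16, 2)
  n_share <- 0
  for (i in 1:(ncol(pairs) - 1)) for (j in (i + 1):ncol(pairs))
    if (length(intersect(pairs[, i], pairs[, j])) > 0) n_share <- n_share + 1
  expect_equal(nrow(call), choose(120, 2) - n_share)

  # determinism of the default ruleset
  c1 <- enumerate_candidates(arr)
  c2 <- enumerate_candidates(arr)
  expect_identical(c1, c2)
  expect_true(all(c1$inj_class %in% c("intra", "inter")))
})

test_that("row norms match their definitions", {
  J <- rbind(c(3, -4), c(0, 0))
  expect_identical(score_l1(J, 1), 7)
  expect_identical(score_l2(J, 1), 5)
  expect_identical(score_l1(J, 2), 0)
  expect_identical(score_l2(J, 2), 0)
  set.seed(2)
  r <- matrix(rnorm(10), 1)
  expect_equal(score_l1(r, 1), sum(abs(r)))
  expect_equal(score_l2(r, 1), sqrt(sum(r^2)))
})

test_that("norm inequalities hold for every Jacobian row", {
  fx <- tiny_fixture()
  J <- compute_jacobian(fx$solver, fx$field_hom, fx$pattern)
  l1 <- score_l1(J); l2 <- score_l2(J)
  expect_true(all(l2 <= l1 + 1e-12))
  expect_true(all(l1 <= sqrt(ncol(J)) * l2 + 1e-12))
})

test_that("Gram volume equals the explicit determinant", {
  expect_equal(gram_volume(rbind(c(2, 0, 0, 0), c(0, 3, 0, 0))), 36)
  expect_equal(gram_volume(rbind(c(1, 2, 3), c(1, 2, 3))), 0)
  set.seed(5)
  A <- matrix(rnorm(40), 4, 10)
  expect_equal(gram_volume(A), det(A %*% t(A)))
})

test_that("selection picks orthogonal rows over near-duplicates", {
  fx <- tiny_fixture()
  cand <- fx$candidates[1:6, ]
  J <- rbind(diag(3) * c(5, 4, 3),
             matrix(rep(c(4.9, 1e-3, 1e-3), 3), 3, byrow = TRUE))
  p <- select_pattern(J, cand, counts = c(volume = 3))
  # exhaustive check: the orthogonal trio dominates every other subset
  best <- which.max(utils::combn(6, 3, function(s) gram_volume(J[s, ])))
  expect_identical(sort(utils::combn(6, 3)[, best]), 1:3)
  expect_setequal(attr(p, "selection")$candidate, 1:3)
})

test_that("l1-only selection is a sort", {
  fx <- tiny_fixture()
  set.seed(3)
  J <- matrix(rnorm(12 * 8), 12, 8)
  p <- select_pattern(J, fx$candidates[1:12, ], counts = c(l1 = 5))
  expect_setequal(attr(p, "selection")$candidate,
                  order(-score_l1(J))[1:5])
})

test_that("greedy Gram-volume selection is near-optimal on small instances", {
  fx <- tiny_fixture()
  for (seed in 1:5) {
    set.seed(seed)
    J <- matrix(rnorm(12 * 10), 12, 10)
    p <- select_pattern(J, fx$candidates[1:12, ], counts = c(volume = 4))
    sel <- attr(p, "selection")$candidate
    greedy_vol <- gram_volume(J[sel, ])
    all_vols <- utils::combn(12, 4, function(s) gram_volume(J[s, ]))
    expect_gte(mean(all_vols <= greedy_vol), 0.9)
    gains <- attr(p, "volume_gains")
    expect_true(all(diff(gains) <= 1e-9 * gains[1]))
  }
})

test_that("selected patterns are clean and complete", {
  fx <- tiny_fixture()
  m <- as.matrix(fx$pattern$meas)
  expect_identical(nrow(m), 8L)
  # four-point and reciprocity cleanliness are enforced by construction;
  # re-validating the frame must succeed
  expect_s3_class(im_pattern(fx$pattern$meas), "im_pattern")
  # requesting more than available fails
  expect_error(select_pattern(matrix(1, 2, 5), fx$candidates[1:2, ],
                              counts = c(volume = 3)), "candidates")
})

test_that("reference-voltage screening drops degenerate candidates", {
  fx <- tiny_fixture()
  set.seed(8)
  J <- matrix(rnorm(10 * 6), 10, 6)
  v_ref <- c(1e-12, rep(0.1, 9))   # candidate 1 has a null reference
  p <- select_pattern(J, fx$candidates[1:10, ], counts = c(volume = 4),
                      v_ref = v_ref)
  expect_false(1L %in% attr(p, "selection")$candidate)
})
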