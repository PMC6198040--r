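# Order parameters c_max and P and the aster/nematic classification key.

test_that("largest V cluster matches a flood-fill oracle on random graphs", {
  set.seed(5)
  for (i in 1:100) {
    n_mt <- sample(5:60, 1)
    n_v <- sample(0:30, 1)
    rec <- tibble::tibble(fil_a = sample(n_mt, n_v, TRUE) - 1L,
                          fil_b = sample(n_mt, n_v, TRUE) - 1L,
                          type = sample(c("V", "Hp"), n_v, TRUE))
    rec <- rec[rec$fil_a != rec$fil_b, ]
    expect_identical(largest_v_cluster(rec), as.integer(brute_v_cluster(rec)))
  }
  # and through the census-series generator
  cen <- make_random_census(c(V = 12, Hp = 2), n_frames = 1, n_mt = 30, seed = 5)
  rec <- cen$records[[1]]
  expect_identical(largest_v_cluster(rec), as.integer(brute_v_cluster(rec)))
})

test_that("a V-link chain over five filaments forms one cluster of five", {
  pairs <- cbind(0:3, 1:4)
  cen <- make_random_census(c(V = 4), n_frames = 1, n_mt = 50, v_pairs = pairs)
  expect_equal(largest_v_cluster(cen$records[[1]]), 5L)
  none <- make_random_census(c(Hp = 10), n_frames = 1, n_mt = 50)
  expect_equal(largest_v_cluster(none$records[[1]]), 0L)
})

test_that("adding a V link never decreases the largest cluster", {
  set.seed(21)
  for (i in 1:30) {
    pairs <- cbind(sample(0:19, 12, TRUE), sample(0:19, 12, TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    sizes <- vapply(seq_len(nrow(pairs)), function(k) {
      cen <- make_random_census(c(V = k), n_frames = 1, n_mt = 20,
                                v_pairs = pairs[seq_len(k), , drop = FALSE])
      largest_v_cluster(cen$records[[1]])
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("P averages the trailing window and handles the undefined case", {
  cen <- make_random_census(c(Hp = 50, Hap = 50), n_frames = 25, n_mt = 100)
  expect_equal(compute_P(cen), 0.5)
  cen2 <- make_random_census(c(Hp = 40), n_frames = 25, n_mt = 100)
  expect_equal(compute_P(cen2), 1)
  cen3 <- make_random_census(c(Hp = 3, Hap = 1), n_frames = 25, n_mt = 100)
  expect_equal(compute_P(cen3), 0.75)
  cen4 <- make_random_census(c(V = 5), n_frames = 25, n_mt = 100)
  expect_true(is.na(compute_P(cen4)))                    # flagged, not 0.5
  expect_error(compute_P(cen[0, ]), "empty")
})

test_that("the aster threshold c_max >= 0.01 is applied on the final frame", {
  # 200 filaments, one V-linked pair: c_max = 2/200 = 0.01 -> aster
  cen <- make_random_census(c(V = 1, Hp = 10, Hap = 10), n_frames = 10,
                            n_mt = 200, v_pairs = cbind(0L, 1L))
  cls <- classify_network(cen, n_mt = 200)
  expect_equal(cls$c_max, 0.01)
  expect_equal(cls$label, "aster")
  # no V links at all: label from P
  cen2 <- make_random_census(c(Hp = 10, Hap = 10), n_frames = 10, n_mt = 200)
  cls2 <- classify_network(cen2, n_mt = 200)
  expect_equal(cls2$c_max, 0)
  expect_equal(cls2$label, "graded")
  expect_equal(cls2$P, 0.5)
  # nothing to classify on: sparse/unclassified
  cen3 <- make_random_census(c(`T` = 4), n_frames = 10, n_mt = 200)
  expect_equal(classify_network(cen3, n_mt = 200)$label, "unclassified")
})

test_that("classification is a pure function of the census", {
  cen <- make_random_census(c(V = 3, Hp = 20, Hap = 5), n_frames = 10,
                            n_mt = 150, seed = 4)
  a <- tidy(classify_network(cen, n_mt = 150))
  b <- tidy(classify_network(cen, n_mt = 150))
  expect_identical(a, b)
  expect_named(a, c("label", "c_max", "C_max", "P", "n_mt"))
})

test_that("ideal fixtures classify by construction", {
  ast <- make_ideal_aster(100, 120, seed = 3)
  cls <- classify_network(crosslink_census(ast), n_mt = 100)
  expect_equal(cls$label, "aster")
  expect_equal(cls$c_max, 1)                      # all plus ends in one cluster
  nem <- make_ideal_nematic(60, 0.5, n_motors = 400, seed = 3)
  cls2 <- classify_network(crosslink_census(nem), n_mt = 60)
  expect_false(cls2$label == "aster")
  expect_lt(abs(cls2$P - 0.5), 0.1)
})
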