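# Crosslink taxonomy and the per-frame census.

test_that("crosslink taxonomy follows end precedence and angle boundaries", {
  expect_equal(classify_crosslink(TRUE, TRUE, pi / 2), "V")     # any angle
  expect_equal(classify_crosslink(TRUE, TRUE, 0), "V")
  expect_equal(classify_crosslink(TRUE, FALSE, pi), "T")
  expect_equal(classify_crosslink(FALSE, TRUE, 0.1), "T")
  expect_equal(classify_crosslink(FALSE, FALSE, 0), "Hp")
  expect_equal(classify_crosslink(FALSE, FALSE, pi), "Hap")
  expect_equal(classify_crosslink(FALSE, FALSE, pi / 3), "X")       # closed
  expect_equal(classify_crosslink(FALSE, FALSE, 2 * pi / 3), "X")   # closed
  expect_equal(classify_crosslink(FALSE, FALSE, pi / 3 - 1e-9), "Hp")
  expect_equal(classify_crosslink(FALSE, FALSE, 2 * pi / 3 + 1e-9), "Hap")
  expect_error(classify_crosslink(FALSE, FALSE, pi / 2, fil_a = 3, fil_b = 3),
               "same filament")
})

test_that("census equals brute-force per-motor classification on random
           geometries", {
  for (seed in 1:5) {
    traj <- make_random_frame(n_filaments = 30, n_motors = 200, seed = seed)
    cen <- crosslink_census(traj)
    expected <- brute_census(traj)
    got <- unlist(cen[1, c("V", "T", "Hp", "Hap", "X")])
    expect_equal(unname(got), as.integer(expected))
    # partition: every doubly bound motor lands in exactly one class
    expect_equal(cen$n_links[1], 200L)
  }
})

test_that("census is invariant under rotation, translation and head swap", {
  traj <- make_random_frame(25, 120, seed = 9)
  cen0 <- unlist(crosslink_census(traj)[1, c("V", "T", "Hp", "Hap", "X")])
  # rigid rotation about z plus translation
  th <- 0.83
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 3,
                             y = sin(th) * x + cos(th) * y - 1)
  tr <- traj
  xy <- rot(tr$filaments$x, tr$filaments$y)
  tr$filaments$x <- xy$x; tr$filaments$y <- xy$y
  cen1 <- unlist(crosslink_census(tr)[1, c("V", "T", "Hp", "Hap", "X")])
  expect_equal(cen1, cen0)
  # swapping head labels a <-> b
  sw <- traj
  sw$motors <- dplyr::rename(sw$motors, fil_a = "fil_b", fil_b = "fil_a",
                             abs_a = "abs_b", abs_b = "abs_a",
                             end_a = "end_b", end_b = "end_a")
  cen2 <- unlist(crosslink_census(sw)[1, c("V", "T", "Hp", "Hap", "X")])
  expect_equal(cen2, cen0)
})

test_that("an ideal aster census is V-dominated and an empty frame counts
           zero", {
  ast <- make_ideal_aster(50, 80, seed = 2)
  cen <- crosslink_census(ast)
  expect_equal(cen$V[1], 80L)
  expect_equal(cen$n_links[1], 80L)
  empty <- make_ideal_aster(10, 0, seed = 1)
  cen0 <- crosslink_census(empty)
  expect_equal(unname(unlist(cen0[1, c("V", "T", "Hp", "Hap", "X")])),
               rep(0L, 5))
})

test_that("census names the motor when a filament reference dangles", {
  traj <- make_random_frame(10, 5, seed = 1)
  traj$motors$fil_b[3] <- 99L
  expect_error(crosslink_census(traj), "motor 2")
})
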