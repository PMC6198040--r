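# Single-step physical laws: growth under load, force-velocity, Kramers
# unbinding, steric pair forces, and the stochastic event statistics they
# imply.

test_that("plus-end growth responds to antagonistic load as exp(f_a/f_g)", {
  # 30 nm/s unloaded for 1 s
  expect_equal(growth_increment(0, 1, vg = 0.03), 0.03)
  # load equal to the characteristic force reduces growth by exp(-1)
  expect_equal(growth_increment(-1.7, 1, vg = 0.03, fg = 1.7),
               0.03 * exp(-1))
  # assisting load does not accelerate growth
  expect_equal(growth_increment(3, 1, vg = 0.03), 0.03)
  expect_error(growth_increment(0, -1), "non-negative")
})

test_that("zero catastrophe rate means unbounded growth", {
  cfg <- sim_config(vg = 0.03, kcat = 1e-300, target_mean_length = NULL,
                    n_nuc = 1, n_mot = 0, t_end = 1)
  fils <- tibble::tibble(length = 0.1, state = "growing")
  set.seed(1)
  for (i in 1:200) fils <- step_dynamic_instability(fils, 0, 1, cfg)[1:2]
  expect_equal(fils$state, "growing")
  expect_equal(fils$length, 0.1 + 200 * 0.03)
})

test_that("mean length at catastrophe is L0 + vg/kcat (no rescue)", {
  cfg <- sim_config(vg = 0.03, n_nuc = 1, n_mot = 0, t_end = 1)  # kcat tied to 2.5 um
  n <- 1200
  dt <- 0.5
  set.seed(42)
  fils <- tibble::tibble(length = cfg$L0, state = "growing")[rep(1, n), ]
  lengths_at_cat <- numeric(0)
  while (nrow(fils) > 0) {
    fils <- step_dynamic_instability(fils, 0, dt, cfg)
    hit <- fils$state == "shrinking"
    lengths_at_cat <- c(lengths_at_cat, fils$length[hit])
    fils <- fils[!hit, 1:2]
  }
  expected <- cfg$L0 + cfg$vg / cfg$kcat
  se <- stats::sd(lengths_at_cat) / sqrt(n)
  # discretisation adds vg*dt/2 = 3 nm; negligible against SE ~ 50 nm
  expect_lt(abs(mean(lengths_at_cat) - expected), 3 * se + cfg$vg * dt)
  expect_equal(length(lengths_at_cat), n)
})

test_that("motor force-velocity is linear with a stall and no backstepping", {
  expect_equal(motor_velocity(-5, vm = 0.03, f_stall = 5), 0)       # stall
  expect_equal(motor_velocity(0, vm = 0.03), 0.03)                  # unloaded
  expect_equal(motor_velocity(-10, vm = 0.03, f_stall = 5), 0)      # clamped
  expect_equal(motor_velocity(2.5, vm = 0.03, f_stall = 5), 0.045)  # assisting
})

test_that("motor heads clamp and dwell at the plus end", {
  s <- motor_step(abscissa = 2.49, v = 0.03, dt = 1, length = 2.5)
  expect_equal(s$abscissa, 2.5)
  expect_true(s$end_bound)
  s2 <- motor_step(1, 0.03, 1, 2.5)
  expect_false(s2$end_bound)
})

test_that("Kramers unbinding rate doubles per f_unbind*log(2) of load", {
  expect_equal(detach_rate(0, 0.1), 0.1)
  expect_equal(detach_rate(2.5, 0.1, 2.5), 0.1 * exp(1))
  expect_equal(detach_rate(-2.5, 0.1, 2.5), 0.1 * exp(1))  # magnitude convention
})

test_that("unloaded dwell times are exponential with means 1/koff and 1/kend", {
  set.seed(7)
  for (rates in list(c(koff = 0.1, side = TRUE), c(koff = 0.05, side = FALSE))) {
    n <- 10000
    dt <- 0.5
    alive <- rep(TRUE, n)
    steps <- integer(n)
    k <- rates[["koff"]]
    while (any(alive)) {
      det <- motor_detach(rep(0, sum(alive)), end_bound = !rates[["side"]],
                          dt = dt, koff = k, kend = k)
      steps[alive] <- steps[alive] + 1L
      alive[alive] <- !det
    }
    dwell <- steps * dt
    se <- stats::sd(dwell) / sqrt(n)
    # geometric discretisation offsets the mean by +dt/2
    expect_lt(abs(mean(dwell) - (1 / k + dt / 2)), 3 * se)
  }
})

test_that("steric force vanishes at contact distance and beyond", {
  f <- steric_pair_force(c(0, 0, 0), c(0.1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(f$f_a, c(0, 0, 0))
  f2 <- steric_pair_force(c(0, 0, 0), c(0.3, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(f2$f_b, c(0, 0, 0))
})

test_that("steric force has magnitude kappa_s*(d0-d), perpendicular to
           parallel axes, and conserves momentum", {
  pa <- c(0, 0, 0); pb <- c(0, 0.05, 0)   # d = d0/2
  ta <- c(1, 0, 0); tb <- c(1, 0, 0)
  f <- steric_pair_force(pa, pb, ta, tb, kappa_s = 50, d0 = 0.1)
  expect_equal(sqrt(sum(f$f_a^2)), 50 * 0.05)
  expect_equal(sum(f$f_a * ta), 0)                 # perpendicular to axis a
  expect_equal(sum(f$f_b * tb), 0)                 # perpendicular to axis b
  expect_equal(f$f_a + f$f_b, c(0, 0, 0))          # Newton pair
  # anti-parallel contact behaves identically
  f2 <- steric_pair_force(pa, pb, ta, -tb, kappa_s = 50, d0 = 0.1)
  expect_equal(sqrt(sum(f2$f_a^2)), 50 * 0.05)
  expect_equal(sum(f2$f_a * ta), 0)
  # crossing filaments still conserve momentum exactly
  set.seed(3)
  for (i in 1:50) {
    th <- runif(1, 0, pi)
    g <- steric_pair_force(runif(3, 0, 0.01), runif(3, 0, 0.05),
                           c(1, 0, 0), c(cos(th), sin(th), 0))
    expect_equal(g$f_a + g$f_b, c(0, 0, 0))
  }
})

test_that("nucleation follows Bernoulli statistics with p = 1 - exp(-k dt)", {
  set.seed(11)
  knuc <- 0.8; dt <- 0.5
  reps <- 10000
  counts <- vapply(seq_len(reps), function(i) nucleate_events(1, knuc, dt),
                   integer(1))
  p <- 1 - exp(-knuc * dt)
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(mean(counts) - p), 4 * se)
  expect_equal(nucleate_events(0, knuc, dt), 0L)
  expect_equal(nucleate_events(100, 0, dt), 0L)
})
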