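# Engine-level behavior: determinism, conservation of structure, diffusion,
# attachment statistics, and motor-driven sliding.

test_that("identical config and seed replay bit-identical trajectories", {
  cfg <- sim_config(n_nuc = 8, n_mot = 20, t_end = 10, Lx = 5, Ly = 5)
  a <- run_simulation(cfg, seed = 99)
  b <- run_simulation(cfg, seed = 99)
  expect_identical(a$filaments, b$filaments)
  expect_identical(a$motors, b$motors)
  c <- run_simulation(cfg, seed = 100)
  expect_false(identical(a$filaments, c$filaments))
})

test_that("filament count never exceeds the nucleator count", {
  cfg <- sim_config(n_nuc = 6, n_mot = 0, t_end = 120, Lx = 5, Ly = 5,
                    knuc = 5)
  traj <- run_simulation(cfg, seed = 2)
  per_frame <- dplyr::count(dplyr::distinct(traj$filaments[c("frame", "fil_id")]),
                            frame)
  expect_true(all(per_frame$n <= 6))
  expect_gt(nrow(per_frame), 0)
  # steady state: the pool stays near-fully occupied once filled
  late <- per_frame$n[per_frame$frame > max(per_frame$frame) / 2]
  expect_gt(mean(late), 3)
})

test_that("with no forces and no noise the state is a fixed point", {
  init <- data.frame(x = 2, y = 2, z = 0, ux = 1, uy = 0, uz = 0, length = 2)
  cfg <- sim_config(n_nuc = 1, n_mot = 0, t_end = 5, Lx = 5, Ly = 5,
                    kT = 0, vg = 1e-12, vs = 1e-12, knuc = 1e-12,
                    target_mean_length = NULL, kcat = 1e-12,
                    init_filaments = init)
  traj <- run_simulation(cfg, seed = 1)
  first <- dplyr::filter(traj$filaments, frame == 0)
  last <- dplyr::filter(traj$filaments, frame == max(frame))
  expect_equal(last$x, first$x, tolerance = 1e-9)
  expect_equal(last$y, first$y, tolerance = 1e-9)
  expect_equal(last$z, first$z, tolerance = 1e-9)
})

test_that("growth moves only the plus end; the minus end is static", {
  init <- data.frame(x = 1, y = 2.5, z = 0, ux = 1, uy = 0, uz = 0,
                     length = 0.5)
  cfg <- sim_config(n_nuc = 1, n_mot = 0, t_end = 30, Lx = 8, Ly = 5,
                    kT = 0, vg = 0.05, target_mean_length = NULL,
                    kcat = 1e-12, knuc = 1e-12, init_filaments = init)
  traj <- run_simulation(cfg, seed = 1)
  minus <- dplyr::filter(traj$filaments, vertex == 0)
  expect_equal(minus$x, rep(1, nrow(minus)), tolerance = 1e-8)
  expect_equal(minus$y, rep(2.5, nrow(minus)), tolerance = 1e-8)
  last <- dplyr::filter(traj$filaments, frame == max(frame))
  expect_equal(max(last$length), 0.5 + 0.05 * 30, tolerance = 1e-3)
  # segment lengths stay uniform (inextensibility up to tolerance)
  segs <- diff(last$x[order(last$vertex)])
  expect_lt(max(abs(segs - segs[1])), 1e-6)
})

test_that("centre-of-mass diffusion matches the drag model", {
  # one free filament, no growth or turnover: MSD per dimension = 2 D t with
  # D = kT / (n_vertices * gamma_vertex)
  init <- data.frame(x = 5, y = 5, z = 0, ux = 1, uy = 0, uz = 0, length = 2.5)
  cfg <- sim_config(n_nuc = 1, n_mot = 0, t_end = 10, Lx = 12, Ly = 12,
                    vg = 1e-12, vs = 1e-12, target_mean_length = NULL,
                    kcat = 1e-12, knuc = 1e-12, init_filaments = init)
  nv <- round(2.5 / cfg$seg) + 1
  gam <- 3 * pi * cfg$viscosity * cfg$seg
  D <- cfg$kT / (nv * gam)
  reps <- 40
  sq <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    traj <- run_simulation(cfg, seed = 1000 + r)
    com <- dplyr::summarise(dplyr::group_by(traj$filaments, frame),
                            x = mean(x), y = mean(y))
    com <- com[order(com$frame), ]
    n <- nrow(com)
    sq[r, ] <- c((com$x[n] - com$x[1])^2, (com$y[n] - com$y[1])^2)
  }
  msd <- mean(sq)
  expected <- 2 * D * 10
  se <- stats::sd(as.vector(sq)) / sqrt(length(sq))
  expect_lt(abs(msd - expected), 3 * se)
})

test_that("a free motor head binds a filament in range at rate k_on", {
  # 10^4 singly bound motors facing a parallel filament 30 nm away;
  # one step of binding kinetics approximates a Bernoulli trial with
  # p = 1 - exp(-k_on dt)
  n <- 10000
  init <- data.frame(x = c(1, 1), y = c(2, 2.03), z = c(0, 0),
                     ux = c(1, 1), uy = c(0, 0), uz = c(0, 0),
                     length = c(3, 3))
  mot <- data.frame(fil_a = rep(1L, n), abs_a = runif(n, 0.2, 2.8),
                    fil_b = NA_integer_, abs_b = NA_real_)
  dt <- 0.002
  cfg <- sim_config(n_nuc = 2, n_mot = n, t_end = dt, dt = dt, Lx = 5, Ly = 5,
                    kT = 0, vg = 1e-12, vs = 1e-12, target_mean_length = NULL,
                    kcat = 1e-12, knuc = 1e-12, kon = 5,
                    koff = 1e-9, kend = 1e-9,
                    init_filaments = init, init_motors = mot)
  traj <- run_simulation(cfg, seed = 5)
  last <- dplyr::filter(traj$motors, frame == max(frame))
  bound2 <- sum(last$fil_a >= 0 & last$fil_b >= 0)
  p <- 1 - exp(-5 * dt)
  se <- sqrt(p * (1 - p) * n)
  expect_lt(abs(bound2 - n * p), 4 * se)
  # no filament in range: no crosslinks form
  init2 <- init; init2$y[2] <- 3   # 1 um away >> r_b
  cfg2 <- sim_config(n_nuc = 2, n_mot = n, t_end = dt, dt = dt, Lx = 5, Ly = 5,
                     kT = 0, vg = 1e-12, vs = 1e-12, target_mean_length = NULL,
                     kcat = 1e-12, knuc = 1e-12, kon = 5,
                     koff = 1e-9, kend = 1e-9,
                     init_filaments = init2, init_motors = mot)
  traj2 <- run_simulation(cfg2, seed = 5)
  last2 <- dplyr::filter(traj2$motors, frame == max(frame))
  expect_equal(sum(last2$fil_a >= 0 & last2$fil_b >= 0), 0L)
})

test_that("a motor crosslinking two anti-parallel filaments slides them
           apart", {
  # filament 1 spans x in [2, 5] pointing +x; filament 2 spans [3, 6]
  # pointing -x; the motor bridges both at x = 4, mid-overlap
  init <- data.frame(x = c(2, 6), y = c(4, 4.04), z = c(0, 0),
                     ux = c(1, -1), uy = c(0, 0), uz = c(0, 0),
                     length = c(3, 3))
  mot <- data.frame(fil_a = 1L, abs_a = 2, fil_b = 2L, abs_b = 2)
  cfg <- sim_config(n_nuc = 2, n_mot = 1, t_end = 25, Lx = 20, Ly = 8,
                    kT = 0, vg = 1e-12, vs = 1e-12, target_mean_length = NULL,
                    kcat = 1e-12, knuc = 1e-12, kon = 1e-12,
                    koff = 1e-12, kend = 1e-12, f_unbind = 1e6,
                    kappa_s = 1e-12,
                    init_filaments = init, init_motors = mot)
  traj <- run_simulation(cfg, seed = 1)
  minus <- dplyr::filter(traj$filaments, vertex == 0)
  sep <- dplyr::summarise(dplyr::group_by(minus, frame),
                          d = abs(diff(range(x))))
  sep <- sep[order(sep$frame), ]
  # relative sliding at up to 2 v_m while both heads walk
  expect_gt(sep$d[nrow(sep)] - sep$d[1], 0.5)
})

test_that("the run log counts events and the manifest reproduces runs", {
  cfg <- sim_config(n_nuc = 5, n_mot = 10, t_end = 20, Lx = 5, Ly = 5)
  traj <- run_simulation(cfg, seed = 3)
  expect_gt(traj$log$nucleations, 0)
  expect_gt(traj$log$first_attachments, 0)
  man <- run_manifest(cfg, 3, log = traj$log)
  expect_equal(man$seed, 3L)
  traj2 <- run_simulation(do.call(sim_config, man$config), man$seed)
  expect_identical(traj$filaments, traj2$filaments)
})
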