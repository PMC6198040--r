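# Single-filament motor-distribution theory: closed forms against the
# method-of-lines oracle, the speed-ratio scaling property, and the
# stochastic validator.

test_that("closed forms agree with the numerical oracle across the
           parameter grid", {
  for (vp in c(1.5, 3, 6)) for (kr in c(0.5, 1, 2)) {
    p <- theory_params(vg = 0.09 / vp, vm = 0.09, kon_prime = 2,
                       koff = 0.1, kend = 0.1 / kr)
    t_end <- 250
    orc <- cached_oracle(sprintf("acc_%g_%g", vp, kr), p, t_end, nx = 3000)
    keep <- orc$t >= 0.2 * t_end
    ns_err <- abs(ns_closed_form(p, orc$t[keep]) - orc$ns[keep]) / orc$ns[keep]
    ne_err <- abs(ne_closed_form(p, orc$t[keep]) - orc$ne[keep]) /
      pmax(orc$ne[keep], 1e-9)
    expect_lt(max(ns_err), 0.005)
    expect_lt(max(ne_err), 0.005)
    rat_err <- abs(ratio_end_to_side(p, orc$t[keep]) - orc$ratio[keep]) /
      orc$ratio[keep]
    expect_lt(max(rat_err), 0.01)
  }
})

test_that("degenerate and boundary cases of the closed forms", {
  p <- theory_params(vg = 0.01, vm = 0.03)
  expect_equal(ns_closed_form(p, 0), 0)
  expect_equal(ne_closed_form(p, 0), 0)
  expect_error(ns_closed_form(p, -1), "non-negative")
  expect_error(ratio_end_to_side(p, 0), "undefined")
  # vm = vg: the tip outruns no motors, zero incoming flux
  peq <- theory_params(vg = 0.03, vm = 0.03)
  expect_warning(ne_eq <- ne_closed_form(peq, c(10, 100)), class = "mtnet_no_end_flux")
  expect_equal(ne_eq, c(0, 0))
  # long-time limits: ne -> n_inf, ns slope -> rho0*vg
  expect_lt(abs(ne_closed_form(p, 1e5) - p$n_inf) / p$n_inf, 1e-6)
  slope <- (ns_closed_form(p, 1e5) - ns_closed_form(p, 1e5 - 100)) / 100
  expect_lt(abs(slope - p$rho0 * p$vg) / (p$rho0 * p$vg), 1e-6)
  # the ratio decays to zero at long times
  expect_lt(ratio_end_to_side(p, 1e5), 1e-3)
  # the degenerate two-exponential case evaluates continuously:
  # koff/v' = kend exactly
  pd <- theory_params(vg = 0.01, vm = 0.03, koff = 0.15, kend = 0.05)
  pd_near <- theory_params(vg = 0.01, vm = 0.03, koff = 0.15, kend = 0.0500001)
  tt <- c(5, 50, 200)
  expect_equal(ne_closed_form(pd, tt), ne_closed_form(pd_near, tt),
               tolerance = 1e-4)
})

test_that("the end/side ratio depends on speeds only through vm/vg", {
  p1 <- theory_params(vg = 0.01, vm = 0.03)
  p3 <- theory_params(vg = 0.03, vm = 0.09)   # both speeds scaled x3
  tt <- c(10, 50, 150, 400)
  r1 <- ratio_end_to_side(p1, tt)
  r3 <- ratio_end_to_side(p3, tt)
  expect_equal(r1, r3, tolerance = 1e-9)
  # and via the oracle, independently of the closed form
  o1 <- integrate_profile(p1, 200, nx = 3000)
  o3 <- integrate_profile(p3, 200, nx = 3000)
  keep <- o1$t >= 40
  expect_lt(max(abs(o1$ratio[keep] - o3$ratio[keep]) / o1$ratio[keep]), 0.01)
})

test_that("oracle honours its degenerate limits and refuses CFL violations", {
  p0 <- theory_params(vg = 0.01, vm = 0.03, kon_prime = 1e-12)
  o <- integrate_profile(p0, 50, nx = 1000)
  expect_lt(max(o$ns), 1e-9)
  expect_lt(max(o$ne), 1e-9)
  expect_error(integrate_profile(theory_params(), 100, nx = 1000, dt = 10),
               "CFL")
})

test_that("stochastic single-filament ratios track the oracle within
           replicate error", {
  p <- theory_params(vg = 0.01, vm = 0.03, kon_prime = 4)
  t_end <- 200
  orc <- cached_oracle("acc_stoch", p, t_end, nx = 2500)
  sim <- stochastic_single_filament(p, t_end, n_reps = 4, dt = 0.02, seed = 3)
  # compare the pooled ratio at late times where ns is populated; the SE is
  # the jackknife over replicates floored by Poisson count propagation
  for (tt in c(80, 120, 160, 200)) {
    io <- which.min(abs(orc$t - tt))
    is <- which.min(abs(sim$t - tt))
    se_pois <- sim$ratio_pooled[is] *
      sqrt(1 / (4 * sim$ne[is]) + 1 / (4 * sim$ns[is]))
    se <- max(sim$ratio_pooled_se[is], se_pois)
    expect_lt(abs(sim$ratio_pooled[is] - orc$ratio[io]), 3 * se)
  }
})

test_that("stochastic error shrinks with the number of replicates", {
  p <- theory_params(vg = 0.01, vm = 0.03, kon_prime = 4)
  orc <- integrate_profile(p, 120, nx = 2000)
  rms <- function(n_reps) {
    sim <- stochastic_single_filament(p, 120, n_reps = n_reps, dt = 0.05,
                                      seed = 17)
    keep <- sim$t >= 60
    oi <- vapply(sim$t[keep], function(tt) orc$ratio[which.min(abs(orc$t - tt))],
                 double(1))
    sqrt(mean((sim$ratio[keep] - oi)^2))
  }
  expect_lt(rms(32), rms(4))
})
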