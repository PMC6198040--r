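# Motor distribution along a single growing filament.
#
# Continuum model: side density rho(x, t) on 0 < x < L(t) = vg*t obeys
#   d_t rho = kon' * Theta(vg t - x) - koff * rho - vm * d_x rho,
# with no inflow at the minus end, and the end-bound population obeys
#   d_t ne = -kend * ne + (vm - vg) * rho(vg t, t).
#
# Solving by characteristics gives, for vm > vg,
#   rho(x, t)      = rho0 * (1 - exp(-koff x / vm))        (x <= vg t)
#   rho(vg t, t)   = rho0 * (1 - exp(-(koff/v') t)),  v' = vm/vg
#   ns(t)          = rho0 * (L - (vm/koff) * (1 - exp(-koff L / vm)))
#   ne(t)          = n_inf * (1 - psi exp(-(koff/v') t) - (1-psi) exp(-kend t))
# with rho0 = kon'/koff, n_inf = rho0 (vm - vg)/kend and
# psi = (1 - koff/(v' kend))^-1 (analytic limit when koff/v' = kend).
# The side-population decay length is vm/koff (the distance a motor walks in
# one residence time): a depletion layer sits at the minus end because bound
# motors stream toward the plus end. The end/side ratio ne/ns at a given
# time depends on (v', koff, kend) only -- the speed scale cancels -- which
# is why vg/vm acts as a control parameter for network organization.

#' Parameters of the single-filament motor distribution model
#'
#' @param vg filament growth speed, um/s
#' @param vm motor speed, um/s
#' @param kon_prime binding rate per unit filament length, 1/(um s)
#' @param koff unbinding rate from the filament side, 1/s
#' @param kend unbinding rate from the plus end, 1/s
#' @return object of class `theory_params` carrying the base parameters and
#'   the derived quantities `rho0` (motors/um), `lambda_m = vg/koff`,
#'   `lambda_e = vg/kend`, `vprime = vm/vg` and `n_inf` (motors at the end of
#'   an infinitely long filament; 0 when `vm <= vg`)
#' @examples
#' p <- theory_params(vg = 0.005, vm = 0.03)
#' p$n_inf
#' @export
theory_params <- function(vg = 0.005, vm = 0.03, kon_prime = 2,
                          koff = 0.1, kend = 0.05) {
  for (v in list(vg = vg, vm = vm, kon_prime = kon_prime, koff = koff, kend = kend))
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      abort("all theory parameters must be single positive numbers")
  rho0 <- kon_prime / koff
  structure(list(vg = vg, vm = vm, kon_prime = kon_prime, koff = koff,
                 kend = kend, rho0 = rho0,
                 lambda_m = vg / koff, lambda_e = vg / kend,
                 vprime = vm / vg,
                 n_inf = max(0, rho0 * (vm - vg) / kend)),
            class = "theory_params")
}

#' Side-bound motor number, closed form
#'
#' Number of motors bound along the side of a filament of age `t` (length
#' `L = vg*t`). Zero at `t = 0`; the slope approaches `rho0 * vg` once the
#' minus-end depletion layer (width `vm/koff`) is established.
#'
#' @param p a [theory_params()]
#' @param t time since nucleation, s (vectorised, non-negative)
#' @return motor number (same length as `t`)
#' @export
ns_closed_form <- function(p, t) {
  stopifnot(inherits(p, "theory_params"))
  if (any(t < 0)) abort("t must be non-negative")
  L <- p$vg * t
  lw <- p$vm / p$koff
  p$rho0 * (L - lw * (1 - exp(-L / lw)))
}

#' End-bound motor number, closed form
#'
#' Rises from 0 to `n_inf`. When `vm <= vg` the plus end outruns the motors,
#' the incoming flux `(vm - vg) * rho` is non-positive and the end
#' population is identically zero (returned clamped, with a warning).
#'
#' @inheritParams ns_closed_form
#' @return motor number (same length as `t`)
#' @export
ne_closed_form <- function(p, t) {
  stopifnot(inherits(p, "theory_params"))
  if (any(t < 0)) abort("t must be non-negative")
  if (p$vm <= p$vg) {
    warn("vm <= vg: no net flux into the plus end; ne = 0", class = "mtnet_no_end_flux")
    return(rep(0, length(t)))
  }
  a <- p$koff / p$vprime            # decay rate of the tip density
  if (abs(p$kend - a) < 1e-10 * p$kend) {
    # degenerate case: analytic limit of the two-exponential form
    return(p$n_inf * (1 - exp(-a * t) - a * t * exp(-a * t)))
  }
  psi <- p$kend / (p$kend - a)
  p$n_inf * (1 - psi * exp(-a * t) - (1 - psi) * exp(-p$kend * t))
}

#' Ratio of end-bound to side-bound motors
#'
#' `ne(t)/ns(t)`. At fixed unbinding rates the ratio depends on the speeds
#' only through `vm/vg`: scaling both speeds by a common factor leaves the
#' ratio unchanged at any given time point in the filament's life (the
#' filament lengths differ). The ratio decays to 0 at long times since `ne`
#' is bounded by `n_inf` while `ns` grows linearly.
#'
#' @inheritParams ns_closed_form
#' @param t time, s; must be positive (the ratio is undefined at t = 0)
#' @return dimensionless ratio (vectorised)
#' @export
ratio_end_to_side <- function(p, t) {
  if (any(t <= 0)) abort("the end/side ratio is undefined at t <= 0")
  ns <- ns_closed_form(p, t)
  ne <- ne_closed_form(p, t)
  ne / ns
}

#' Method-of-lines integration of the motor-distribution model
#'
#' Independent numerical oracle for the closed forms: first-order upwind
#' advection of the side density on a fixed grid with the moving-domain
#' binding source (area-weighted at the front cell) and explicit
#' integration of the plus-end flux balance.
#'
#' By default the step is locked to the grid, `dt = dx/vm`, which makes the
#' upwind advection exact (zero numerical diffusion); binding/unbinding are
#' then applied as an exact exponential relaxation per step, and the
#' plus-end balance is integrated with an exponential integrator. Supplying
#' `dt` explicitly switches to a conventional first-order upwind step;
#' values violating the advective stability bound `dt <= dx/vm` are
#' refused.
#'
#' @param p a [theory_params()]
#' @param t_end final time, s
#' @param nx number of grid cells (the grid spans `[0, vg*t_end]` plus the
#'   distance a motor can overshoot); it must resolve the depletion length
#'   `vm/koff`
#' @param n_out number of output sample times
#' @param dt optional explicit time step, s (see above)
#' @return tibble of class `motor_profile` with columns `t`, `ns`, `ne`,
#'   `ratio` and attribute `rho` (final density profile tibble `x`, `rho`)
#' @export
integrate_profile <- function(p, t_end, nx = 2000, n_out = 100, dt = NULL) {
  stopifnot(inherits(p, "theory_params"))
  if (t_end <= 0) abort("t_end must be positive")
  L_end <- p$vg * t_end
  x_max <- L_end + min(3 * p$vm / p$koff, p$vm * t_end) + 1e-9
  dx <- x_max / nx
  if (dx > 0.5 * p$vm / p$koff)
    abort("grid too coarse: dx must resolve the depletion length vm/koff")
  exact_advection <- is.null(dt)
  if (exact_advection) dt <- dx / p$vm
  if (dt > dx / p$vm + 1e-15)
    abort(sprintf("CFL violation: dt = %g exceeds dx/vm = %g", dt, dx / p$vm))
  nt <- ceiling(t_end / dt)
  if (!exact_advection) dt <- t_end / nt
  xc <- (seq_len(nx) - 0.5) * dx          # cell centres
  rho <- numeric(nx)
  ne <- 0
  t_out <- seq(0, t_end, length.out = n_out + 1)[-1]
  out_ns <- out_ne <- numeric(length(t_out))
  io <- 1
  cfl <- p$vm * dt / dx
  decay <- exp(-p$koff * dt)
  gain <- p$kon_prime / p$koff * (1 - decay)
  dece <- exp(-p$kend * dt)
  fluxw <- if (p$kend > 0) (1 - dece) / p$kend else dt
  vrel <- max(0, p$vm - p$vg)
  for (k in seq_len(nt)) {
    t_now <- (k - 1) * dt
    front <- p$vg * t_now
    # tip density from one-sided interpolation over occupied cells only:
    # the profile has a slope discontinuity at the front, so interpolating
    # across it would bias the plus-end flux
    rho_tip <- 0
    if (front > 0) {
      jf <- min(max(floor(front / dx - 0.5) + 1, 1), nx)   # last centre <= front
      if (jf >= 2) {
        sl <- (rho[jf] - rho[jf - 1]) / dx
        rho_tip <- max(0, rho[jf] + sl * (front - xc[jf]))
      } else rho_tip <- rho[1] * front / xc[1]
    }
    ne <- ne * dece + vrel * rho_tip * fluxw
    if (exact_advection) {
      # shift by exactly one cell (exact advection at CFL = 1), then apply
      # the exact exponential binding/unbinding relaxation with the source
      # evaluated at the midpoint front position
      covm <- pmin(pmax((p$vg * (t_now + dt / 2) - (xc - 0.5 * dx)) / dx, 0), 1)
      rho <- c(0, rho[-nx]) * decay + gain * covm
    } else {
      cov <- pmin(pmax((front - (xc - 0.5 * dx)) / dx, 0), 1)
      upw <- c(0, rho[-nx])
      rho <- rho + dt * (p$kon_prime * cov - p$koff * rho) - cfl * (rho - upw)
    }
    t_next <- k * dt
    while (io <= length(t_out) && t_out[io] <= t_next + 1e-12) {
      front2 <- p$vg * t_out[io]
      cov2 <- pmin(pmax((front2 - (xc - 0.5 * dx)) / dx, 0), 1)
      out_ns[io] <- sum(rho * cov2) * dx
      out_ne[io] <- ne
      io <- io + 1
    }
  }
  out <- tibble::tibble(t = t_out, ns = out_ns, ne = out_ne,
                        ratio = ifelse(out_ns > 0, out_ne / out_ns, NA_real_))
  structure(out, rho = tibble::tibble(x = xc, rho = rho),
            class = c("motor_profile", class(out)))
}

#' Stochastic single-filament simulation
#'
#' Discrete-event counterpart of the continuum model: motors bind along the
#' growing filament at rate `kon_prime` per unit length, walk at `vm`, dwell
#' at the plus end and unbind at `koff` (side) or `kend` (end). Replicate
#' ratio trajectories average toward the continuum oracle as the number of
#' replicates grows.
#'
#' @param p a [theory_params()]
#' @param t_end final time, s
#' @param n_reps number of replicate filaments (4 matches the validation
#'   protocol of the reference figure)
#' @param dt event time step, s
#' @param n_out number of output sample times
#' @param seed integer seed
#' @return tibble with columns `t`, `ns`, `ne` (replicate-mean counts),
#'   `ratio` (mean of per-replicate ratios) with `ratio_se`, and
#'   `ratio_pooled` (ratio of replicate-mean counts, the direct analogue of
#'   the continuum `ne/ns`, free of the ratio-of-small-counts bias) with its
#'   jackknife standard error `ratio_pooled_se`; attribute `reps` holds the
#'   per-replicate ratio matrix (time x replicate)
#' @export
stochastic_single_filament <- function(p, t_end, n_reps = 4, dt = 0.01,
                                       n_out = 50, seed = 1) {
  stopifnot(inherits(p, "theory_params"), n_reps >= 1)
  set.seed(seed)
  t_out <- seq(0, t_end, length.out = n_out + 1)[-1]
  NS <- NE <- matrix(0, length(t_out), n_reps)
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  p_off <- 1 - exp(-p$koff * dt)
  p_end <- 1 - exp(-p$kend * dt)
  for (r in seq_len(n_reps)) {
    xs <- numeric(0)        # side-bound motor positions
    n_end <- 0L
    io <- 1
    for (k in seq_len(nt)) {
      t_now <- k * dt
      L <- p$vg * t_now
      # binding (Poisson number along the existing lattice)
      nb <- stats::rpois(1, p$kon_prime * L * dt)
      if (nb > 0) xs <- c(xs, runif(nb, 0, L))
      # walking; heads reaching the plus end transfer to the end pool
      if (length(xs) > 0) {
        xs <- xs + p$vm * dt
        hit <- xs >= L
        n_end <- n_end + sum(hit)
        xs <- xs[!hit]
      }
      # unbinding
      if (length(xs) > 0) xs <- xs[runif(length(xs)) >= p_off]
      if (n_end > 0) n_end <- n_end - stats::rbinom(1, n_end, p_end)
      while (io <= length(t_out) && t_out[io] <= t_now + 1e-12) {
        NS[io, r] <- length(xs)
        NE[io, r] <- n_end
        io <- io + 1
      }
    }
  }
  ratios <- ifelse(NS > 0, NE / NS, NA_real_)
  se <- apply(ratios, 1, function(z) stats::sd(z, na.rm = TRUE) /
                                      sqrt(sum(!is.na(z))))
  ns_bar <- rowMeans(NS)
  ne_bar <- rowMeans(NE)
  # pooled estimator (ratio of replicate-mean counts, the direct analogue of
  # the continuum ne/ns) with jackknife standard error over replicates
  pooled <- ifelse(ns_bar > 0, ne_bar / ns_bar, NA_real_)
  pooled_se <- pooled
  if (n_reps > 1) {
    jk <- sapply(seq_len(n_reps), function(r) {
      nsr <- rowMeans(NS[, -r, drop = FALSE])
      ifelse(nsr > 0, rowMeans(NE[, -r, drop = FALSE]) / nsr, NA_real_)
    })
    pooled_se <- sqrt((n_reps - 1) / n_reps *
                        rowSums((jk - rowMeans(jk, na.rm = TRUE))^2, na.rm = TRUE))
  }
  tibble::tibble(t = t_out, ns = ns_bar, ne = ne_bar,
                 ratio = rowMeans(ratios, na.rm = TRUE), ratio_se = se,
                 ratio_pooled = pooled, ratio_pooled_se = pooled_se) |>
    structure(reps = ratios)
}
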