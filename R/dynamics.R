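# Elemental physics operations. These are the single-step laws the compiled
# engine applies; they are exposed as vectorised pure functions so each law
# can be exercised and validated in isolation.

#' Force-dependent growth increment of a filament plus end
#'
#' A growing plus end elongates by `vg * exp(f_a / fg) * dt` under an
#' antagonistic load `f_a < 0`; an assisting load does not accelerate growth
#' (the exponential factor is capped at 1).
#'
#' @param f_a antagonistic force on the tip, pN (negative = opposing growth)
#' @param dt time step, s (must be non-negative)
#' @param vg unloaded growth speed, um/s
#' @param fg characteristic growth-stall force, pN
#' @return length increment in um, vectorised over `f_a`
#' @examples
#' growth_increment(0, 1, vg = 0.03)          # 30 nm in 1 s
#' growth_increment(-1.7, 1, vg = 0.03, fg = 1.7) / 0.03  # exp(-1)
#' @export
growth_increment <- function(f_a, dt, vg = 0.03, fg = 1.7) {
  if (any(dt < 0)) abort("dt must be non-negative")
  vg * pmin(1, exp(f_a / fg)) * dt
}

#' First-order event probability over one time step
#'
#' Nucleation, catastrophe, attachment and detachment are all first-order
#' random events with constant rate: the per-step probability is
#' `1 - exp(-rate * dt)`.
#'
#' @param rate event rate, 1/s
#' @param dt time step, s
#' @return probability in \[0, 1\]
#' @export
event_prob <- function(rate, dt) 1 - exp(-rate * dt)

#' One dynamic-instability step for a table of filaments
#'
#' Growing filaments elongate under their tip load and catastrophe with
#' probability `1 - exp(-kcat dt)`; shrinking filaments shorten by `vs * dt`
#' and are flagged `removed` when their length reaches zero. There is no
#' rescue.
#'
#' @param fils tibble with columns `length` (um) and `state`
#'   (`"growing"`/`"shrinking"`)
#' @param f_a per-filament antagonistic tip force, pN (recycled)
#' @param dt time step, s
#' @param cfg an [sim_config()] supplying `vg`, `vs`, `kcat`, `fg`
#' @return the input tibble with updated `length`, `state` and a logical
#'   `removed` column
#' @export
step_dynamic_instability <- function(fils, f_a, dt, cfg) {
  if (dt < 0) abort("dt must be non-negative")
  n <- nrow(fils)
  f_a <- rep_len(f_a, n)
  growing <- fils$state == "growing"
  new_len <- fils$length
  new_len[growing] <- new_len[growing] +
    growth_increment(f_a[growing], dt, cfg$vg, cfg$fg)
  new_len[!growing] <- new_len[!growing] - cfg$vs * dt
  cat_hit <- growing & runif(n) < event_prob(cfg$kcat, dt)
  new_state <- ifelse(cat_hit, "shrinking", fils$state)
  dplyr::mutate(fils, length = pmax(.env$new_len, 0), state = .env$new_state,
                removed = !.env$growing & .env$new_len <= 0)
}

#' Linear force-velocity relation of a crosslinking motor head
#'
#' `v = vm * (1 + f_par / f_stall)`, clamped below at zero (no load-driven
#' backstepping). `f_par` is the component of the load along the head's
#' direction of travel: `-f_stall` stalls the head, `0` gives the unloaded
#' speed.
#'
#' @param f_par load component along the travel direction, pN
#' @param vm unloaded motor speed, um/s
#' @param f_stall stall force, pN
#' @return speed in um/s (vectorised)
#' @export
motor_velocity <- function(f_par, vm = 0.03, f_stall = 5) {
  pmax(0, vm * (1 + f_par / f_stall))
}

#' Kramers load-dependent unbinding rate
#'
#' `k = k_base * exp(|f_load| / f_unbind)` where `k_base` is `koff` for a
#' side-bound head and `kend` for an end-bound head.
#'
#' @param f_load spring force on the head, pN (magnitude is used)
#' @param k_base unloaded unbinding rate, 1/s
#' @param f_unbind characteristic unbinding force, pN
#' @return rate in 1/s (vectorised)
#' @export
detach_rate <- function(f_load, k_base = 0.1, f_unbind = 2.5) {
  k_base * exp(abs(f_load) / f_unbind)
}

#' Advance a motor head along its filament
#'
#' The abscissa advances by `v * dt` toward the plus end and is clamped at
#' the filament length; a head that reaches the plus end is flagged
#' end-bound and dwells there.
#'
#' @param abscissa head position from the minus end, um
#' @param v head speed from [motor_velocity()], um/s
#' @param dt time step, s
#' @param length filament length, um
#' @return tibble with columns `abscissa` and `end_bound`
#' @export
motor_step <- function(abscissa, v, dt, length) {
  a <- pmin(pmax(abscissa + v * dt, 0), length)
  tibble::tibble(abscissa = a, end_bound = a >= length)
}

#' Stochastic unbinding of motor heads over one step
#'
#' @param f_load spring force magnitude per head, pN
#' @param end_bound logical, end-bound heads use `kend` as base rate
#' @param dt time step, s
#' @param koff,kend,f_unbind unbinding parameters
#' @return logical vector, `TRUE` where the head detached this step
#' @export
motor_detach <- function(f_load, end_bound, dt, koff = 0.1, kend = 0.05,
                         f_unbind = 2.5) {
  k <- detach_rate(f_load, ifelse(end_bound, kend, koff), f_unbind)
  runif(length(k)) < event_prob(k, dt)
}

#' Soft-core steric force between two filament points
#'
#' For a separation `d < d0` the two filaments are pushed apart with equal
#' and opposite forces of magnitude `kappa_s * (d0 - d)`; the force vanishes
#' for `d >= d0`. The push acts along the separation vector with its
#' component along the mean filament axis removed, so the pair conserves
#' momentum exactly and is perpendicular to both axes whenever the filaments
#' are parallel or anti-parallel (steric forces must not interfere with
#' sliding along the axis).
#'
#' @param pa,pb points on filaments A and B (length-3 numeric)
#' @param ta,tb local unit tangents of A and B at those points
#' @param kappa_s steric stiffness, pN/um
#' @param d0 equilibrium distance, um
#' @return list with force vectors `f_a`, `f_b` (pN) and the separation `d`
#' @export
steric_pair_force <- function(pa, pb, ta, tb, kappa_s = 50, d0 = 0.1) {
  dvec <- pb - pa
  d <- sqrt(sum(dvec^2))
  if (d >= d0) return(list(f_a = c(0, 0, 0), f_b = c(0, 0, 0), d = d))
  if (d < 1e-12) {
    phi <- runif(1, 0, 2 * pi)
    u <- c(cos(phi), sin(phi), 0)
  } else {
    u <- dvec / d
  }
  sgn <- if (sum(ta * tb) >= 0) 1 else -1
  m <- ta + sgn * tb
  mn <- sqrt(sum(m^2))
  if (mn > 1e-9) {
    m <- m / mn
    u <- u - sum(u * m) * m
    un <- sqrt(sum(u^2))
    if (un < 1e-9) {
      # separation parallel to the axes: seeded arbitrary perpendicular
      phi <- runif(1, 0, 2 * pi)
      e1 <- c(-m[2], m[1], 0)
      if (sqrt(sum(e1^2)) < 1e-9) e1 <- c(1, 0, 0)
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(m[2] * e1[3] - m[3] * e1[2],
              m[3] * e1[1] - m[1] * e1[3],
              m[1] * e1[2] - m[2] * e1[1])
      u <- cos(phi) * e1 + sin(phi) * e2
    } else {
      u <- u / un
    }
  }
  fm <- kappa_s * (d0 - d)
  list(f_a = -fm * u, f_b = fm * u, d = d)
}

#' Nucleation events for a pool of free nucleators
#'
#' Each free nucleator fires independently with probability
#' `1 - exp(-knuc * dt)` in one step.
#'
#' @param n_free number of free nucleators
#' @param knuc nucleation rate per nucleator, 1/s
#' @param dt time step, s
#' @return integer number of nucleation events this step
#' @export
nucleate_events <- function(n_free, knuc = 1, dt = 0.002) {
  if (n_free == 0 || knuc == 0) return(0L)
  sum(runif(n_free) < event_prob(knuc, dt))
}
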