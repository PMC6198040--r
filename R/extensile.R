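# Extensile-behavior metric: the minus-end velocity-polarity correlation.
# Anti-parallel motor sliding transports a filament backward while its plus
# end grows forward, so extensile nematic networks show a negative mean
# v_hat . p_hat. Measuring from the minus end avoids the trivial positive
# contribution of plus-end growth.

#' Minus-end velocity-polarity correlation
#'
#' For every filament present in the frames nearest to `t0` and `t0 +
#' delta_t`, computes the unit minus-end displacement direction `v_hat`
#' (minimum-image across the periodic box) and the unit plus-end direction
#' `p_hat` at the later frame, and returns the per-filament dot products and
#' their mean. Filaments whose minus-end displacement is below `min_disp`
#' (default 1 nm; `v_hat` is undefined at zero displacement) are excluded.
#'
#' @param traj an [mt_trajectory()]
#' @param t0 start time, s; should be past the steady-state onset of the
#'   filament length distribution
#' @param delta_t lag, s (default 100)
#' @param min_disp exclusion threshold on the displacement magnitude, um
#' @return a tibble of class `vp_sample` with one row per contributing
#'   filament (`fil_id`, `vp`) and attributes `mean`, `n`, `t0`, `delta_t`
#' @export
compute_vp <- function(traj, t0, delta_t = 100, min_disp = 1e-3) {
  ft <- frame_times(traj)
  pick <- function(tt) {
    i <- which.min(abs(ft$time - tt))
    if (abs(ft$time[i] - tt) > max(diff(sort(ft$time)), na.rm = TRUE))
      abort(sprintf("no frame near t = %g s", tt))
    ft$frame[i]
  }
  f0 <- pick(t0); f1 <- pick(t0 + delta_t)
  if (f0 == f1) abort("delta_t shorter than the frame interval")
  fl <- traj$filaments
  minus <- dplyr::filter(fl, .data$vertex == 0, .data$frame %in% c(f0, f1))
  a <- dplyr::filter(minus, .data$frame == f0)
  b <- dplyr::filter(minus, .data$frame == f1)
  # same filament = same id and same birth time (ids are never recycled by
  # the engine, but fixtures may restart numbering)
  key_a <- paste(a$fil_id, a$birth); key_b <- paste(b$fil_id, b$birth)
  common <- intersect(key_a, key_b)
  a <- a[match(common, key_a), , drop = FALSE]
  b <- b[match(common, key_b), , drop = FALSE]
  if (nrow(a) == 0) abort("no filament present in both frames")
  mi <- function(d, L) d - L * round(d / L)
  dx <- mi(b$x - a$x, traj$box$Lx)
  dy <- mi(b$y - a$y, traj$box$Ly)
  dz <- b$z - a$z
  disp <- sqrt(dx^2 + dy^2 + dz^2)
  # plus-end direction at the later frame: last vertex minus first vertex
  plus <- dplyr::filter(fl, .data$frame == f1)
  plus <- dplyr::summarise(
    dplyr::group_by(plus, .data$fil_id, .data$birth),
    px = .data$x[which.max(.data$vertex)] - .data$x[which.min(.data$vertex)],
    py = .data$y[which.max(.data$vertex)] - .data$y[which.min(.data$vertex)],
    pz = .data$z[which.max(.data$vertex)] - .data$z[which.min(.data$vertex)],
    .groups = "drop")
  ib <- match(paste(b$fil_id, b$birth), paste(plus$fil_id, plus$birth))
  pn <- sqrt(plus$px[ib]^2 + plus$py[ib]^2 + plus$pz[ib]^2)
  keep <- disp >= min_disp & pn > 1e-12
  vp <- (dx * plus$px[ib] + dy * plus$py[ib] + dz * plus$pz[ib])[keep] /
    (disp[keep] * pn[keep])
  out <- tibble::tibble(fil_id = a$fil_id[keep], vp = vp)
  structure(out, mean = mean(vp), n = sum(keep), t0 = t0, delta_t = delta_t,
            class = c("vp_sample", class(out)))
}

#' Mean minus-end velocity-polarity correlation over a window
#'
#' Averages [compute_vp()] over all start times `t0` in
#' `[t_start, t_end - delta_t]` on the trajectory's frame grid and pools the
#' per-filament samples.
#'
#' @inheritParams compute_vp
#' @param t_start analysis onset, s (steady state of the length distribution)
#' @return tibble with one row per sample time (`t0`, `mean_vp`,
#'   `n_filaments`) and attribute `mean` (pooled mean)
#' @export
vp_time_course <- function(traj, t_start, delta_t = 100, min_disp = 1e-3) {
  ft <- frame_times(traj)
  t_max <- max(ft$time)
  t0s <- ft$time[ft$time >= t_start & ft$time <= t_max - delta_t]
  if (length(t0s) == 0) abort("window contains no usable start frame")
  rows <- purrr::map(t0s, function(tt) {
    s <- compute_vp(traj, tt, delta_t, min_disp)
    tibble::tibble(t0 = tt, mean_vp = attr(s, "mean"), n_filaments = attr(s, "n"),
                   sum_vp = sum(s$vp))
  })
  out <- dplyr::bind_rows(rows)
  pooled <- sum(out$sum_vp) / sum(out$n_filaments)
  structure(out[c("t0", "mean_vp", "n_filaments")], mean = pooled)
}
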