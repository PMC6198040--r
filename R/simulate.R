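# Running the engine and the trajectory container shared by simulation and
# fixtures: downstream modules (census, classifier, metrics) cannot tell the
# two apart.

#' Construct a trajectory object
#'
#' The frame container shared by the simulator and the synthetic fixtures.
#' `filaments` holds one row per vertex per frame; `motors` one row per bound
#' motor per frame, with `fil_a`/`fil_b` = -1 (or `NA`) for an unbound head.
#'
#' @param filaments tibble with columns `frame`, `time`, `fil_id`, `state`,
#'   `length`, `birth`, `vertex`, `x`, `y`, `z` (and optionally `nuc_id`)
#' @param motors tibble with columns `frame`, `time`, `motor_id`, `fil_a`,
#'   `abs_a`, `end_a`, `fil_b`, `abs_b`, `end_b`
#' @param box list with `Lx`, `Ly`, `Lz`
#' @param config optional `mt_config` that produced the trajectory
#' @param log optional run log (event counters)
#' @return an object of class `mt_trajectory`
#' @export
mt_trajectory <- function(filaments, motors, box, config = NULL, log = NULL) {
  filaments <- tibble::as_tibble(filaments)
  motors <- tibble::as_tibble(motors)
  need_f <- c("frame", "time", "fil_id", "state", "length", "vertex", "x", "y", "z")
  miss <- setdiff(need_f, names(filaments))
  if (length(miss) > 0)
    abort(paste0("filament table lacks column(s): ", paste(miss, collapse = ", ")))
  need_m <- c("frame", "motor_id", "fil_a", "abs_a", "end_a", "fil_b", "abs_b", "end_b")
  miss <- setdiff(need_m, names(motors))
  if (length(miss) > 0)
    abort(paste0("motor table lacks column(s): ", paste(miss, collapse = ", ")))
  structure(list(filaments = filaments, motors = motors,
                 box = box[c("Lx", "Ly", "Lz")], config = config, log = log),
            class = "mt_trajectory")
}

#' Simulate a microtubule-motor network
#'
#' Runs the Brownian-dynamics engine: overdamped Langevin motion of
#' semiflexible filaments with nucleation, two-state dynamic instability
#' (catastrophe without rescue), soft-core steric repulsion, z-confinement,
#' and two-headed crosslinking motors with linear force-velocity walking and
#' Kramers load-dependent unbinding, in a thin box periodic in x and y.
#'
#' Each step executes, in order: nucleation, dynamic instability, motor
#' attachment, motor walking, motor detachment, Langevin integration. All
#' randomness flows from R's generator, so `run_simulation(cfg, seed)` is
#' exactly reproducible.
#'
#' @param config an [sim_config()]
#' @param seed integer seed; the trajectory is a deterministic function of
#'   `(config, seed)`
#' @return an [mt_trajectory()] with the run log attached
#' @examples
#' cfg <- sim_config(n_nuc = 5, n_mot = 10, t_end = 20, Lx = 5, Ly = 5)
#' traj <- run_simulation(cfg, seed = 1)
#' dplyr::count(traj$filaments, frame)
#' @export
run_simulation <- function(config, seed = 1) {
  stopifnot(inherits(config, "mt_config"))
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  res <- sim_run_cpp(unclass(config))
  log <- c(res$log, wall_clock_s = proc.time()[["elapsed"]] - t0, seed = seed)
  fl <- tibble::as_tibble(res$filaments)
  fl$state <- ifelse(fl$state == 1, "growing", "shrinking")
  mt_trajectory(fl, tibble::as_tibble(res$motors),
                box = config[c("Lx", "Ly", "Lz")], config = config, log = log)
}

#' @export
print.mt_trajectory <- function(x, ...) {
  nf <- length(unique(x$filaments$frame))
  cat(sprintf("<mt_trajectory> %d frames, box %g x %g x %g um\n",
              nf, x$box$Lx, x$box$Ly, x$box$Lz))
  if (nrow(x$filaments) > 0) {
    last <- dplyr::filter(x$filaments, .data$frame == max(.data$frame))
    cat(sprintf("  final frame: %d filaments at t = %g s\n",
                length(unique(last$fil_id)), max(last$time)))
  }
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj an `mt_trajectory`
#' @return tibble with `frame` and `time`
#' @export
frame_times <- function(traj) {
  dplyr::distinct(traj$filaments[c("frame", "time")])
}

#' Extract one frame of a trajectory
#'
#' @param traj an `mt_trajectory`
#' @param frame frame index; defaults to the final frame
#' @return list with `filaments` and `motors` tibbles for that frame and the box
#' @export
get_frame <- function(traj, frame = NULL) {
  if (is.null(frame)) frame <- max(traj$filaments$frame)
  list(filaments = dplyr::filter(traj$filaments, .data$frame == !!frame),
       motors = dplyr::filter(traj$motors, .data$frame == !!frame),
       box = traj$box)
}

# local unit tangent at abscissa s, from the vertex polyline of one filament
# (rows of `verts` ordered by vertex index)
tangent_at_abscissa <- function(verts, s) {
  n <- nrow(verts)
  if (n < 2) return(c(1, 0, 0))
  lrest <- verts$length[1] / (n - 1)
  k <- min(max(floor(s / lrest), 0), n - 2) + 1
  v <- c(verts$x[k + 1] - verts$x[k], verts$y[k + 1] - verts$y[k],
         verts$z[k + 1] - verts$z[k])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}
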