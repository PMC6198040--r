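# Plain-text persistence of trajectories and run manifests. Small runs
# round-trip exactly through CSV; the manifest records everything needed to
# reproduce a run bit-exactly (config, seed, derived stage seeds).

#' Write / read a trajectory as CSV files
#'
#' Writes `filaments.csv`, `motors.csv` and `meta.yaml` (box geometry) into
#' `dir`. Reading the directory back reproduces the in-memory trajectory
#' exactly (up to numeric text round-trip; 15 significant digits are kept).
#'
#' @param traj an [mt_trajectory()]
#' @param dir output directory (created if missing)
#' @return `write_trajectory()` returns `dir` invisibly; `read_trajectory()`
#'   returns an `mt_trajectory`
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "mt_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 15); on.exit(options(old))
  write.csv(as.data.frame(traj$filaments), file.path(dir, "filaments.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(traj$motors), file.path(dir, "motors.csv"),
            row.names = FALSE)
  yaml::write_yaml(traj$box, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  fl <- tibble::as_tibble(read.csv(file.path(dir, "filaments.csv")))
  mot <- tibble::as_tibble(read.csv(file.path(dir, "motors.csv")))
  for (cl in c("end_a", "end_b")) mot[[cl]] <- as.logical(mot[[cl]])
  box <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  mt_trajectory(fl, mot, box = box)
}

#' Run manifest
#'
#' A small record sufficient to reproduce a run: the full resolved
#' configuration, its hash, the seed, and per-stage derived seeds.
#'
#' @param config an `mt_config`
#' @param seed integer master seed
#' @param outputs named character vector of output files (optional)
#' @param log run log (optional)
#' @return list of class `mt_manifest`
#' @export
run_manifest <- function(config, seed, outputs = character(), log = NULL) {
  keep <- config[!vapply(config, is.null, logical(1))]
  keep <- keep[!names(keep) %in% c("nucleator_positions", "init_filaments",
                                   "init_motors")]
  structure(list(config = keep, config_hash = rlang::hash(keep),
                 seed = as.integer(seed),
                 stage_seeds = c(simulate = as.integer(seed)),
                 outputs = outputs, log = log,
                 package_version = as.character(utils::packageVersion("mtnet"))),
            class = "mt_manifest")
}

#' Simulate-census-classify pipeline
#'
#' Runs the full pipeline on one configuration: simulation, crosslink
#' census, network classification, and (when the run is long enough for the
#' lag) the minus-end velocity-polarity correlation. Any stage can equally
#' be run standalone on a stored trajectory or fixture, which share the
#' same frame container.
#'
#' @param config an [sim_config()]
#' @param seed integer seed
#' @param out_dir optional directory; when given, the trajectory, census CSV,
#'   classification CSV and manifest YAML are written there
#' @param vp_delta_t lag for [vp_time_course()], s
#' @return list with `trajectory`, `census`, `classification`, `vp` (or
#'   `NULL`) and `manifest`
#' @export
pipeline_run <- function(config, seed = 1, out_dir = NULL, vp_delta_t = 100) {
  traj <- run_simulation(config, seed)
  cen <- crosslink_census(traj)
  cls <- classify_network(cen, n_mt = config$n_nuc)
  vp <- NULL
  onset <- config$t_end / 2
  if (config$t_end - onset > vp_delta_t + config$frame_interval)
    vp <- vp_time_course(traj, t_start = onset, delta_t = vp_delta_t)
  man <- run_manifest(config, seed, log = traj$log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, file.path(out_dir, "trajectory"))
    write_census_csv(cen, file.path(out_dir, "census.csv"))
    write.csv(as.data.frame(tidy(cls)), file.path(out_dir, "classification.csv"),
              row.names = FALSE)
    yaml::write_yaml(list(config = man$config, config_hash = man$config_hash,
                          seed = man$seed), file.path(out_dir, "manifest.yaml"))
    man$outputs <- c(trajectory = file.path(out_dir, "trajectory"),
                     census = file.path(out_dir, "census.csv"),
                     classification = file.path(out_dir, "classification.csv"))
  }
  list(trajectory = traj, census = cen, classification = cls, vp = vp,
       manifest = man)
}
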