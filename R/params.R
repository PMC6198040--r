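# Configuration: all lengths in micrometres, times in seconds, forces in pN,
# speeds in um/s. One flat validated list drives both the compiled engine and
# the analysis defaults.

mt_defaults <- function() {
  list(
    # box geometry: thin cuboid, periodic in x and y, confined in z
    Lx = 10, Ly = 10, Lz = 0.4, z_stiff = 100,
    # filament dynamic instability (two-state, no rescue)
    vg = 0.03, vs = 0.5, kcat = NULL, target_mean_length = 2.5,
    fg = 1.7, L0 = 0.1, rigidity = 20, seg = 0.5,
    # nucleator pool
    n_nuc = 120, knuc = 1,
    # soft-core steric repulsion
    kappa_s = 50, d0 = 0.1,
    # two-headed crosslinking motors
    n_mot = 276, vm = 0.03, f_stall = 5, kon = 5, rb = 0.05,
    koff = 0.1, kend = 0.05, f_unbind = 2.5, dm = 0.05, kappa_m = 100,
    plus_end_directed = TRUE,
    # integration
    viscosity = 0.05, kT = 0.0042, dt = 0.002,
    t_end = NULL, frame_interval = NULL,
    # optional deterministic initial state (tests, fixtures)
    nucleator_positions = NULL, init_filaments = NULL, init_motors = NULL
  )
}

#' Simulation configuration
#'
#' Builds and validates the full parameter set of a microtubule-motor network
#' simulation. All lengths are in micrometres, times in seconds, forces in pN
#' and speeds in um/s (30 nm/s = 0.03 um/s).
#'
#' The default geometry is a thin 10 x 10 x 0.4 um box, periodic in x and y.
#' By default the catastrophe rate is tied to the growth speed so that
#' filaments reach a target mean length at catastrophe of
#' `target_mean_length` (2.5 um): `kcat = vg / (target_mean_length - L0)`.
#' Passing `kcat` explicitly (and `target_mean_length = NULL`) switches to a
#' fixed catastrophe rate. If `t_end` is `NULL` the run lasts six mean
#' filament lifetimes; if `frame_interval` is `NULL` one hundred frames are
#' emitted.
#'
#' @param ... named parameters overriding the defaults; unknown names are an
#'   error. See `mt_defaults()` for the full list.
#' @return A validated list of class `mt_config`.
#' @examples
#' cfg <- sim_config(n_nuc = 10, n_mot = 20, t_end = 30)
#' cfg$kcat   # tied to vg via the target mean length
#' @export
sim_config <- function(...) {
  over <- list(...)
  defs <- mt_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown) > 0)
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defs, over, keep.null = TRUE)
  # mean-length mode overrides kcat unless an explicit kcat is given
  if (!is.null(cfg$target_mean_length) && is.null(over$kcat)) {
    if (cfg$target_mean_length <= cfg$L0)
      abort("target_mean_length must exceed the nucleation length L0")
    cfg$kcat <- cfg$vg / (cfg$target_mean_length - cfg$L0)
  }
  if (is.null(cfg$kcat)) abort("either kcat or target_mean_length must be set")
  validate_config(cfg)
  if (is.null(cfg$t_end)) cfg$t_end <- 6 * mean_lifetime(cfg)
  if (is.null(cfg$frame_interval)) cfg$frame_interval <- cfg$t_end / 100
  if (cfg$frame_interval < cfg$dt) cfg$frame_interval <- cfg$dt
  structure(cfg, class = "mt_config")
}

#' Expected filament lifetime under the two-state model
#'
#' Mean time from nucleation to disappearance: an exponential growth phase of
#' mean duration `1/kcat` followed by shrinkage of the mean length at
#' catastrophe, `L0 + vg/kcat`, at speed `vs`.
#'
#' @param cfg an `mt_config`
#' @return time in seconds
#' @export
mean_lifetime <- function(cfg) {
  mean_len <- cfg$L0 + cfg$vg / cfg$kcat
  1 / cfg$kcat + mean_len / cfg$vs
}

validate_config <- function(cfg) {
  pos <- c("Lx", "Ly", "Lz", "vg", "vs", "kcat", "fg", "L0", "seg",
           "kappa_s", "d0", "f_stall", "kon", "rb", "koff", "kend",
           "f_unbind", "dm", "kappa_m", "viscosity", "dt", "knuc")
  for (k in pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      abort(paste0("config field `", k, "` must be a single positive number (got ",
                   deparse(cfg[[k]]), ")"))
  }
  nn <- c("z_stiff", "kT", "rigidity", "vm")   # vm = 0: static crosslinkers
  for (k in nn) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      abort(paste0("config field `", k, "` must be a single non-negative number"))
  }
  for (k in c("n_nuc", "n_mot")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      abort(paste0("config field `", k, "` must be a non-negative integer"))
  }
  if (!is.logical(cfg$plus_end_directed) || length(cfg$plus_end_directed) != 1)
    abort("plus_end_directed must be TRUE or FALSE")
  if (!is.null(cfg$t_end) && (!is.numeric(cfg$t_end) || cfg$t_end <= 0))
    abort("t_end must be positive")
  invisible(cfg)
}

#' Preset configurations at desk and full scale
#'
#' `desk_config()` returns the scaled-down 10 x 10 x 0.4 um geometry with
#' counts preserving filaments-per-area and motors-per-filament of the full
#' system at roughly 1/16 of the area. Two named cells reproduce the two
#' reference states: `"nematic"` (growth speed = motor speed = 30 nm/s, dense
#' filaments at a 10% steric volume fraction, 2.3 motors per filament) and
#' `"aster"` (growth speed 5 nm/s = motor speed / 6, sparse filaments,
#' 16 motors per filament).
#' `paper_config()` returns the full-scale 40 x 40 x 0.4 um geometry.
#'
#' @param preset one of `"nematic"`, `"aster"`
#' @param ... overrides forwarded to [sim_config()]
#' @return an `mt_config`
#' @export
desk_config <- function(preset = c("nematic", "aster"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    nematic = list(vg = 0.03, vm = 0.03, n_nuc = 200, n_mot = 460),
    aster   = list(vg = 0.005, vm = 0.03, n_nuc = 40, n_mot = 640))
  do.call(sim_config, modifyList(c(base, list(Lx = 10, Ly = 10, Lz = 0.4)),
                                 list(...)))
}

#' @rdname desk_config
#' @export
paper_config <- function(preset = c("nematic", "aster"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    nematic = list(vg = 0.03, vm = 0.03, n_nuc = 17920, n_mot = 40960),
    aster   = list(vg = 0.005, vm = 0.03, n_nuc = 2560, n_mot = 40960))
  do.call(sim_config, modifyList(c(base, list(Lx = 40, Ly = 40, Lz = 0.4)),
                                 list(...)))
}

#' Per-filament steric effective volume
#'
#' Volume of the soft-core excluded region around one filament: an open
#' cylinder of radius `d0/2` along the filament closed by two hemispherical
#' caps.
#'
#' @param length filament length (um); defaults to the 2.5 um mean length
#' @param d0 steric equilibrium distance (um)
#' @return volume in um^3
#' @examples
#' effective_volume()   # ~0.02 um^3 at defaults
#' @export
effective_volume <- function(length = 2.5, d0 = 0.1) {
  r <- d0 / 2
  pi * r^2 * length + 4 / 3 * pi * r^3
}

#' Read and write configurations
#'
#' Configurations round-trip through a plain YAML key-value file. Unknown
#' keys in the file are rejected with the offending key named.
#'
#' @param path file path
#' @param cfg an `mt_config`
#' @return `read_config()` returns an `mt_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mt_config"))
  keep <- cfg[!vapply(cfg, is.null, logical(1))]
  keep <- keep[!names(keep) %in% c("nucleator_positions", "init_filaments", "init_motors")]
  yaml::write_yaml(keep, path)
  invisible(path)
}

#' @export
print.mt_config <- function(x, ...) {
  cat("<mt_config>\n")
  cat(sprintf("  box %g x %g x %g um (periodic x-y), dt %g ms, t_end %g s\n",
              x$Lx, x$Ly, x$Lz, x$dt * 1000, x$t_end))
  cat(sprintf("  filaments: %d nucleators, vg %g nm/s, mean length %g um\n",
              x$n_nuc, x$vg * 1000, x$L0 + x$vg / x$kcat))
  cat(sprintf("  motors: %d, vm %g nm/s (%s-end directed)\n",
              x$n_mot, x$vm * 1000, if (x$plus_end_directed) "plus" else "minus"))
  invisible(x)
}
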