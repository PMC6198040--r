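# Heavy simulations shared across test files, computed once per session.
.mtnet_run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, cfg, seed) {
  id <- paste0(key, "_", seed)
  if (is.null(.mtnet_run_cache[[id]]))
    .mtnet_run_cache[[id]] <- run_simulation(cfg, seed)
  .mtnet_run_cache[[id]]
}

cached_cell <- function(preset, seed, ...) {
  cached_run(paste0(preset, rlang::hash(list(...))), desk_config(preset, ...), seed)
}

cached_classification <- function(preset, seed, ...) {
  id <- paste0("cls_", preset, rlang::hash(list(...)), "_", seed)
  if (is.null(.mtnet_run_cache[[id]])) {
    traj <- cached_cell(preset, seed, ...)
    .mtnet_run_cache[[id]] <-
      classify_network(crosslink_census(traj), n_mt = traj$config$n_nuc)
  }
  .mtnet_run_cache[[id]]
}

cached_oracle <- function(key, p, t_end, nx = 2500) {
  id <- paste0("orc_", key)
  if (is.null(.mtnet_run_cache[[id]]))
    .mtnet_run_cache[[id]] <- integrate_profile(p, t_end, nx = nx)
  .mtnet_run_cache[[id]]
}
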