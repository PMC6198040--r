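# Phase-space scanning and the control-parameter collapse. A scan runs a
# grid of scaled-down simulations, classifies each, and the collapse score
# quantifies whether scans taken at different filament numbers or speed
# scales agree when plotted in a chosen coordinate pair. The ratio
# coordinates (motors per filament, growth speed over motor speed) collapse
# the phase spaces; raw or difference coordinates do not.

#' Run a grid of simulations and classify each
#'
#' @param grid tibble with columns `vg`, `vm` (um/s), `n_mt` (nucleator
#'   count) and `n_mot` (motor count); one simulation is run per row and
#'   seed
#' @param seeds integer vector of seeds per cell
#' @param scan_id label recorded with every point (used by
#'   [collapse_scan()] to identify which scan a point belongs to)
#' @param ... configuration overrides applied to every cell (box size etc.)
#' @return tibble of scan points: the grid columns, `seed`, `c_max`,
#'   `C_max`, `P`, `label`, `error` (NA unless the run failed) and the
#'   recomputed control coordinates `mot_per_mt` and `vg_over_vm`
#' @export
run_scan <- function(grid, seeds = 1L, scan_id = "scan", ...) {
  need <- c("vg", "vm", "n_mt", "n_mot")
  miss <- setdiff(need, names(grid))
  if (length(miss) > 0)
    abort(paste0("grid lacks column(s): ", paste(miss, collapse = ", ")))
  cells <- tidyr::expand_grid(grid, seed = as.integer(seeds))
  rows <- purrr::pmap(cells, function(vg, vm, n_mt, n_mot, seed, ...) {
    res <- tryCatch({
      cfg <- sim_config(vg = vg, vm = vm, n_nuc = n_mt, n_mot = n_mot, ...)
      cls <- classify_network(crosslink_census(run_simulation(cfg, seed)),
                              n_mt = n_mt)
      tibble::tibble(c_max = cls$c_max, C_max = cls$C_max, P = cls$P,
                     label = cls$label, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(c_max = NA_real_, C_max = NA_integer_, P = NA_real_,
                     label = NA_character_, error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(vg = vg, vm = vm, n_mt = n_mt,
                                    n_mot = n_mot, seed = seed), res)
  }, ...)
  out <- dplyr::bind_rows(rows)
  out$scan_id <- scan_id
  # control coordinates are always recomputed, never stored independently
  dplyr::mutate(out, mot_per_mt = .data$n_mot / .data$n_mt,
                vg_over_vm = .data$vg / .data$vm)
}

scan_coordinates <- function(points, coords) {
  switch(coords,
    ratio = tibble::tibble(u = points$n_mot / points$n_mt,
                           w = points$vg / points$vm),
    difference = tibble::tibble(u = points$n_mot / points$n_mt,
                                w = points$vg - points$vm),
    raw = tibble::tibble(u = points$n_mot, w = points$vg),
    abort("coords must be one of 'ratio', 'difference', 'raw'"))
}

labels_match <- function(label, P, p_tol) {
  if (any(is.na(label))) return(FALSE)
  if (length(unique(label)) > 1) return(FALSE)
  if (label[1] != "graded") return(TRUE)
  max(P) - min(P) <= p_tol
}

#' Collapse score of classified scans
#'
#' Bins scan points by a coordinate pair (rounded to `digits` significant
#' figures) and scores, over the bins where at least two different scans
#' coincide, the fraction of bins whose classifications agree: asters match
#' asters, graded states match when their polarity-sorting values differ by
#' at most `p_tol`. A successful dimensionality reduction gives a higher
#' score for the `"ratio"` coordinates (N_mot/N_mt, vg/vm) than for
#' `"raw"` (N_mot, vg) or `"difference"` (N_mot/N_mt, vg - vm) coordinates.
#'
#' @param points scan-point table from one or more [run_scan()] calls bound
#'   together (distinct `scan_id`s)
#' @param coords `"ratio"`, `"difference"` or `"raw"`
#' @param digits significant figures defining bin coincidence
#' @param p_tol tolerance on P for two graded states to match
#' @return list with `score` (fraction of matching coincident bins, 1 when
#'   only one scan is supplied), `n_bins` (coincident bins) and `table`
#'   (per-bin detail)
#' @export
collapse_scan <- function(points, coords = c("ratio", "difference", "raw"),
                          digits = 2, p_tol = 0.1) {
  coords <- match.arg(coords)
  if (!"scan_id" %in% names(points)) points$scan_id <- "scan"
  if (any(!is.na(points$error))) points <- points[is.na(points$error), ]
  uv <- scan_coordinates(points, coords)
  pts <- dplyr::mutate(points, .u = signif(uv$u, digits), .w = signif(uv$w, digits))
  n_scans <- length(unique(pts$scan_id))
  if (n_scans < 2) {
    return(list(score = 1, n_bins = 0L,
                table = tibble::tibble(u = double(), w = double(),
                                       n_scans = integer(), match = logical())))
  }
  bins <- dplyr::summarise(
    dplyr::group_by(pts, .data$.u, .data$.w),
    n_scans = length(unique(.data$scan_id)),
    match = labels_match(.data$label, .data$P, p_tol),
    .groups = "drop")
  coin <- bins[bins$n_scans >= 2, , drop = FALSE]
  if (nrow(coin) == 0)
    abort("no coincident bins: the scans do not overlap in these coordinates")
  list(score = mean(coin$match), n_bins = nrow(coin),
       table = dplyr::rename(coin, u = ".u", w = ".w"))
}
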