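# Network-state classification from the crosslink census: the aster-strength
# order parameter c_max (largest V-link cluster as a fraction of the filament
# number) and the polarity-sorting parameter P (time-averaged share of
# parallel links among parallel + anti-parallel side-side links).

#' Size of the largest V-link cluster
#'
#' Builds the graph whose nodes are filaments and whose edges are V links
#' (end-end crosslinks) and returns the node count of its largest connected
#' component. Components require at least one V edge, so the result is 0
#' when no V links exist (isolated filaments are not clusters).
#'
#' @param records crosslink record tibble (one frame) as produced by
#'   [crosslink_census()], or an `mt_census` (its final frame is used)
#' @return integer cluster size
#' @export
largest_v_cluster <- function(records) {
  if (inherits(records, "mt_census"))
    records <- records$records[[which.max(records$frame)]]
  if (is.null(records) || nrow(records) == 0 || !"type" %in% names(records))
    return(0L)
  v <- records[records$type == "V", , drop = FALSE]
  if (nrow(v) == 0) return(0L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(v$fil_a), to = as.character(v$fil_b)),
    directed = FALSE)
  as.integer(max(igraph::components(g)$csize))
}

#' Polarity-sorting parameter P
#'
#' `P = Hp_bar / (Hp_bar + Hap_bar)` where `Hp_bar`, `Hap_bar` are the
#' parallel and anti-parallel side-side link counts averaged over the
#' trailing fraction of the simulated time (4% by default). A network of
#' totally mixed polarity has P = 0.5; a totally polarity-sorted network has
#' P = 1. The value is `NA` (flagged, not 0.5) when no side-side links are
#' present in the window.
#'
#' @param census an `mt_census` (or any tibble with `time`, `Hp`, `Hap`)
#' @param final_fraction trailing fraction of simulated time to average over
#' @return P in \[0, 1\], or `NA` when undefined
#' @examples
#' cen <- make_random_census(c(Hp = 50, Hap = 50), n_frames = 10, n_mt = 100)
#' compute_P(cen)   # 0.5
#' @export
compute_P <- function(census, final_fraction = 0.04) {
  if (nrow(census) == 0) abort("census series is empty")
  t1 <- max(census$time)
  t0 <- min(census$time)
  win <- census$time >= t1 - final_fraction * (t1 - t0)
  if (!any(win)) abort("empty trailing window")
  hp <- mean(census$Hp[win])
  hap <- mean(census$Hap[win])
  if (hp + hap == 0) return(NA_real_)
  hp / (hp + hap)
}

#' Classify a network as aster or nematic-gradient
#'
#' Applies the two-parameter classification key: a network whose largest
#' V-link cluster at the final frame contains at least a fraction
#' `c_threshold` (default 0.01) of all filaments is an aster; otherwise the
#' network carries the polarity-sorting value P on the nematic (P = 0.5) to
#' polar (P = 1) gradient. Runs with no side-side links and no aster are
#' labelled `"unclassified"` (sparse).
#'
#' @param census an `mt_census` with `records`
#' @param n_mt total filament number; defaults to the final-frame count
#' @param c_threshold aster threshold on `c_max`
#' @param final_fraction trailing time fraction for the P average
#' @return an object of class `mt_classification` with fields `C_max`,
#'   `c_max`, `P`, `label` (`"aster"`, `"graded"` or `"unclassified"`) and
#'   `n_mt`
#' @export
classify_network <- function(census, n_mt = NULL, c_threshold = 0.01,
                             final_fraction = 0.04) {
  if (nrow(census) == 0) abort("census series is empty")
  fin <- which.max(census$frame)
  if (is.null(n_mt)) n_mt <- census$n_mt[fin]
  if (is.na(n_mt) || n_mt <= 0) abort("n_mt must be a positive count")
  C_max <- if ("records" %in% names(census)) largest_v_cluster(census) else 0L
  c_max <- C_max / n_mt
  P <- compute_P(census, final_fraction)
  label <- if (c_max >= c_threshold) "aster"
           else if (is.na(P)) "unclassified"
           else "graded"
  structure(list(C_max = as.integer(C_max), c_max = c_max, P = P,
                 label = label, n_mt = as.integer(n_mt),
                 c_threshold = c_threshold),
            class = "mt_classification")
}

#' @export
print.mt_classification <- function(x, ...) {
  cat(sprintf("<mt_classification> %s  (c_max = %.4g [C_max = %d / %d], P = %s)\n",
              x$label, x$c_max, x$C_max, x$n_mt,
              if (is.na(x$P)) "NA" else sprintf("%.3f", x$P)))
  invisible(x)
}

#' Tidy a network classification
#' @param x an `mt_classification`
#' @param ... unused
#' @return one-row tibble with `label`, `c_max`, `C_max`, `P`, `n_mt`
#' @export
tidy.mt_classification <- function(x, ...) {
  tibble::tibble(label = x$label, c_max = x$c_max, C_max = x$C_max,
                 P = x$P, n_mt = x$n_mt)
}

#' @rdname tidy.mt_classification
#' @export
glance.mt_classification <- function(x, ...) tidy(x)
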