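# Crosslink census: classify every doubly bound motor into one of five link
# types and aggregate per-frame counts. The taxonomy, with theta the internal
# angle between the plus-end-directed tangents at the two attachment points:
#   V   both heads end-bound (end-end)
#   T   exactly one head end-bound (end-side)
#   Hp  side-side, 0 <= theta < pi/3        (parallel)
#   Hap side-side, 2*pi/3 < theta <= pi     (anti-parallel)
#   X   side-side, pi/3 <= theta <= 2*pi/3  (crossing; boundaries closed)
# End-bound status takes precedence: the angle never reclassifies a link that
# involves a plus end.

link_types <- c("V", "T", "Hp", "Hap", "X")

#' Classify a motor crosslink
#'
#' @param end_a,end_b logical, is the head bound at the filament plus end
#' @param theta internal angle between the plus-end-directed tangents at the
#'   two attachment points, radians in \[0, pi\]
#' @param fil_a,fil_b optional filament ids; identical ids are rejected (a
#'   motor bridging one filament to itself is not a crosslink)
#' @return character vector over `c("V","T","Hp","Hap","X")` (vectorised)
#' @examples
#' classify_crosslink(TRUE, TRUE, pi / 2)    # "V"
#' classify_crosslink(FALSE, FALSE, pi)      # "Hap"
#' classify_crosslink(FALSE, FALSE, pi / 3)  # "X" (closed boundary)
#' @export
classify_crosslink <- function(end_a, end_b, theta, fil_a = NULL, fil_b = NULL) {
  if (!is.null(fil_a) && !is.null(fil_b) && any(fil_a == fil_b))
    abort("both heads are bound to the same filament; not a crosslink")
  if (any(theta < -1e-9 | theta > pi + 1e-9))
    abort("theta must lie in [0, pi]")
  n_end <- end_a + end_b
  out <- character(length(theta))
  out[n_end == 2] <- "V"
  out[n_end == 1] <- "T"
  side <- n_end == 0
  out[side & theta < pi / 3] <- "Hp"
  out[side & theta > 2 * pi / 3] <- "Hap"
  out[side & theta >= pi / 3 & theta <= 2 * pi / 3] <- "X"
  out
}

# per-frame crosslink records with tangent angles, vectorised across frames
crosslink_records_all <- function(traj) {
  mot <- traj$motors
  unb <- function(f) is.na(f) | f < 0
  dbl <- mot[!unb(mot$fil_a) & !unb(mot$fil_b), , drop = FALSE]
  if (nrow(dbl) == 0) {
    return(tibble::tibble(frame = integer(), motor_id = integer(),
                          fil_a = integer(), fil_b = integer(),
                          abs_a = double(), abs_b = double(),
                          end_a = logical(), end_b = logical(),
                          theta = double(), type = character()))
  }
  if (any(dbl$fil_a == dbl$fil_b)) {
    bad <- dbl$motor_id[dbl$fil_a == dbl$fil_b][1]
    abort(paste0("motor ", bad, " is doubly bound to a single filament"))
  }
  fl <- traj$filaments
  fl <- dplyr::arrange(fl, .data$frame, .data$fil_id, .data$vertex)
  fkey <- paste(fl$frame, fl$fil_id)
  info <- dplyr::summarise(dplyr::group_by(fl, .data$frame, .data$fil_id),
                           nv = dplyr::n(), length = .data$length[1],
                           .groups = "drop")
  ikey <- paste(info$frame, info$fil_id)

  head_tangent <- function(fil, abs, motor_id) {
    hk <- paste(dbl$frame, fil)
    idx <- match(hk, ikey)
    if (anyNA(idx)) {
      bad <- motor_id[is.na(idx)][1]
      abort(paste0("motor ", bad, " references a filament absent from its frame"))
    }
    nv <- info$nv[idx]
    len <- info$length[idx]
    lrest <- len / pmax(nv - 1, 1)
    k <- pmin(pmax(floor(abs / lrest), 0), nv - 2)
    k[nv < 2] <- 0
    vkey <- paste(fl$frame, fl$fil_id, fl$vertex)
    i0 <- match(paste(dbl$frame, fil, k), vkey)
    i1 <- match(paste(dbl$frame, fil, k + 1), vkey)
    tx <- fl$x[i1] - fl$x[i0]; ty <- fl$y[i1] - fl$y[i0]; tz <- fl$z[i1] - fl$z[i0]
    nn <- sqrt(tx^2 + ty^2 + tz^2)
    nn[nn < 1e-12 | is.na(nn)] <- 1
    cbind(tx / nn, ty / nn, tz / nn)
  }
  ta <- head_tangent(dbl$fil_a, dbl$abs_a, dbl$motor_id)
  tb <- head_tangent(dbl$fil_b, dbl$abs_b, dbl$motor_id)
  ct <- pmin(pmax(rowSums(ta * tb), -1), 1)
  theta <- acos(ct)
  tibble::tibble(frame = dbl$frame, motor_id = dbl$motor_id,
                 fil_a = dbl$fil_a, fil_b = dbl$fil_b,
                 abs_a = dbl$abs_a, abs_b = dbl$abs_b,
                 end_a = as.logical(dbl$end_a), end_b = as.logical(dbl$end_b),
                 theta = theta,
                 type = classify_crosslink(as.logical(dbl$end_a),
                                           as.logical(dbl$end_b), theta))
}

#' Crosslink census of a trajectory
#'
#' Classifies every doubly bound motor in every frame and aggregates the
#' per-frame counts of the five link types. The census is a partition: each
#' doubly bound motor contributes to exactly one count.
#'
#' @param traj an [mt_trajectory()] (simulated or a fixture)
#' @return a tibble of class `mt_census`, one row per frame with columns
#'   `frame`, `time`, `V`, `T`, `Hp`, `Hap`, `X`, `n_mt`, `n_links` and a
#'   list-column `records` of the per-motor [classify_crosslink()] records
#' @examples
#' frame <- make_ideal_aster(20, 30, seed = 1)
#' crosslink_census(frame)
#' @export
crosslink_census <- function(traj) {
  stopifnot(inherits(traj, "mt_trajectory"))
  ft <- frame_times(traj)
  n_mt <- dplyr::count(dplyr::distinct(traj$filaments[c("frame", "fil_id")]),
                       .data$frame, name = "n_mt")
  rec <- crosslink_records_all(traj)
  counts <- tidyr::pivot_wider(
    dplyr::count(rec, .data$frame, .data$type),
    names_from = "type", values_from = "n", values_fill = 0L)
  for (tp in link_types) if (!tp %in% names(counts)) counts[[tp]] <- 0L
  out <- dplyr::left_join(ft, counts, by = "frame")
  out <- dplyr::left_join(out, n_mt, by = "frame")
  for (tp in link_types) out[[tp]][is.na(out[[tp]])] <- 0L
  out$n_mt[is.na(out$n_mt)] <- 0L
  out$n_links <- out$V + out$T + out$Hp + out$Hap + out$X
  recs <- split(rec, factor(rec$frame, levels = out$frame))
  out$records <- unname(recs)
  out <- out[c("frame", "time", link_types, "n_mt", "n_links", "records")]
  class(out) <- c("mt_census", class(out))
  out
}

#' Write / read a census as CSV (one row per frame; records dropped)
#' @param census an `mt_census`
#' @param path file path
#' @return `read_census_csv()` returns a census tibble without records;
#'   `write_census_csv()` returns `path` invisibly
#' @export
write_census_csv <- function(census, path) {
  write.csv(as.data.frame(census[setdiff(names(census), "records")]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  out <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  class(out) <- c("mt_census", class(out))
  out
}
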