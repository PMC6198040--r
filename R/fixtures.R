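# Synthetic-geometry and synthetic-census generators. Fixtures share the
# trajectory/frame container of the simulator, so census, classifier and
# metric code cannot distinguish a fixture from a simulation. At zero noise
# each fixture satisfies its defining property exactly.

fixture_filament_rows <- function(minus, plus, ids, n_seg = 5, time = 0,
                                  frame = 0) {
  n <- nrow(minus)
  purrr::map_dfr(seq_len(n), function(i) {
    len <- sqrt(sum((plus[i, ] - minus[i, ])^2))
    w <- seq(0, 1, length.out = n_seg + 1)
    tibble::tibble(frame = frame, time = time, fil_id = ids[i],
                   state = "growing", length = len, birth = 0,
                   vertex = seq_len(n_seg + 1) - 1L,
                   x = minus[i, 1] + w * (plus[i, 1] - minus[i, 1]),
                   y = minus[i, 2] + w * (plus[i, 2] - minus[i, 2]),
                   z = minus[i, 3] + w * (plus[i, 3] - minus[i, 3]))
  })
}

#' Ideal aster fixture
#'
#' `n_filaments` filaments with their plus ends coincident at a common focus
#' and minus ends pointing radially outward; motors crosslink consecutive
#' plus ends with both heads end-bound, so the census is V-dominated and the
#' classifier labels the frame an aster. With `n_motors >= n_filaments - 1`
#' all filaments join one V cluster and `c_max = 1`.
#'
#' @param n_filaments number of filaments (>= 2)
#' @param n_motors number of end-end motors
#' @param seed integer seed
#' @param radius aster radius (filament length), um
#' @param angle_noise sd of angular jitter on the spoke directions, rad
#' @return an [mt_trajectory()] with a single frame
#' @export
make_ideal_aster <- function(n_filaments, n_motors, seed = 1, radius = 2.5,
                             angle_noise = 0) {
  stopifnot(n_filaments >= 2, n_motors >= 0)
  set.seed(seed)
  L <- radius + 1
  centre <- c(L, L, 0)
  ang <- 2 * pi * (seq_len(n_filaments) - 1) / n_filaments +
    stats::rnorm(n_filaments, 0, angle_noise)
  minus <- cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang), 0)
  plus <- matrix(rep(centre, each = n_filaments), ncol = 3)
  fl <- fixture_filament_rows(minus, plus, seq_len(n_filaments) - 1L)
  if (n_motors > 0) {
    fa <- (seq_len(n_motors) - 1L) %% n_filaments
    fb <- seq_len(n_motors) %% n_filaments
    mot <- tibble::tibble(frame = 0L, time = 0, motor_id = seq_len(n_motors) - 1L,
                          fil_a = fa, abs_a = radius, end_a = TRUE,
                          fil_b = fb, abs_b = radius, end_b = TRUE)
  } else {
    mot <- tibble::tibble(frame = integer(), time = double(), motor_id = integer(),
                          fil_a = integer(), abs_a = double(), end_a = logical(),
                          fil_b = integer(), abs_b = double(), end_b = logical())
  }
  mt_trajectory(fl, mot, box = list(Lx = 2 * L, Ly = 2 * L, Lz = 0.4))
}

#' Ideal mixed-polarity nematic fixture
#'
#' Aligned filaments along the x axis, an exact fraction
#' `polarity_fraction` of them pointing +x, crosslinked side-to-side by
#' motors on uniformly random distinct filament pairs. Under this random
#' pairing the expected polarity-sorting parameter is
#' `(C(k,2) + C(n-k,2)) / C(n,2)` with `k` the number of +x filaments,
#' which tends to `f^2 + (1-f)^2` for large `n`.
#'
#' @param n_filaments number of filaments
#' @param polarity_fraction fraction pointing +x, in \[0, 1\]
#' @param n_motors number of side-side motors
#' @param seed integer seed
#' @param length filament length, um
#' @param box_l box edge, um
#' @return an [mt_trajectory()] with a single frame
#' @export
make_ideal_nematic <- function(n_filaments, polarity_fraction = 0.5,
                               n_motors = 100, seed = 1, length = 2.5,
                               box_l = 10) {
  stopifnot(n_filaments >= 2, polarity_fraction >= 0, polarity_fraction <= 1)
  set.seed(seed)
  k <- round(polarity_fraction * n_filaments)
  dir <- c(rep(1, k), rep(-1, n_filaments - k))
  x0 <- runif(n_filaments, 0, box_l - length)
  y0 <- runif(n_filaments, 0, box_l)
  minus <- cbind(ifelse(dir > 0, x0, x0 + length), y0, 0)
  plus <- cbind(ifelse(dir > 0, x0 + length, x0), y0, 0)
  fl <- fixture_filament_rows(minus, plus, seq_len(n_filaments) - 1L)
  pair <- function() sample(n_filaments, 2) - 1L
  pairs <- t(replicate(n_motors, pair()))
  mot <- tibble::tibble(frame = 0L, time = 0, motor_id = seq_len(n_motors) - 1L,
                        fil_a = pairs[, 1], abs_a = length / 2, end_a = FALSE,
                        fil_b = pairs[, 2], abs_b = length / 2, end_b = FALSE)
  mt_trajectory(fl, mot, box = list(Lx = box_l, Ly = box_l, Lz = 0.4))
}

#' Random crosslink geometry fixture
#'
#' Straight filaments at uniformly random in-plane orientations and
#' positions, with motors doubly bound to random distinct filament pairs at
#' random abscissas; each head is end-bound with probability `p_end`. Used
#' to exercise the census against brute-force classification.
#'
#' @param n_filaments,n_motors counts
#' @param seed integer seed
#' @param p_end probability that a head sits at the plus end
#' @param length filament length, um
#' @param box_l box edge, um
#' @return an [mt_trajectory()] with a single frame
#' @export
make_random_frame <- function(n_filaments, n_motors, seed = 1, p_end = 0.2,
                              length = 2.5, box_l = 10) {
  set.seed(seed)
  ang <- runif(n_filaments, 0, 2 * pi)
  x0 <- runif(n_filaments, 0, box_l)
  y0 <- runif(n_filaments, 0, box_l)
  minus <- cbind(x0, y0, 0)
  plus <- cbind(x0 + length * cos(ang), y0 + length * sin(ang), 0)
  fl <- fixture_filament_rows(minus, plus, seq_len(n_filaments) - 1L)
  pairs <- t(replicate(n_motors, sample(n_filaments, 2) - 1L))
  ea <- runif(n_motors) < p_end
  eb <- runif(n_motors) < p_end
  mot <- tibble::tibble(frame = 0L, time = 0, motor_id = seq_len(n_motors) - 1L,
                        fil_a = pairs[, 1],
                        abs_a = ifelse(ea, length, runif(n_motors, 0, 0.95 * length)),
                        end_a = ea,
                        fil_b = pairs[, 2],
                        abs_b = ifelse(eb, length, runif(n_motors, 0, 0.95 * length)),
                        end_b = eb)
  mt_trajectory(fl, mot, box = list(Lx = box_l, Ly = box_l, Lz = 0.4))
}

#' Synthetic census series with prescribed counts
#'
#' Builds an `mt_census` with exactly the requested per-frame counts,
#' bypassing geometry, for direct classifier testing. V links are placed on
#' distinct random filament pairs (or on `v_pairs` if given), so the V-link
#' cluster structure is well defined.
#'
#' @param counts named vector with any of `V`, `T`, `Hp`, `Hap`, `X`
#' @param n_frames number of frames (times 0, 1, ... seconds)
#' @param n_mt filament number reported per frame
#' @param seed integer seed
#' @param v_pairs optional two-column matrix of filament ids for the V links
#' @return an `mt_census` tibble
#' @examples
#' make_random_census(c(Hp = 3, Hap = 1), n_frames = 5, n_mt = 50)
#' @export
make_random_census <- function(counts, n_frames = 10, n_mt = 200, seed = 1,
                               v_pairs = NULL) {
  set.seed(seed)
  cn <- setNames(rep(0L, 5), link_types)
  bad <- setdiff(names(counts), link_types)
  if (length(bad) > 0)
    abort(paste0("unknown link type(s): ", paste(bad, collapse = ", ")))
  cn[names(counts)] <- as.integer(counts)
  if (any(cn < 0)) abort("counts must be non-negative")
  nV <- cn[["V"]]
  if (is.null(v_pairs) && nV > 0) {
    v_pairs <- t(replicate(nV, sample(n_mt, 2) - 1L))
  }
  theta_for <- function(type, n) {
    switch(type,
      V = runif(n, 0, pi), T = runif(n, 0, pi),
      Hp = runif(n, 0, pi / 3 - 1e-6),
      Hap = runif(n, 2 * pi / 3 + 1e-6, pi),
      X = runif(n, pi / 3, 2 * pi / 3))
  }
  empty_rec <- tibble::tibble(frame = integer(), motor_id = integer(),
                              fil_a = integer(), fil_b = integer(),
                              abs_a = double(), abs_b = double(),
                              end_a = logical(), end_b = logical(),
                              theta = double(), type = character())
  one_frame <- function(fr) {
    recs <- purrr::map_dfr(link_types, function(tp) {
      n <- cn[[tp]]
      if (n == 0) return(NULL)
      if (tp == "V") {
        fa <- v_pairs[, 1]; fb <- v_pairs[, 2]
      } else {
        pr <- t(replicate(n, sample(n_mt, 2) - 1L))
        fa <- pr[, 1]; fb <- pr[, 2]
      }
      tibble::tibble(frame = fr, motor_id = seq_len(n) - 1L,
                     fil_a = fa, fil_b = fb, abs_a = 1, abs_b = 1,
                     end_a = tp == "V", end_b = tp %in% c("V", "T"),
                     theta = theta_for(tp, n), type = tp)
    })
    if (nrow(recs) == 0) empty_rec else recs
  }
  frames <- seq_len(n_frames) - 1L
  out <- tibble::tibble(frame = frames, time = as.double(frames))
  for (tp in link_types) out[[tp]] <- cn[[tp]]
  out$n_mt <- as.integer(n_mt)
  out$n_links <- sum(cn)
  out$records <- purrr::map(frames, one_frame)
  class(out) <- c("mt_census", class(out))
  out
}
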