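# Independent brute-force oracles, deliberately written as plain loops with
# no shared code with the package internals.

brute_classify_one <- function(end_a, end_b, theta) {
  if (end_a && end_b) return("V")
  if (end_a || end_b) return("T")
  if (theta < pi / 3) return("Hp")
  if (theta > 2 * pi / 3) return("Hap")
  "X"
}

# classify every doubly bound motor of a single-frame trajectory by direct
# per-motor geometry
brute_census <- function(traj) {
  fl <- as.data.frame(traj$filaments)
  mot <- as.data.frame(traj$motors)
  out <- character(0)
  for (i in seq_len(nrow(mot))) {
    fa <- mot$fil_a[i]; fb <- mot$fil_b[i]
    if (is.na(fa) || is.na(fb) || fa < 0 || fb < 0) next
    tangent <- function(fid, s) {
      v <- fl[fl$fil_id == fid & fl$frame == mot$frame[i], ]
      v <- v[order(v$vertex), ]
      lr <- v$length[1] / (nrow(v) - 1)
      k <- min(max(floor(s / lr), 0), nrow(v) - 2) + 1
      d <- c(v$x[k + 1] - v$x[k], v$y[k + 1] - v$y[k], v$z[k + 1] - v$z[k])
      d / sqrt(sum(d^2))
    }
    ta <- tangent(fa, mot$abs_a[i])
    tb <- tangent(fb, mot$abs_b[i])
    th <- acos(min(max(sum(ta * tb), -1), 1))
    out <- c(out, brute_classify_one(mot$end_a[i], mot$end_b[i], th))
  }
  table(factor(out, levels = c("V", "T", "Hp", "Hap", "X")))
}

# largest connected component over V edges by flood fill
brute_v_cluster <- function(records) {
  v <- records[records$type == "V", , drop = FALSE]
  if (nrow(v) == 0) return(0L)
  nodes <- unique(c(v$fil_a, v$fil_b))
  best <- 0L
  unvisited <- nodes
  while (length(unvisited) > 0) {
    frontier <- unvisited[1]
    comp <- frontier
    unvisited <- unvisited[-1]
    while (length(frontier) > 0) {
      nb <- unique(c(v$fil_b[v$fil_a %in% frontier], v$fil_a[v$fil_b %in% frontier]))
      frontier <- intersect(nb, unvisited)
      comp <- c(comp, frontier)
      unvisited <- setdiff(unvisited, frontier)
    }
    best <- max(best, length(comp))
  }
  best
}
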