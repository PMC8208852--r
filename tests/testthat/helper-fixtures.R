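# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately implemented by a different route than the
# package code they check (dot products instead of the law of cosines,
# explicit queue search instead of synchronous dilation, triple loops
# instead of vectorized shifts).

# ---- fixtures ---------------------------------------------------------

# straight line of n voxels along axis 1
fix_line <- function(n = 7, pad = 2) {
  v <- array(0L, c(n + 2 * pad, 5, 5))
  v[(pad + 1):(pad + n), 3, 3] <- 1L
  v
}

# three straight arms meeting at one central voxel (a "Y")
fix_y <- function(arm = 5) {
  v <- array(0L, c(21, 21, 5))
  c0 <- c(11, 11, 3)
  v[c0[1], c0[2], c0[3]] <- 1L
  for (s in seq_len(arm)) {
    v[c0[1] + s, c0[2], c0[3]] <- 1L
    v[c0[1] - s, c0[2] + s, c0[3]] <- 1L
    v[c0[1] - s, c0[2] - s, c0[3]] <- 1L
  }
  v
}

# four diagonal arms crossing at one voxel (an "X", the smallest adhesion)
fix_x <- function(arm = 5) {
  v <- array(0L, c(21, 21, 5))
  c0 <- c(11, 11, 3)
  v[c0[1], c0[2], c0[3]] <- 1L
  for (s in seq_len(arm)) {
    v[c0[1] + s, c0[2] + s, c0[3]] <- 1L
    v[c0[1] - s, c0[2] - s, c0[3]] <- 1L
    v[c0[1] + s, c0[2] - s, c0[3]] <- 1L
    v[c0[1] - s, c0[2] + s, c0[3]] <- 1L
  }
  v
}

# a star of arms with given unit directions rasterized from one center
fix_star <- function(dirs, len = 10, size = 41) {
  v <- array(0L, rep(size, 3))
  c0 <- rep((size + 1) / 2, 3)
  for (r in seq_len(nrow(dirs))) {
    seg <- avsep:::bresenham3(c0, c0 + dirs[r, ] * len)
    v[seg] <- 1L
  }
  v
}

# random unit directions with pairwise angle >= min_sep (degrees)
rand_dirs <- function(k, min_sep = 30) {
  repeat {
    m <- matrix(stats::rnorm(3 * k), k, 3)
    m <- m / sqrt(rowSums(m^2))
    cc <- tcrossprod(m)
    cc[cc > 1] <- 1; cc[cc < -1] <- -1
    ang <- acos(cc) * 180 / pi
    diag(ang) <- 180
    if (min(ang) >= min_sep) return(m)
  }
}

small_phantom <- function(seed, ...) {
  vascular_phantom(seed = seed, depth = 3, shape = c(96L, 96L, 96L),
                   n_adhesions = 3, n_satellites = 1, ...)
}

# ---- oracles ----------------------------------------------------------

# angle at P via unit-vector dot product (independent of law of cosines)
oracle_angle <- function(P, A, B) {
  u <- (A - P) / sqrt(sum((A - P)^2))
  v <- (B - P) / sqrt(sum((B - P)^2))
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

# exhaustive 3-pairing enumeration for four branches; reps is a list of
# 4 representative coordinates, ids the corresponding link ids
oracle_pairing4 <- function(P, reps, ids) {
  combos <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                 list(c(1, 4), c(2, 3)))
  scores <- vapply(combos, function(cb) {
    oracle_angle(P, reps[[cb[[1]][1]]], reps[[cb[[1]][2]]]) +
      oracle_angle(P, reps[[cb[[2]][1]]], reps[[cb[[2]][2]]])
  }, numeric(1))
  best <- combos[[which.max(scores)]]
  list(pairs = lapply(best, function(cb) sort(ids[cb])),
       score = max(scores), gap = max(scores) - sort(scores, decreasing = TRUE)[2])
}

# queue-based multi-source geodesic BFS on one slice (8-connectivity,
# within the mask); returns the per-voxel label matrix
oracle_slice_growth <- function(m, seeds) {
  nr <- nrow(m); nc <- ncol(m)
  dist_from <- function(lab) {
    d <- matrix(Inf, nr, nc)
    q <- which(seeds == lab, arr.ind = TRUE)
    if (nrow(q) == 0) return(d)
    d[q] <- 0
    head <- 1
    q <- as.list(asplit(q, 1))
    while (head <= length(q)) {
      v <- q[[head]]; head <- head + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        i <- v[1] + di; j <- v[2] + dj
        if (i < 1 || j < 1 || i > nr || j > nc) next
        if (!m[i, j]) next
        if (d[i, j] > d[v[1], v[2]] + 1) {
          d[i, j] <- d[v[1], v[2]] + 1
          q[[length(q) + 1]] <- c(i, j)
        }
      }
    }
    d
  }
  d1 <- dist_from(1L); d2 <- dist_from(2L)
  out <- matrix(0L, nr, nc)
  out[is.finite(d1) & (d1 <= d2)] <- 1L
  out[is.finite(d2) & (d2 < d1)] <- 2L
  out
}

# brute-force element counts for small skeletons: triple-loop degrees,
# flood-fill components of junction voxels and of path chains
oracle_graph_counts <- function(v) {
  dims <- dim(v)
  deg <- array(0L, dims)
  fg <- which(v > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ]
    cnt <- 0L
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      q <- p + c(di, dj, dk)
      if (any(q < 1) || any(q > dims)) next
      if (v[q[1], q[2], q[3]] > 0) cnt <- cnt + 1L
    }
    deg[p[1], p[2], p[3]] <- cnt
  }
  flood_count <- function(sel) {
    seen <- array(FALSE, dims)
    n <- 0L
    pts <- which(sel, arr.ind = TRUE)
    for (r in seq_len(nrow(pts))) {
      p <- pts[r, ]
      if (seen[p[1], p[2], p[3]]) next
      n <- n + 1L
      stack <- list(p)
      seen[p[1], p[2], p[3]] <- TRUE
      while (length(stack)) {
        q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          w <- q + c(di, dj, dk)
          if (any(w < 1) || any(w > dims)) next
          if (!sel[w[1], w[2], w[3]] || seen[w[1], w[2], w[3]]) next
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    n
  }
  list(
    n_junction_clusters = flood_count(v > 0 & deg >= 3),
    n_leaves = sum(deg == 1 & v > 0),
    n_path_components = flood_count(v > 0 & deg > 0 & deg <= 2)
  )
}
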