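#' Parameters of the synthetic vascular phantom
#'
#' The phantom emulates the geometry the separation pipeline faces in
#' clinical CT at desk scale: two interdigitated bifurcating tubular trees
#' (arterial and venous), the venous tree bulkier, with a controlled number
#' of planted artery-vein adhesion crossings and detached satellite
#' fragments, plus per-voxel ground-truth labels.
#'
#' Both trees grow along the axial (slice) axis so that every occupied
#' slice of every tube contains a skeleton seed. The venous tree replays
#' the arterial tree's branching draws with a small angular jitter and is
#' translated laterally by `interdigitation_offset`, so each arterial leaf
#' tip has a venous counterpart within the peripheral-matching radius.
#' Adhesions are planted as short venous twigs that cross one arterial
#' centerline voxel transversally, guaranteeing exactly `n_adhesions`
#' degree-4 crossings.
#'
#' @param depth Branching generations (leaves per tree = `2^depth`).
#' @param shape Grid dimensions (voxels).
#' @param spacing Voxel size (mm).
#' @param root_radius Arterial root radius (voxels).
#' @param taper Radius multiplier per generation.
#' @param min_radius Radius floor (voxels).
#' @param branch_length Root branch length range (voxels).
#' @param length_decay Length multiplier per generation.
#' @param branch_angle Bifurcation half-angle range (degrees), drawn per
#'   split; deeper generations use internally scaled-down angles along the
#'   interdigitation direction so the trees interleave without touching.
#' @param volume_scale Target venous/arterial volume ratio (> 1); venous
#'   radii are scaled by `sqrt(volume_scale)`.
#' @param interdigitation_offset Translation of the venous tree (voxels).
#'   Its component along the internal lane axis (the x = y diagonal) sets
#'   the interleaving spacing; its component along the orthogonal fan axis
#'   separates the lane-transition segments of the two trees.
#' @param jitter_deg Angular jitter of the venous replay (degrees).
#' @param n_adhesions Planted adhesion count; `NULL` draws from 4:8.
#' @param n_satellites Detached satellite fragments (alternating classes).
#' @param seed Random stream seed (all draws derive from it).
#' @return A `tree_params` list.
#' @export
phantom_params <- function(depth = 4L, shape = c(128L, 128L, 128L),
                           spacing = c(1, 1, 1), root_radius = 2.5,
                           taper = 0.72, min_radius = 0.6,
                           branch_length = c(18, 24), length_decay = 0.88,
                           branch_angle = c(25, 35), volume_scale = 1.5,
                           interdigitation_offset = c(2, 8, 0),
                           jitter_deg = 1.5, n_adhesions = NULL,
                           n_satellites = 2L, seed = 1L) {
  if (depth < 1L) abort("`depth` must be >= 1")
  if (root_radius <= 0 || min_radius <= 0) abort("radii must be > 0")
  if (volume_scale <= 1) abort("`volume_scale` must be > 1 (venous dominance)")
  structure(list(
    depth = as.integer(depth), shape = as.integer(shape),
    spacing = as.numeric(spacing), root_radius = root_radius, taper = taper,
    min_radius = min_radius, branch_length = branch_length,
    length_decay = length_decay, branch_angle = branch_angle,
    volume_scale = volume_scale,
    interdigitation_offset = as.numeric(interdigitation_offset),
    jitter_deg = jitter_deg, n_adhesions = n_adhesions,
    n_satellites = as.integer(n_satellites), seed = as.integer(seed)
  ), class = "tree_params")
}

# 3-D Bresenham-style rasterization of the segment a -> b (26-connected).
bresenham3 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- max(abs(round(b) - round(a)), 1)
  t <- seq(0, 1, length.out = n + 1L)
  pts <- round(outer(1 - t, a) + outer(t, b))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  storage.mode(pts) <- "integer"
  pts
}

seg_dist <- function(p1, q1, p2, q2) {
  # minimum distance between segments [p1,q1] and [p2,q2]
  u <- q1 - p1; v <- q2 - p2; w <- p1 - p2
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c - b * b
  if (D < 1e-9) { sc <- 0 } else sc <- min(1, max(0, (b * e - c * d) / D))
  tc <- if (c < 1e-9) 0 else min(1, max(0, (b * sc + e) / c))
  sc <- if (a < 1e-9) 0 else min(1, max(0, (b * tc - d) / a))
  sqrt(sum((w + sc * u - tc * v)^2))
}

# One attempt at a full phantom geometry; returns NULL on a constraint
# violation that a reseed can fix, aborts on a hard grid violation.
phantom_geometry_attempt <- function(params, verbose = FALSE) {
  depth <- params$depth
  n_branch <- 2L^(depth + 1L) - 1L
  gen_of <- floor(log2(seq_len(n_branch)))

  # all random draws up front, in a fixed order
  n_adh <- params$n_adhesions %||% sample(4:8, 1L)
  len_base <- runif(n_branch, params$branch_length[1], params$branch_length[2])
  theta <- matrix(runif(2L * n_branch, params$branch_angle[1],
                        params$branch_angle[2]), n_branch, 2L)
  vein_dlen <- runif(n_branch, -0.02, 0.02)
  vein_dtheta <- matrix(runif(2L * n_branch, -params$jitter_deg,
                              params$jitter_deg), n_branch, 2L)
  slot_shuffle <- runif(512L)

  off <- params$interdigitation_offset
  ctr <- params$shape[1:2] / 2
  root_a <- c(ctr[1] - off[1] / 2, ctr[2] - off[2] / 2, 10)
  root_v <- root_a + off
  rad_factor <- c(artery = 1, vein = sqrt(params$volume_scale))

  # Lane layout. The venous tree replays the arterial draws translated by
  # `interdigitation_offset`. Internally two fixed lateral axes are used:
  # the lane axis `e_lane` and the orthogonal fan axis `e_fan`. The
  # generation-2 split moves each subtree into a lane along `e_lane`
  # (arterial lanes at +/-s; with the offset's lane component ~ s, venous
  # lanes fall at 0 and 2s, interleaved). Every other generation splits
  # along `e_fan`, which never closes the inter-tree lane gap; deep fan
  # splits are scaled down so same-lane cousin groups stay separated. The
  # offset's fan component keeps the gen-2 transition segments of the two
  # trees — the only place opposite-slope lane changes cross in the
  # lane-z plane — laterally apart.
  e_lane <- normalize(c(1, 1, 0))
  e_fan <- normalize(c(-1, 1, 0))
  split_axis <- function(g) if (g == 1L) e_lane else e_fan
  split_scale <- function(g) {
    if (g <= 1L) 1.0 else if (g == 2L) 0.6 else 0.45
  }

  build_tree <- function(tree) {
    rows <- vector("list", n_branch)
    start <- if (tree == "artery") root_a else root_v
    dir0 <- c(0, 0, 1)
    recurse <- function(b, start, dir) {
      g <- gen_of[b]
      len <- len_base[b] * params$length_decay^g
      if (tree == "vein") len <- len * (1 + vein_dlen[b])
      radius <- max(params$root_radius * params$taper^g, params$min_radius) *
        rad_factor[[tree]]
      end <- start + dir * len
      rows[[b]] <<- list(tree = tree, heap = b, gen = g, start = start,
                         end = end, dir = dir, len = len, radius = radius)
      if (g < depth) {
        ax <- split_axis(g)
        if (abs(sum(ax * dir)) > 0.99) ax <- c(0, 0, 1)
        u <- normalize(ax - sum(ax * dir) * dir)
        for (side in 1:2) {
          th <- theta[b, side] * split_scale(g)
          if (tree == "vein") th <- th + vein_dtheta[b, side]
          th <- th * pi / 180
          cd <- normalize(cos(th) * dir + sin(th) * (if (side == 1) u else -u))
          recurse(2L * b + (side - 1L), end, cd)
        }
      }
    }
    recurse(1L, start, dir0)
    rows
  }

  arteries <- build_tree("artery")
  veins <- build_tree("vein")
  all_br <- c(arteries, veins)

  # grid fit (margin = radius + 2 voxels)
  for (br in all_br) {
    m <- br$radius + 2
    if (any(br$start < m) || any(br$end < m) ||
        any(br$start > params$shape - m) || any(br$end > params$shape - m))
      abort(sprintf("branch %s/%d does not fit the grid; shrink lengths or enlarge `shape`",
                    br$tree, br$heap))
  }

  # within-tree and between-tree clearance (ignoring pairs sharing a point)
  share_pt <- function(b1, b2) {
    eps <- 1e-6
    any(c(sqdist(b1$start, b2$start), sqdist(b1$start, b2$end),
          sqdist(b1$end, b2$start), sqdist(b1$end, b2$end)) < eps)
  }
  for (i in seq_along(all_br)) for (j in seq_along(all_br)) {
    if (i >= j) next
    b1 <- all_br[[i]]; b2 <- all_br[[j]]
    if (share_pt(b1, b2)) next
    dmin <- seg_dist(b1$start, b1$end, b2$start, b2$end)
    # same-tree branches must stay well separated; cross-tree branches only
    # need to avoid lumen contact (radii taper distally, where the trees
    # interdigitate most closely) — exact skeleton-contact verification
    # happens after rasterization
    lim <- if (b1$tree == b2$tree) 2.5 else max(2.2, b1$radius + b2$radius + 0.4)
    if (dmin < lim) {
      if (verbose) inform(sprintf("clearance violation %s/%d vs %s/%d (%.2f)",
                                  b1$tree, b1$heap, b2$tree, b2$heap, dmin))
      return(NULL)
    }
  }

  # detached satellite spurs first (twigs must then keep clear of them):
  # short segments alongside a generation-1/2 branch, on the side facing
  # away from the opposite tree, far from every leaf tip so peripheral
  # matching cannot reach them
  leaf_tips <- do.call(rbind, map(all_br[vapply(all_br, function(b) b$gen, 0) == depth], "end"))
  satellites <- list()
  off_lat <- e_lane
  # trunk first: its mid-section is far from every leaf tip and from the
  # higher generations where adhesion twigs are planted
  sat_gens <- c(1L, which(gen_of == 1L))
  for (s in seq_len(params$n_satellites)) {
    tree <- if (s %% 2L == 1L) "artery" else "vein"
    away <- if (tree == "artery") -off_lat else off_lat
    placed <- FALSE
    for (heap in sat_gens) {
      if (placed) break
      pb <- (if (tree == "artery") arteries else veins)[[heap]]
      for (t in c(0.5, 0.35, 0.65)) {
        ctr_pt <- pb$start + t * (pb$end - pb$start) + away * (pb$radius + 4)
        s_start <- ctr_pt - 4 * pb$dir
        s_end <- ctr_pt + 4 * pb$dir
        ok <- all(s_start > 3) && all(s_end > 3) &&
          all(s_start < params$shape - 3) && all(s_end < params$shape - 3)
        if (ok) for (br in all_br) {
          if (seg_dist(s_start, s_end, br$start, br$end) < 3) { ok <- FALSE; break }
        }
        if (ok && !is.null(leaf_tips) && nrow(leaf_tips) > 0L) {
          d1 <- sqrt(rowSums(sweep(leaf_tips, 2L, s_start, `-`)^2))
          d2 <- sqrt(rowSums(sweep(leaf_tips, 2L, s_end, `-`)^2))
          if (min(c(d1, d2)) < 12) ok <- FALSE
        }
        if (ok) for (sat in satellites) {
          dd <- min(sqrt(sum((s_start - sat$start)^2)), sqrt(sum((s_end - sat$end)^2)),
                    sqrt(sum((s_start - sat$end)^2)), sqrt(sum((s_end - sat$start)^2)))
          if (dd < 12) { ok <- FALSE; break }
        }
        if (ok) {
          satellites[[length(satellites) + 1L]] <- list(
            tree = tree, start = s_start, end = s_end, radius = 0.8)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      if (verbose) inform("could not place a satellite")
      return(NULL)
    }
  }

  # adhesion twigs: short side-shoots anchored on one tree that cross one
  # centerline voxel of the other tree's partner branch transversally.
  # Anchors alternate between the trees; candidate slots sit on branches of
  # generations 1..min(3, depth - 1), away from both branch ends.
  twig_gens <- seq_len(min(3L, max(depth - 1L, 1L)))
  cand <- list()
  for (b in which(gen_of %in% twig_gens)) {
    for (tree in c("vein", "artery")) {
      # slots are arc positions on the TARGET branch (the one that gets
      # crossed), kept away from the junction clusters of both the target
      # and the anchor: the anchor's arc is shifted by the projection of
      # the inter-tree offset onto the branch direction
      tb <- (if (tree == "vein") arteries else veins)[[b]]
      ab <- (if (tree == "vein") veins else arteries)[[b]]
      cshift <- sum((tb$start - ab$start) * ab$dir)
      lo <- max(5, 4 - cshift)
      hi <- min(tb$len - 3.5, ab$len - 3 - cshift)
      if (hi <= lo) next
      n_slots <- max(1L, floor((hi - lo) / 5) + 1L)
      ts <- if (n_slots == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = n_slots)
      for (t in ts) {
        cand[[length(cand) + 1L]] <- list(heap = b, arc = t, tree = tree)
      }
    }
  }
  ord <- order(slot_shuffle[seq_along(cand)])
  cand <- cand[ord]

  art_vox <- map(arteries, ~ bresenham3(.x$start, .x$end))
  vein_vox <- map(veins, ~ bresenham3(.x$start, .x$end))

  twigs <- list()
  chosen_P <- NULL
  rej <- c(tA = 0L, psep = 0L, branch = 0L, sat = 0L, twig = 0L, grid = 0L)
  for (cd in cand) {
    if (length(twigs) >= n_adh) break
    anchor <- (if (cd$tree == "vein") veins else arteries)[[cd$heap]]
    target <- (if (cd$tree == "vein") arteries else veins)[[cd$heap]]
    target_vox <- (if (cd$tree == "vein") art_vox else vein_vox)[[cd$heap]]
    anchor_vox <- (if (cd$tree == "vein") vein_vox else art_vox)[[cd$heap]]
    # crossing voxel on the target branch at the slot's arc position, then
    # the anchor point as the nearest anchor-branch voxel; the anchor
    # point must also sit away from the anchor's own junctions
    Pc <- target$start + cd$arc * target$dir
    P <- target_vox[which.min(rowSums(sweep(target_vox, 2L, Pc, `-`)^2)), ]
    Q <- anchor_vox[which.min(rowSums(sweep(anchor_vox, 2L, as.numeric(P), `-`)^2)), ]
    qA <- sum((Q - anchor$start) * anchor$dir)
    if (qA < 4 || anchor$len - qA < 3) {
      rej["tA"] <- rej["tA"] + 1L; next
    }
    w <- normalize(as.numeric(P - Q))
    tip <- round(P + 6 * w)
    ok <- TRUE
    if (!is.null(chosen_P) &&
        min(sqrt(rowSums(sweep(chosen_P, 2L, as.numeric(P), `-`)^2))) < 5) {
      ok <- FALSE; rej["psep"] <- rej["psep"] + 1L
    }
    # graph-adjacent relatives of the anchor legitimately pass near Q and
    # are exempt from the clearance check; on the target side only the
    # branch itself and its parent/children are exempt — the target's
    # sibling must stay clear of the twig tip. The rasterization contact
    # count verifies the final configuration regardless.
    rel_anchor <- unique(c(cd$heap, cd$heap %/% 2L, 2L * cd$heap,
                           2L * cd$heap + 1L, bitwXor(cd$heap, 1L)))
    rel_target <- unique(c(cd$heap, cd$heap %/% 2L, 2L * cd$heap, 2L * cd$heap + 1L))
    target_tree <- if (cd$tree == "vein") "artery" else "vein"
    if (ok) for (br in all_br) {
      if (br$tree == cd$tree && br$heap %in% rel_anchor) next
      if (br$tree == target_tree && br$heap %in% rel_target) next
      if (seg_dist(as.numeric(Q), as.numeric(tip), br$start, br$end) < 2.5) {
        ok <- FALSE; rej["branch"] <- rej["branch"] + 1L
        if (verbose) inform(sprintf("twig %s/%d t %.2f blocked by %s/%d",
                                    cd$tree, cd$heap, cd$arc, br$tree, br$heap))
        break
      }
    }
    if (ok) for (sat in satellites) {
      if (seg_dist(as.numeric(Q), as.numeric(tip), sat$start, sat$end) < 4 ||
          min(sqrt(sum((tip - sat$start)^2)), sqrt(sum((tip - sat$end)^2))) < 12) {
        ok <- FALSE; rej["sat"] <- rej["sat"] + 1L; break
      }
    }
    if (ok) for (tw in twigs) {
      if (seg_dist(as.numeric(Q), as.numeric(tip), as.numeric(tw$Q),
                   as.numeric(tw$tip)) < 3) { ok <- FALSE; rej["twig"] <- rej["twig"] + 1L; break }
    }
    if (!ok) next
    if (any(tip < 2) || any(tip > params$shape - 2)) { rej["grid"] <- rej["grid"] + 1L; next }
    twigs[[length(twigs) + 1L]] <- list(
      heap = cd$heap, tree = cd$tree, Q = Q, P = P, tip = tip,
      radius = max(anchor$radius * params$taper, params$min_radius))
    chosen_P <- rbind(chosen_P, as.numeric(P))
  }
  if (length(twigs) < n_adh) {
    if (verbose) inform(sprintf("only %d of %d adhesions placed (rejections: %s)",
                                length(twigs), n_adh,
                                paste(names(rej), rej, sep = "=", collapse = " ")))
    return(NULL)
  }

  list(branches = all_br, twigs = twigs, satellites = satellites,
       n_adhesions = n_adh, params = params)
}

#' Generate the phantom's centerline polylines
#'
#' Runs the seeded recursive growth, venous replay, adhesion-twig planting
#' and satellite placement, retrying with derived sub-seeds when a clearance
#' constraint cannot be met. Deterministic for a given parameter set.
#'
#' @param params A `tree_params` from [phantom_params()].
#' @return A geometry list: `branches` (per-branch start/end/dir/len/radius),
#'   `twigs` (planted adhesions, with crossing voxel `P`), `satellites`,
#'   `n_adhesions` and the originating `params`.
#' @export
generate_polyline_trees <- function(params, start_attempt = 0L,
                                    max_attempts = 60L) {
  for (attempt in seq(start_attempt, start_attempt + max_attempts - 1L)) {
    geo <- with_local_seed(params$seed + attempt * 7919L,
                           phantom_geometry_attempt(params))
    if (!is.null(geo)) {
      geo$attempt <- attempt
      return(geo)
    }
  }
  abort("could not generate a clearance-respecting phantom; adjust parameters")
}

#' Rasterize phantom geometry into mask, skeleton and ground truth
#'
#' The mask is the union of spheres swept along the centerlines with the
#' local radii; the skeleton is the unit-width voxelization of the
#' centerlines; ground-truth labels follow tree identity, with contested
#' (overlapping) voxels assigned to the locally thicker tube (ties to the
#' venous tree).
#'
#' @param geometry Output of [generate_polyline_trees()].
#' @param strict When `TRUE` (default) an unexpected skeleton contact count
#'   raises an error; [vascular_phantom()] instead retries a fresh geometry.
#' @return A `synthetic_case`: list with `mask`, `skeleton`, `gt_labels`
#'   (1 = artery, 2 = vein), `n_adhesions`, `adhesion_sites` and `params`.
#' @export
rasterize_phantom <- function(geometry, strict = TRUE) {
  params <- geometry$params
  shape <- params$shape
  nvox <- prod(shape)
  ra <- numeric(nvox); rv <- numeric(nvox)
  skel_a <- logical(nvox); skel_v <- logical(nvox)

  ball_cache <- new.env(parent = emptyenv())
  ball_offsets <- function(r) {
    key <- sprintf("%.2f", r)
    if (is.null(ball_cache[[key]])) {
      w <- floor(r)
      g <- as.matrix(expand.grid(-w:w, -w:w, -w:w))
      ball_cache[[key]] <- g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
    }
    ball_cache[[key]]
  }
  paint <- function(vox, radius, tree) {
    off <- ball_offsets(radius)
    centers <- lin_index(vox, shape)
    if (tree == "artery") skel_a[centers] <<- TRUE else skel_v[centers] <<- TRUE
    for (oi in seq_len(nrow(off))) {
      sh <- sweep(vox, 2L, off[oi, ], `+`)
      ok <- sh[, 1] >= 1L & sh[, 2] >= 1L & sh[, 3] >= 1L &
        sh[, 1] <= shape[1] & sh[, 2] <= shape[2] & sh[, 3] <= shape[3]
      if (!any(ok)) next
      li <- lin_index(sh[ok, , drop = FALSE], shape)
      if (tree == "artery") ra[li] <<- pmax(ra[li], radius)
      else rv[li] <<- pmax(rv[li], radius)
    }
  }

  for (br in geometry$branches)
    paint(bresenham3(br$start, br$end), br$radius, br$tree)
  for (tw in geometry$twigs) {
    vox <- rbind(bresenham3(tw$Q, tw$P), bresenham3(tw$P, tw$tip))
    vox <- vox[!duplicated(vox), , drop = FALSE]
    paint(vox, tw$radius, tw$tree %||% "vein")
  }
  for (sat in geometry$satellites)
    paint(bresenham3(sat$start, sat$end), sat$radius, sat$tree)

  mask <- ra > 0 | rv > 0
  skel <- skel_a | skel_v
  gt <- integer(nvox)
  gt[ra > 0 & (rv == 0 | ra > rv)] <- 1L
  gt[rv > 0 & (ra == 0 | rv >= ra)] <- 2L

  dim(mask) <- shape; dim(skel) <- shape; dim(gt) <- shape

  # verify the planted adhesion count: contact clusters between the two
  # skeletons under 26-adjacency (shared voxels included)
  av <- which(skel_a); dim(skel_a) <- shape
  vv_lin <- which(skel_v); dim(skel_v) <- shape
  acoords <- which(skel_a, arr.ind = TRUE)
  contact <- logical(nrow(acoords))
  offs <- rbind(c(0L, 0L, 0L), nb26())
  for (oi in seq_len(nrow(offs))) {
    sh <- sweep(acoords, 2L, offs[oi, ], `+`)
    ok <- sh[, 1] >= 1L & sh[, 2] >= 1L & sh[, 3] >= 1L &
      sh[, 1] <= shape[1] & sh[, 2] <= shape[2] & sh[, 3] <= shape[3]
    hit <- rep(FALSE, nrow(acoords))
    hit[ok] <- skel_v[sh[ok, , drop = FALSE]]
    contact <- contact | hit
  }
  sites <- acoords[contact, , drop = FALSE]
  n_clusters <- 0L
  if (nrow(sites) > 0L) {
    d <- as.matrix(stats::dist(sites, method = "maximum"))
    g <- igraph::graph_from_adjacency_matrix(d <= 1.5, mode = "undirected")
    n_clusters <- igraph::components(g)$no
  }
  if (n_clusters != geometry$n_adhesions) {
    msg <- sprintf("rasterization produced %d contact clusters, expected %d",
                   n_clusters, geometry$n_adhesions)
    if (strict) abort(msg)
    inform(msg)
    return(NULL)
  }

  structure(list(
    mask = vox_volume(mask, params$spacing),
    skeleton = vox_volume(skel, params$spacing),
    gt_labels = vox_volume(gt, params$spacing),
    n_adhesions = geometry$n_adhesions,
    adhesion_sites = sites,
    geometry = geometry,
    params = params
  ), class = "synthetic_case")
}

#' Generate a complete synthetic phantom case
#'
#' Convenience wrapper: [phantom_params()] |> [generate_polyline_trees()]
#' |> [rasterize_phantom()].
#'
#' @param ... Passed to [phantom_params()].
#' @return A `synthetic_case`.
#' @export
vascular_phantom <- function(...) {
  params <- phantom_params(...)
  attempt <- 0L
  for (round in 1:40) {
    geo <- generate_polyline_trees(params, start_attempt = attempt)
    case <- suppressMessages(rasterize_phantom(geo, strict = FALSE))
    if (!is.null(case)) return(case)
    attempt <- geo$attempt + 1L
  }
  abort("could not rasterize a contact-consistent phantom; adjust parameters")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "<synthetic_case> grid %s | %d mask voxels, %d skeleton voxels, %d planted adhesions, seed %d\n",
    paste(x$params$shape, collapse = "x"), sum(x$mask), sum(x$skeleton),
    x$n_adhesions, x$params$seed))
  invisible(x)
}
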