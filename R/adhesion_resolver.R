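#' Detect adhesion nodes
#'
#' An adhesion point is a node where four or more branches meet: a
#' bifurcation contributes degree 3, so degree >= 4 indicates two vessels
#' (typically an artery and a vein) touching in the discrete skeleton.
#'
#' @param graph A `vessel_graph`.
#' @return Integer node ids with degree >= 4, ascending.
#' @export
detect_adhesion_nodes <- function(graph) {
  sort(graph$nodes$id[graph$nodes$degree >= 4L & !graph$nodes$isolated])
}

#' Representative point of a branch at a node
#'
#' The branch-angle computation needs one point per branch. In `endpoint`
#' mode (the default) this is the centroid of the node at the far end of the
#' link; in `k_step` mode it is the k-th voxel of the link's path counted
#' from the query node, clipped to the far end for short links.
#'
#' @param graph A `vessel_graph`.
#' @param node Node id at which the branch is anchored.
#' @param link Id of a link incident to `node`.
#' @param mode `"endpoint"` or `"k_step"`.
#' @param k Step count for `k_step` mode (>= 1).
#' @return Numeric length-3 coordinates (voxel units).
#' @export
branch_representative <- function(graph, node, link, mode = c("endpoint", "k_step"),
                                  k = 5L) {
  mode <- match.arg(mode)
  r <- match(link, graph$links$id)
  if (is.na(r)) abort(sprintf("no link with id %d", link))
  a <- graph$links$n_start[r]; b <- graph$links$n_end[r]
  if (node != a && node != b) abort("link is not incident to node")
  far <- if (node == a) b else a
  pts <- graph$links$points[[r]]
  if (mode == "endpoint" || nrow(pts) == 0L) return(node_com(graph, far))
  if (k < 1L) abort("`k` must be >= 1")
  idx <- min(as.integer(k), nrow(pts))
  if (node == a) as.numeric(pts[idx, ]) else as.numeric(pts[nrow(pts) - idx + 1L, ])
}

#' Angle between two branches at a point
#'
#' Computes the angle `∠APB` in degrees by the law of cosines on the squared
#' side lengths: `a1 = |PA|^2`, `b1 = |PB|^2`, `c1 = |AB|^2`,
#' `pos = (a1 + b1 - c1) / (2 sqrt(a1) sqrt(b1))` (clamped to `[-1, 1]`),
#' `theta = arccos(pos) * 180 / pi`.
#'
#' @param P Coordinates of the vertex (the adhesion point).
#' @param A,B Representative coordinates of the two branches.
#' @return The angle in degrees, in `[0, 180]`.
#' @export
branch_angle <- function(P, A, B) {
  P <- as.numeric(P); A <- as.numeric(A); B <- as.numeric(B)
  a1 <- sqdist(P, A)
  b1 <- sqdist(P, B)
  c1 <- sqdist(A, B)
  if (a1 == 0 || b1 == 0) abort("zero-length branch vector (A or B equals P)")
  pos <- (a1 + b1 - c1) / (2 * sqrt(a1) * sqrt(b1))
  pos <- min(1, max(-1, pos))
  acos(pos) * 180 / pi
}

# All angle-query intermediates for one branch pair, mirroring the published
# quantities (useful for audit logs and tests).
angle_query <- function(P, A, B) {
  a1 <- sqdist(as.numeric(P), as.numeric(A))
  b1 <- sqdist(as.numeric(P), as.numeric(B))
  c1 <- sqdist(as.numeric(A), as.numeric(B))
  pos <- min(1, max(-1, (a1 + b1 - c1) / (2 * sqrt(a1) * sqrt(b1))))
  list(P = P, A = A, B = B, a1 = a1, b1 = b1, c1 = c1, pos = pos,
       theta = acos(pos) * 180 / pi)
}

# Incident links of a node usable for pairing: self-loops are excluded
# (their two attachment directions are ambiguous) and flagged.
pairable_links <- function(graph, node) {
  r <- match(node, graph$nodes$id)
  ids <- graph$nodes$link_ids[[r]]
  dup <- unique(ids[duplicated(ids)])           # self-loops appear twice
  list(links = sort(setdiff(ids, dup)), self_loops = dup)
}

#' Best pairing of branches at an adhesion node
#'
#' For a degree-4 node the three perfect pairings of the four incident links
#' are enumerated; the pairing maximizing the sum of the two pair angles is
#' chosen (ties broken toward the lexicographically smallest link-id pairs).
#' For degree >= 5 the pairing is greedy: the two remaining links with the
#' largest mutual angle are paired repeatedly; an odd leftover link stays
#' unpaired.
#'
#' @inheritParams branch_representative
#' @return A list with `node`, `pairs` (list of sorted id pairs), `angles`
#'   (degrees, one per pair), `leftover` (unpaired link ids, including
#'   self-loops) and `score` (sum of pair angles).
#' @export
best_pairing <- function(graph, node, mode = c("endpoint", "k_step"), k = 5L) {
  mode <- match.arg(mode)
  pl <- pairable_links(graph, node)
  ids <- pl$links
  if (length(ids) + 2L * length(pl$self_loops) < 4L)
    abort("node degree < 4: nothing to pair")
  P <- node_com(graph, node)
  reps <- map(ids, ~ branch_representative(graph, node, .x, mode, k))
  m <- length(ids)
  ang <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i < j) {
    th <- branch_angle(P, reps[[i]], reps[[j]])
    ang[i, j] <- th; ang[j, i] <- th
  }

  if (m == 4L) {
    combos <- list(list(c(1L, 2L), c(3L, 4L)),
                   list(c(1L, 3L), c(2L, 4L)),
                   list(c(1L, 4L), c(2L, 3L)))
    scores <- map_dbl(combos, ~ ang[.x[[1]][1], .x[[1]][2]] + ang[.x[[2]][1], .x[[2]][2]])
    best <- which(scores >= max(scores) - 1e-12)
    choice <- combos[[min(best)]]   # combos are already in lexicographic order
    pairs <- map(choice, ~ ids[.x])
    angles <- map_dbl(choice, ~ ang[.x[1], .x[2]])
    leftover <- pl$self_loops
    score <- sum(angles)
  } else if (m < 2L) {
    pairs <- list(); angles <- double(); leftover <- c(ids, pl$self_loops)
    score <- 0
  } else {
    left <- seq_len(m)
    pairs <- list(); angles <- double()
    while (length(left) >= 2L) {
      sub <- ang[left, left, drop = FALSE]
      mx <- max(sub)
      cand <- which(sub >= mx - 1e-12, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      i <- left[cand[1, 1]]; j <- left[cand[1, 2]]
      pairs <- c(pairs, list(ids[c(i, j)]))
      angles <- c(angles, ang[i, j])
      left <- setdiff(left, c(i, j))
    }
    leftover <- c(ids[left], pl$self_loops)
    score <- sum(angles)
  }
  list(node = node, pairs = pairs, angles = angles,
       leftover = sort(leftover), score = score)
}

#' Split all adhesion nodes of a graph
#'
#' For every node of degree >= 4, the best branch pairing is computed and
#' each paired couple of links is fused into one link passing through the
#' node, so the two touching vessels continue independently. When the node
#' is fully consumed (every incident link paired) its cluster voxels are
#' divided among the fused links by nearest attachment segment and the node
#' is removed; otherwise (odd degree, self-loops) the node remains as a
#' flagged residual keeping its voxels, and fused links carry a recorded gap
#' where they bypass it. Voxel conservation holds throughout.
#'
#' @inheritParams branch_representative
#' @param audit Optional path of a CSV audit log (one row per split decision:
#'   node id, pair, angle).
#' @return A new `vessel_graph` with no unflagged node of degree >= 4.
#' @export
split_adhesions <- function(graph, mode = c("endpoint", "k_step"), k = 5L,
                            audit = NULL) {
  mode <- match.arg(mode)
  adh <- detect_adhesion_nodes(graph)
  if (length(adh) == 0L) {
    if (!is.null(audit)) utils::write.csv(audit_frame(NULL), audit, row.names = FALSE)
    return(graph)
  }

  nodes <- graph$nodes
  links_env <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(graph$links))) {
    assign(as.character(graph$links$id[r]), list(
      id = graph$links$id[r],
      n_start = graph$links$n_start[r], n_end = graph$links$n_end[r],
      points = graph$links$points[[r]],
      n_gaps = graph$links$n_gaps[r],
      through_node = graph$links$through_node[[r]]
    ), envir = links_env)
  }
  node_links <- setNames(nodes$link_ids, as.character(nodes$id))
  removed_nodes <- integer()
  residual_nodes <- integer()
  next_id <- max(graph$links$id) + 1L
  audit_rows <- list()

  get_link <- function(id) get(as.character(id), envir = links_env)
  put_link <- function(l) assign(as.character(l$id), l, envir = links_env)
  drop_link <- function(id) rm(list = as.character(id), envir = links_env)

  # points of link `id` oriented to END at `node`; also its far node id
  oriented_into <- function(id, node) {
    l <- get_link(id)
    if (l$n_end == node) list(pts = l$points, far = l$n_start, l = l)
    else list(pts = l$points[rev(seq_len(nrow(l$points))), , drop = FALSE],
              far = l$n_end, l = l)
  }
  replace_incidence <- function(nid, old, new) {
    key <- as.character(nid)
    ids <- node_links[[key]]
    ids[match(old, ids)] <- new
    node_links[[key]] <<- sort(ids)
  }

  for (nd in adh) {
    # refresh the node's incident set (earlier fusions may have renamed links)
    cur_links <- node_links[[as.character(nd)]]
    dup <- unique(cur_links[duplicated(cur_links)])
    plain <- sort(setdiff(cur_links, dup))
    if (length(plain) + 2L * length(dup) < 4L) next

    # a temporary view of the graph for representative lookup
    tmp_graph <- graph
    tmp_graph$links <- collect_links(links_env)
    tmp_graph$nodes <- nodes
    tmp_graph$nodes$link_ids[match(nd, nodes$id)] <- list(cur_links)
    pr <- best_pairing(tmp_graph, nd, mode, k)
    if (length(pr$pairs) == 0L) next

    fully <- length(pr$leftover) == 0L
    nrow_nd <- match(nd, nodes$id)
    cluster <- nodes$idx[[nrow_nd]]
    P <- c(nodes$com_i[nrow_nd], nodes$com_j[nrow_nd], nodes$com_k[nrow_nd])

    # attachment coordinates per pair (the path voxels abutting the node)
    fused <- list()
    for (pi in seq_along(pr$pairs)) {
      pair <- pr$pairs[[pi]]
      o1 <- oriented_into(pair[1], nd)
      o2 <- oriented_into(pair[2], nd)
      att1 <- if (nrow(o1$pts) > 0L) as.numeric(o1$pts[nrow(o1$pts), ]) else node_com(tmp_graph, o1$far)
      att2 <- if (nrow(o2$pts) > 0L) as.numeric(o2$pts[1, ]) else node_com(tmp_graph, o2$far)
      fused[[pi]] <- list(pair = pair, o1 = o1, o2 = o2, att1 = att1, att2 = att2,
                          angle = pr$angles[pi])
    }

    # divide cluster voxels among pairs (only when the node is fully consumed)
    assign_to <- rep(1L, nrow(cluster))
    if (length(fused) > 1L && fully && nrow(cluster) > 0L) {
      dmat <- vapply(fused, function(f)
        point_segment_dist(cluster, f$att1, f$att2), numeric(nrow(cluster)))
      dmat <- matrix(dmat, nrow = nrow(cluster))
      assign_to <- apply(dmat, 1L, function(d) {
        w <- which(d <= min(d) + 1e-9)
        if (length(w) > 1L) w[which.max(map_dbl(fused[w], "angle"))[1]] else w
      })
    }

    for (pi in seq_along(fused)) {
      f <- fused[[pi]]
      mid <- matrix(integer(), 0L, 3L)
      if (fully && nrow(cluster) > 0L) {
        rows <- which(assign_to == pi)
        if (length(rows) > 0L) {
          sub <- cluster[rows, , drop = FALSE]
          tvec <- f$att2 - f$att1
          proj <- as.numeric(sweep(sub, 2L, f$att1, `-`) %*% tvec)
          mid <- sub[order(proj), , drop = FALSE]
        }
      }
      new_pts <- rbind(f$o1$pts, mid, f$o2$pts[rev(seq_len(nrow(f$o2$pts))), , drop = FALSE])
      # count adjacency gaps introduced at the bypass
      gaps <- f$o1$l$n_gaps + f$o2$l$n_gaps
      if (nrow(new_pts) >= 2L) {
        d <- abs(diff(new_pts))
        gaps <- gaps + sum(!(rowSums(d > 1L) == 0L & rowSums(d) > 0L)) -
          sum(!(path_adjacent(f$o1$pts))) - sum(!(path_adjacent(f$o2$l$points)))
        gaps <- max(gaps, 0L)
      }
      nl <- list(id = next_id, n_start = f$o1$far, n_end = f$o2$far,
                 points = new_pts, n_gaps = as.integer(gaps),
                 through_node = sort(unique(c(f$o1$l$through_node,
                                              f$o2$l$through_node, nd))))
      put_link(nl)
      replace_incidence(f$o1$far, f$pair[1], next_id)
      replace_incidence(f$o2$far, f$pair[2], next_id)
      drop_link(f$pair[1]); drop_link(f$pair[2])
      audit_rows[[length(audit_rows) + 1L]] <- tibble(
        node = nd, link_a = f$pair[1], link_b = f$pair[2],
        fused_link = next_id, angle = f$angle, resolved = fully)
      next_id <- next_id + 1L
    }

    if (fully) {
      removed_nodes <- c(removed_nodes, nd)
      node_links[[as.character(nd)]] <- integer()
    } else {
      residual_nodes <- c(residual_nodes, nd)
      node_links[[as.character(nd)]] <- sort(pr$leftover)
    }
  }

  links_tbl <- collect_links(links_env)
  keep <- !(nodes$id %in% removed_nodes)
  nodes_tbl <- nodes[keep, c("id", "flag", "idx", "com_i", "com_j", "com_k")]
  # nodes fully consumed pass their voxels to fused links; drop them
  nodes_tbl <- finalize_nodes(nodes_tbl, links_tbl)
  nodes_tbl$residual <- nodes_tbl$id %in% residual_nodes
  out <- new_vessel_graph(nodes_tbl, links_tbl, graph$shape, graph$spacing,
                          graph$n_voxels)
  if (!is.null(audit)) utils::write.csv(audit_frame(audit_rows), audit, row.names = FALSE)
  out
}

audit_frame <- function(rows) {
  if (is.null(rows) || length(rows) == 0L)
    return(tibble(node = integer(), link_a = integer(), link_b = integer(),
                  fused_link = integer(), angle = double(), resolved = logical()))
  bind_rows(rows)
}

collect_links <- function(links_env) {
  ids <- sort(as.integer(ls(links_env)))
  ll <- map(ids, ~ get(as.character(.x), envir = links_env))
  tibble(
    id = ids,
    n_start = map_int(ll, ~ as.integer(.x$n_start)),
    n_end = map_int(ll, ~ as.integer(.x$n_end)),
    points = map(ll, "points"),
    n_gaps = map_int(ll, ~ as.integer(.x$n_gaps)),
    through_node = map(ll, "through_node")
  )
}

path_adjacent <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2L) return(logical())
  d <- abs(diff(pts))
  rowSums(d > 1L) == 0L & rowSums(d) > 0L
}

# Distance from each row of `pts` to the segment [a, b].
point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2L, a, `-`)
  if (len2 < 1e-12) return(sqrt(rowSums(rel^2)))
  t <- pmin(1, pmax(0, as.numeric(rel %*% ab) / len2))
  proj <- outer(t, ab)
  sqrt(rowSums((rel - proj)^2))
}
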