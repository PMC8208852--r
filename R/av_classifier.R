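#' Per-class lumen volume and centerline length
#'
#' The anatomical discriminator between the two classes is lumen volume per
#' unit centerline length: the venous tree is the bulkier one. Volume is the
#' labelled voxel count times the voxel volume; centerline length is the
#' summed Euclidean step length over each class's link polylines (node
#' centroid, path voxels, node centroid), in mm.
#'
#' @param labeled Restored labelled volume (1 = class0, 2 = class1).
#' @param graph The adhesion-split `vessel_graph`.
#' @param assignment A `class_assignment`.
#' @param subtrees The matching `subtree_set`.
#' @return A tibble with one row per class: `class`, `n_voxels`,
#'   `volume_mm3`, `centerline_length_mm`, `volume_per_length` (`NA`,
#'   flagged, when the class has no centerline).
#' @export
class_stats <- function(labeled, graph, assignment, subtrees) {
  spacing <- voxel_spacing(labeled)
  voxvol <- prod(spacing)
  link_len <- function(lid) {
    r <- match(lid, graph$links$id)
    a <- node_com(graph, graph$links$n_start[r])
    b <- node_com(graph, graph$links$n_end[r])
    poly <- rbind(a, graph$links$points[[r]], b)
    steps <- diff(sweep(poly, 2L, spacing, `*`))
    sum(sqrt(rowSums(steps^2)))
  }
  per_class <- function(cls, code) {
    sids <- assignment$subtree_id[assignment$class == cls]
    lids <- unlist(subtrees$link_ids[subtrees$id %in% sids])
    len <- if (length(lids)) sum(map_dbl(lids, link_len)) else 0
    nvox <- sum(labeled == code)
    tibble(class = cls, n_voxels = nvox, volume_mm3 = nvox * voxvol,
           centerline_length_mm = len,
           volume_per_length = ifelse(len > 0, nvox * voxvol / len, NA_real_))
  }
  out <- bind_rows(per_class("class0", 1L), per_class("class1", 2L))
  if (any(is.na(out$volume_per_length)))
    warn("a class has zero centerline length; volume_per_length undefined")
  out
}

#' Decide which class is artery and which is vein
#'
#' The class with the higher lumen volume per unit centerline length is the
#' venous tree; the other is arterial. An exact tie maps class0 to vein
#' with a warning.
#'
#' @param stats The two-row tibble from [class_stats()] (or two one-row
#'   tibbles passed as `stats0`, `stats1`).
#' @param stats1 Optional second row when `stats` holds only class0.
#' @return A tibble `class`, `vessel` (`artery`/`vein`).
#' @export
assign_artery_vein <- function(stats, stats1 = NULL) {
  if (!is.null(stats1)) stats <- bind_rows(stats, stats1)
  if (nrow(stats) != 2L) abort("expected statistics for exactly two classes")
  if (any(is.na(stats$volume_per_length)))
    abort("volume_per_length undefined for a class; cannot assign artery/vein")
  v <- stats$volume_per_length
  if (v[1] == v[2]) {
    warn("equal volume per unit length; tie broken toward class0 = vein")
    vein <- 1L
  } else vein <- which.max(v)
  tibble(class = stats$class,
         vessel = ifelse(seq_len(2L) == vein, "vein", "artery"))
}

# Local vessel radius at a coordinate: distance to the nearest background
# voxel of the mask, searched in a window (physical units).
local_radius <- function(mask, coord, window = 8L) {
  shape <- dim(mask)
  spacing <- voxel_spacing(mask)
  ctr <- round(coord)
  lo <- pmax(ctr - window, 1)
  hi <- pmin(ctr + window, shape)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bg <- which(!sub, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(window * min(spacing))
  bg <- sweep(bg, 2L, lo - 1, `+`)
  d <- sweep(bg, 2L, coord, `-`)
  d <- sweep(d, 2L, spacing, `*`)
  min(sqrt(rowSums(d^2)))
}

#' Find the root node of a vessel class
#'
#' The root (trunk end) is taken to be the node with the largest local
#' vessel radius, estimated as the distance from the node centroid to the
#' nearest background voxel of the segmentation mask (ties: smallest node
#' id). A user-supplied coordinate overrides the estimate and selects the
#' nearest class node instead.
#'
#' @param graph A `vessel_graph`.
#' @param class_links Integer ids of the links belonging to the class.
#' @param mask Binary vessel segmentation.
#' @param override Optional numeric length-3 coordinate.
#' @return The root node id.
#' @export
find_root <- function(graph, class_links, mask, override = NULL) {
  if (length(class_links) == 0L) abort("class has no links")
  rows <- match(class_links, graph$links$id)
  nd <- sort(unique(c(graph$links$n_start[rows], graph$links$n_end[rows])))
  coms <- do.call(rbind, map(nd, ~ node_com(graph, .x)))
  if (!is.null(override)) {
    d <- sweep(coms, 2L, as.numeric(override), `-`)
    return(nd[which.min(rowSums(d^2))])
  }
  mask <- as_binary_volume(mask)
  rad <- map_dbl(seq_along(nd), ~ local_radius(mask, coms[.x, ]))
  nd[which(rad >= max(rad) - 1e-12)[1]]
}

#' Classify leftover subtrees by root-path majority vote
#'
#' Small subtrees without enough peripheral information stay unassigned
#' after [infer_two_classes()]. Each of their leaves is bridged to the
#' nearest skeleton voxel of an assigned subtree (within `bridge_dist`) and
#' a path is walked from there toward each class root: at every node the
#' next link maximizes
#' `w_a * theta / 180 - w_d * |d_next - d_cur| / max(d_next, d_cur)`,
#' where `theta` is the continuation angle and `d` the local diameter
#' (twice the mask distance-transform value at the node). The subtree takes
#' the class holding the majority of already-classified links over all
#' walks; an exact tie falls back to the best-scoring walk, and a subtree
#' whose walks reach no classified link stays unassigned.
#'
#' @param graph The adhesion-split `vessel_graph`.
#' @param subtrees The `subtree_set`.
#' @param assignment Current `class_assignment`.
#' @param mask Binary vessel segmentation (for diameters and roots).
#' @param roots Optional named list `class0`/`class1` of root node ids.
#' @param w_a,w_d Weights of the angle and diameter terms.
#' @param bridge_dist Maximum bridge distance (physical units).
#' @param max_steps Walk length cap.
#' @return The updated `class_assignment` (recovered subtrees get
#'   provenance `path_vote`).
#' @export
assign_unlabeled_subtrees <- function(graph, subtrees, assignment, mask,
                                      roots = NULL, w_a = 1, w_d = 1,
                                      bridge_dist = 10, max_steps = 100L) {
  mask <- as_binary_volume(mask)
  spacing <- voxel_spacing(mask)
  unassigned <- assignment$subtree_id[assignment$class == "unassigned"]
  if (length(unassigned) == 0L) return(assignment)

  link_class <- link_class_map(graph, subtrees, assignment)
  assigned_sids <- assignment$subtree_id[assignment$class != "unassigned"]
  if (length(assigned_sids) == 0L) return(assignment)

  # skeleton voxels of assigned subtrees, with owning node for graph entry
  vox <- list(); vox_node <- list()
  for (r in which(subtrees$id %in% assigned_sids)) {
    for (l in subtrees$link_ids[[r]]) {
      lr <- match(l, graph$links$id)
      pts <- graph$links$points[[lr]]
      if (nrow(pts) > 0L) {
        a <- node_com(graph, graph$links$n_start[lr])
        b <- node_com(graph, graph$links$n_end[lr])
        da <- rowSums(sweep(pts, 2L, a, `-`)^2)
        db <- rowSums(sweep(pts, 2L, b, `-`)^2)
        vox[[length(vox) + 1L]] <- pts
        vox_node[[length(vox_node) + 1L]] <-
          ifelse(da <= db, graph$links$n_start[lr], graph$links$n_end[lr])
      }
    }
    for (nd in subtrees$node_ids[[r]]) {
      m <- graph$nodes$idx[[match(nd, graph$nodes$id)]]
      vox[[length(vox) + 1L]] <- m
      vox_node[[length(vox_node) + 1L]] <- rep(nd, nrow(m))
    }
  }
  vox <- do.call(rbind, vox)
  vox_node <- unlist(vox_node)

  if (is.null(roots)) {
    roots <- list()
    for (cls in c("class0", "class1")) {
      lids <- names(link_class)[link_class == cls]
      roots[[cls]] <- if (length(lids)) find_root(graph, as.integer(lids), mask) else NA_integer_
    }
  }

  diam_cache <- new.env(parent = emptyenv())
  node_diam <- function(nid) {
    key <- as.character(nid)
    if (is.null(diam_cache[[key]]))
      diam_cache[[key]] <- 2 * local_radius(mask, node_com(graph, nid))
    diam_cache[[key]]
  }

  walk <- function(entry_node, from_coord, target_root) {
    visited_nodes <- entry_node
    cur <- entry_node
    prev_rep <- from_coord
    cls_links <- character()
    scores <- double()
    steps <- 0L
    repeat {
      steps <- steps + 1L
      if (steps > max_steps || (!is.na(target_root) && cur == target_root)) break
      nr <- match(cur, graph$nodes$id)
      cands <- unique(graph$nodes$link_ids[[nr]])
      best_s <- -Inf; best_l <- NA_integer_; best_far <- NA_integer_
      P <- node_com(graph, cur)
      for (l in sort(cands)) {
        lr <- match(l, graph$links$id)
        far <- if (graph$links$n_start[lr] == cur) graph$links$n_end[lr] else graph$links$n_start[lr]
        if (far %in% visited_nodes) next
        rep_pt <- node_com(graph, far)
        th <- tryCatch(branch_angle(P, prev_rep, rep_pt), error = function(e) 0)
        d_cur <- node_diam(cur); d_next <- node_diam(far)
        dd <- if (max(d_next, d_cur) > 0) abs(d_next - d_cur) / max(d_next, d_cur) else 0
        s <- w_a * th / 180 - w_d * dd
        if (s > best_s + 1e-12) { best_s <- s; best_l <- l; best_far <- far }
      }
      if (is.na(best_l)) break
      lc <- link_class[[as.character(best_l)]]
      if (!is.null(lc)) cls_links <- c(cls_links, lc)
      scores <- c(scores, best_s)
      prev_rep <- node_com(graph, cur)
      cur <- best_far
      visited_nodes <- c(visited_nodes, cur)
    }
    list(classes = cls_links,
         score = if (length(scores)) mean(scores) else -Inf)
  }

  out <- assignment
  for (sid in unassigned) {
    r <- match(sid, subtrees$id)
    lc <- subtrees$leaf_coords[[r]]
    if (nrow(lc) == 0L) next
    walks <- list()
    for (li in seq_len(nrow(lc))) {
      leaf <- lc[li, ]
      d <- cross_dist(matrix(leaf, 1L), vox, spacing)
      jn <- which.min(d)
      if (!length(jn) || d[jn] > bridge_dist) next
      entry <- vox_node[jn]
      for (cls in c("class0", "class1")) {
        walks[[length(walks) + 1L]] <- walk(entry, leaf, roots[[cls]])
      }
    }
    if (length(walks) == 0L) next
    votes <- table(unlist(map(walks, "classes")))
    if (length(votes) == 0L) next
    if (length(votes) == 2L && votes[[1]] == votes[[2]]) {
      best <- walks[[which.max(map_dbl(walks, "score"))]]
      bv <- table(best$classes)
      if (length(bv) == 0L || (length(bv) == 2L && bv[[1]] == bv[[2]])) next
      winner <- names(bv)[which.max(bv)]
    } else winner <- names(votes)[which.max(votes)]
    out$class[out$subtree_id == sid] <- winner
    out$provenance[out$subtree_id == sid] <- "path_vote"
  }
  out
}

# link id (character) -> class, for assigned subtrees
link_class_map <- function(graph, subtrees, assignment) {
  m <- character()
  for (r in seq_len(nrow(subtrees))) {
    cls <- assignment$class[match(subtrees$id[r], assignment$subtree_id)]
    if (is.na(cls) || cls == "unassigned") next
    lids <- subtrees$link_ids[[r]]
    m[as.character(lids)] <- cls
  }
  as.list(m)
}

#' Branch accuracy from counts
#'
#' `100 * (total - misjudged) / total`, reported to 2 decimals — the
#' branch-level separation accuracy used in the clinical evaluation.
#'
#' @param total Total branch count (> 0).
#' @param misjudged Misjudged branch count, `0 <= misjudged <= total`.
#' @return Accuracy percentage, rounded to 2 decimals. Vectorised.
#' @export
accuracy_from_counts <- function(total, misjudged) {
  if (any(total <= 0)) abort("`total` must be > 0")
  if (any(misjudged < 0) || any(misjudged > total))
    abort("`misjudged` must satisfy 0 <= misjudged <= total")
  round(100 * (total - misjudged) / total, 2L)
}

#' Evaluate predicted labels against a gold standard
#'
#' Each link's gold class is the majority gold label over its skeleton
#' voxels (path voxels plus endpoint node voxels for point-free links);
#' a link is misjudged when its predicted vessel differs (links left
#' unassigned count as misjudged). Lung sides are split at the mid-sagittal
#' plane of the gold bounding box along `lung_axis` unless `lung_split` is
#' given.
#'
#' @param graph The final split `vessel_graph`.
#' @param link_vessels Tibble `link_id`, `vessel` (`artery`/`vein`/`NA`).
#' @param gold Gold labelled volume (1 = artery, 2 = vein).
#' @param lung_axis Axis whose midpoint separates left from right lung.
#' @param lung_split Optional explicit split coordinate.
#' @return A tibble (class `accuracy_report`): one row per side plus an
#'   overall row, with `total_branches`, `misjudged_branches`,
#'   `accuracy_percent`; per-branch detail in `attr(, "branches")`.
#' @export
evaluate_separation <- function(graph, link_vessels, gold, lung_axis = 1L,
                                lung_split = NULL) {
  code <- c(artery = 1L, vein = 2L)
  link_pts <- function(r) {
    pts <- graph$links$points[[r]]
    if (nrow(pts) == 0L) {
      pts <- rbind(graph$nodes$idx[[match(graph$links$n_start[r], graph$nodes$id)]],
                   graph$nodes$idx[[match(graph$links$n_end[r], graph$nodes$id)]])
    }
    pts
  }
  skel_n <- 0L; cov_n <- 0L
  gold_cls <- character(nrow(graph$links))
  side_coord <- double(nrow(graph$links))
  for (r in seq_len(nrow(graph$links))) {
    pts <- link_pts(r)
    labs <- gold[pts]
    skel_n <- skel_n + nrow(pts)
    cov_n <- cov_n + sum(labs > 0L)
    labs <- labs[labs > 0L]
    gold_cls[r] <- if (length(labs) == 0L) NA_character_
      else names(code)[as.integer(names(which.max(table(labs))))]
    side_coord[r] <- mean(pts[, lung_axis])
  }
  if (cov_n < 0.5 * skel_n)
    abort("gold labels cover less than half of the skeleton voxels")
  if (is.null(lung_split)) {
    fg <- which(gold > 0L, arr.ind = TRUE)
    lung_split <- (min(fg[, lung_axis]) + max(fg[, lung_axis])) / 2
  }
  pred <- link_vessels$vessel[match(graph$links$id, link_vessels$link_id)]
  branches <- tibble(
    link_id = graph$links$id,
    side = ifelse(side_coord <= lung_split, "left", "right"),
    gold = gold_cls, predicted = pred,
    correct = !is.na(gold_cls) & !is.na(pred) & gold_cls == pred
  )
  scored <- filter(branches, !is.na(.data$gold))
  per_side <- bind_rows(map(c("left", "right"), function(sd) {
    b <- filter(scored, .data$side == sd)
    if (nrow(b) == 0L)
      return(tibble(side = sd, total_branches = 0L, misjudged_branches = 0L,
                    accuracy_percent = NA_real_))
    tibble(side = sd, total_branches = nrow(b),
           misjudged_branches = sum(!b$correct),
           accuracy_percent = accuracy_from_counts(nrow(b), sum(!b$correct)))
  }))
  overall <- tibble(side = "overall", total_branches = nrow(scored),
                    misjudged_branches = sum(!scored$correct),
                    accuracy_percent = accuracy_from_counts(nrow(scored), sum(!scored$correct)))
  out <- bind_rows(per_side, overall)
  structure(out, branches = branches, class = c("accuracy_report", class(out)))
}
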