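#' Group links into subtrees
#'
#' After adhesion splitting, the links of the graph fall into connected
#' components; each component is one subtree, the unit that belongs wholly
#' to either the arterial or the venous class. Traversal starts from leaf
#' nodes (depth-first), so every link is visited exactly once.
#'
#' @param graph An adhesion-split `vessel_graph`.
#' @return A tibble (class `subtree_set`) with one row per subtree:
#'   `id`, `link_ids`, `node_ids`, `leaf_node_ids`, `leaf_coords`
#'   (matrix of leaf centroids), `n_links`, `n_leaves`. Carries the graph's
#'   spacing as an attribute.
#' @export
build_subtrees <- function(graph) {
  links <- graph$links
  if (nrow(links) == 0L) {
    out <- tibble(id = integer(), link_ids = list(), node_ids = list(),
                  leaf_node_ids = list(), leaf_coords = list(),
                  n_links = integer(), n_leaves = integer())
    return(structure(out, spacing = graph$spacing, class = c("subtree_set", class(out))))
  }
  vids <- sort(unique(c(links$n_start, links$n_end)))
  g <- igraph::make_empty_graph(n = length(vids), directed = FALSE)
  g <- igraph::add_edges(g, rbind(match(links$n_start, vids),
                                  match(links$n_end, vids)))
  memb <- igraph::components(g)$membership
  comp_of_link <- memb[match(links$n_start, vids)]

  # order components by their smallest member node id (deterministic)
  comp_min <- tapply(vids, memb, min)
  ord <- order(comp_min)
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)

  leaf_ids <- graph$nodes$id[graph$nodes$ep == 1L]
  rows <- map(seq_along(ord), function(s) {
    comp <- which(remap == s)
    nd <- vids[memb == comp]
    lk <- links$id[comp_of_link == comp]
    lv <- intersect(nd, leaf_ids)
    lc <- do.call(rbind, map(lv, ~ node_com(graph, .x)))
    if (is.null(lc)) lc <- matrix(double(), 0L, 3L)
    tibble(id = s, link_ids = list(sort(lk)), node_ids = list(sort(nd)),
           leaf_node_ids = list(sort(lv)), leaf_coords = list(lc),
           n_links = length(lk), n_leaves = length(lv))
  })
  out <- bind_rows(rows)
  structure(out, spacing = graph$spacing, class = c("subtree_set", class(out)))
}

#' Peripheral matching: inter-subtree matching strength (IMS)
#'
#' Arteries and veins approach each other at the periphery (alveolar sacs)
#' without connecting, so nearby leaf tips of two different subtrees are
#' evidence that the subtrees belong to opposite classes. For every leaf of
#' every subtree, the nearest leaf belonging to a different subtree is
#' found; when that distance is within `d_max` the pair's IMS is
#' incremented. Matching is directional and accumulated both ways, so a
#' mutual nearest pair contributes 2.
#'
#' @param subtrees A `subtree_set` from [build_subtrees()].
#' @param d_max Matching radius in physical units (mm).
#' @param spacing Per-axis voxel size; defaults to the spacing recorded in
#'   `subtrees`.
#' @return A tibble (class `ims_matrix`) with columns `subtree_i`,
#'   `subtree_j` (`i < j`) and integer `ims`, only for nonzero entries.
#'   `attr(, "n_subtrees")` records the universe size.
#' @export
peripheral_match <- function(subtrees, d_max = 10, spacing = NULL) {
  if (d_max <= 0) abort("`d_max` must be > 0")
  spacing <- spacing %||% attr(subtrees, "spacing") %||% c(1, 1, 1)
  leaves <- bind_rows(map(seq_len(nrow(subtrees)), function(r) {
    lc <- subtrees$leaf_coords[[r]]
    if (nrow(lc) == 0L) return(NULL)
    tibble(subtree = subtrees$id[r], i = lc[, 1], j = lc[, 2], k = lc[, 3])
  }))
  counts <- new.env(parent = emptyenv())
  if (!is.null(leaves) && nrow(leaves) > 0L && length(unique(leaves$subtree)) > 1L) {
    xyz <- as.matrix(leaves[, c("i", "j", "k")])
    dm <- cross_dist(xyz, xyz, spacing)
    same <- outer(leaves$subtree, leaves$subtree, `==`)
    dm[same] <- Inf
    for (r in seq_len(nrow(leaves))) {
      jn <- which.min(dm[r, ])
      if (is.finite(dm[r, jn]) && dm[r, jn] <= d_max) {
        a <- leaves$subtree[r]; b <- leaves$subtree[jn]
        key <- paste(min(a, b), max(a, b), sep = "_")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  out <- if (length(keys) == 0L) {
    tibble(subtree_i = integer(), subtree_j = integer(), ims = integer())
  } else {
    parts <- do.call(rbind, strsplit(keys, "_"))
    tibble(subtree_i = as.integer(parts[, 1]),
           subtree_j = as.integer(parts[, 2]),
           ims = map_int(keys, ~ as.integer(counts[[.x]])))
  }
  out <- arrange(out, .data$subtree_i, .data$subtree_j)
  structure(out, n_subtrees = nrow(subtrees),
            subtree_ids = subtrees$id,
            class = c("ims_matrix", class(out)))
}

#' @export
as.matrix.ims_matrix <- function(x, ...) {
  ids <- attr(x, "subtree_ids") %||% sort(unique(c(x$subtree_i, x$subtree_j)))
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(x) > 0L) {
    ii <- match(x$subtree_i, ids); jj <- match(x$subtree_j, ids)
    m[cbind(ii, jj)] <- x$ims
    m[cbind(jj, ii)] <- x$ims
  }
  m
}

#' Infer the two vessel classes from IMS relations
#'
#' Every IMS entry at or above `ims_min` is a "different class" constraint.
#' The constraint graph is two-coloured breadth-first (parity colouring);
#' odd cycles are resolved by repeatedly dropping the conflicting edge with
#' the smallest IMS (ties: smallest id pair) and recolouring. Subtrees
#' related only through a chain (no direct edge to the component seed side)
#' are classified by the indirect rule and marked so. Subtrees with no
#' retained relation stay unassigned. Component-local colourings are
#' canonicalised so the smallest subtree id in each component is `class0`.
#'
#' @param ims An `ims_matrix` from [peripheral_match()].
#' @param ims_min Minimum IMS for a relation to count (>= 1).
#' @return A tibble (class `class_assignment`): `subtree_id`, `class`
#'   (`class0`/`class1`/`unassigned`), `provenance` (`direct`/`indirect`/
#'   `unassigned`). Dropped edges are in `attr(, "dropped_edges")`.
#' @export
infer_two_classes <- function(ims, ims_min = 2L) {
  if (ims_min < 1L) abort("`ims_min` must be >= 1")
  ids <- attr(ims, "subtree_ids") %||% sort(unique(c(ims$subtree_i, ims$subtree_j)))
  edges <- filter(as_tibble(ims), .data$ims >= ims_min)
  dropped <- tibble(subtree_i = integer(), subtree_j = integer(),
                    ims = integer(), reason = character())

  color_once <- function(edges) {
    color <- setNames(rep(NA_integer_, length(ids)), ids)
    depth <- setNames(rep(NA_integer_, length(ids)), ids)
    nbrs <- function(v) sort(unique(c(edges$subtree_j[edges$subtree_i == v],
                                      edges$subtree_i[edges$subtree_j == v])))
    touched <- sort(unique(c(edges$subtree_i, edges$subtree_j)))
    for (seed in touched) {
      key <- as.character(seed)
      if (!is.na(color[key])) next
      color[key] <- 0L; depth[key] <- 0L
      queue <- seed
      while (length(queue) > 0L) {
        v <- queue[1]; queue <- queue[-1]
        for (w in nbrs(v)) {
          wk <- as.character(w)
          if (is.na(color[wk])) {
            color[wk] <- 1L - color[[as.character(v)]]
            depth[wk] <- depth[[as.character(v)]] + 1L
            queue <- c(queue, w)
          }
        }
      }
    }
    conflicts <- which(color[as.character(edges$subtree_i)] ==
                         color[as.character(edges$subtree_j)])
    list(color = color, depth = depth, conflicts = conflicts)
  }

  repeat {
    res <- color_once(edges)
    if (length(res$conflicts) == 0L) break
    bad <- edges[res$conflicts, ]
    bad <- arrange(bad, .data$ims, .data$subtree_i, .data$subtree_j)
    drop_row <- bad[1, ]
    dropped <- bind_rows(dropped, mutate(drop_row, reason = "parity_conflict"))
    edges <- filter(edges, !(.data$subtree_i == drop_row$subtree_i &
                               .data$subtree_j == drop_row$subtree_j))
  }

  color <- res$color; depth <- res$depth
  # canonicalise: within each component the smallest id gets class0
  if (nrow(edges) > 0L) {
    touched <- sort(unique(c(edges$subtree_i, edges$subtree_j)))
    g <- igraph::make_empty_graph(n = length(touched), directed = FALSE)
    g <- igraph::add_edges(g, rbind(match(edges$subtree_i, touched),
                                    match(edges$subtree_j, touched)))
    memb <- igraph::components(g)$membership
    for (cid in unique(memb)) {
      members <- touched[memb == cid]
      seed <- min(members)
      if (color[[as.character(seed)]] == 1L) {
        mk <- as.character(members)
        color[mk] <- 1L - color[mk]
      }
    }
  }

  cls <- map_chr(as.character(ids), function(key) {
    if (is.na(color[[key]])) "unassigned"
    else if (color[[key]] == 0L) "class0" else "class1"
  })
  prov <- map_chr(as.character(ids), function(key) {
    if (is.na(color[[key]])) "unassigned"
    else if (depth[[key]] >= 2L) "indirect" else "direct"
  })
  out <- tibble(subtree_id = ids, class = cls, provenance = prov)
  structure(out, dropped_edges = dropped,
            class = c("class_assignment", class(out)))
}
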