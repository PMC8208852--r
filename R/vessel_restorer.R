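#' Paint skeleton voxels with their subtree's class
#'
#' Produces a labelled volume (`0` background, `1` class0, `2` class1)
#' covering exactly the skeleton voxels of assigned subtrees. Voxels of
#' unassigned subtrees remain 0 and are reported via a message.
#'
#' @param graph An adhesion-split `vessel_graph`.
#' @param assignment A `class_assignment` from [infer_two_classes()] (or
#'   after [assign_unlabeled_subtrees()]).
#' @param subtrees The `subtree_set` the assignment refers to.
#' @param shape Grid dimensions; defaults to the graph's shape.
#' @return An integer 3-D array with the graph's spacing; the number of
#'   painted voxels is in `attr(, "n_painted")`.
#' @export
paint_skeleton <- function(graph, assignment, subtrees, shape = graph$shape) {
  shape <- as.integer(shape)
  lab <- array(0L, shape)
  class_code <- c(class0 = 1L, class1 = 2L, unassigned = 0L)
  n_unassigned <- 0L
  for (r in seq_len(nrow(subtrees))) {
    sid <- subtrees$id[r]
    cls <- assignment$class[match(sid, assignment$subtree_id)]
    code <- class_code[[cls %||% "unassigned"]]
    if (code == 0L) { n_unassigned <- n_unassigned + 1L; next }
    for (l in subtrees$link_ids[[r]]) {
      pts <- graph$links$points[[match(l, graph$links$id)]]
      if (nrow(pts) > 0L) {
        if (any(pts > rep(shape, each = nrow(pts))) || any(pts < 1L))
          abort("graph voxel indices fall outside `shape`")
        lab[pts] <- code
      }
    }
    for (nd in subtrees$node_ids[[r]]) {
      m <- graph$nodes$idx[[match(nd, graph$nodes$id)]]
      if (nrow(m) > 0L) {
        if (any(m > rep(shape, each = nrow(m))) || any(m < 1L))
          abort("graph voxel indices fall outside `shape`")
        lab[m] <- code
      }
    }
  }
  if (n_unassigned > 0L)
    inform(sprintf("%d unassigned subtree(s) left unpainted", n_unassigned))
  out <- vox_volume(lab, graph$spacing)
  attr(out, "n_painted") <- sum(lab > 0L)
  out
}

# One level-synchronous growth pass on a single slice. `m` is the logical
# mask matrix, `l` the integer label matrix. Level-synchronous dilation is
# exactly breadth-first geodesic growth under 8-connectivity; a voxel
# reached by both labels in the same round (equal geodesic distance) takes
# class0 (label 1).
grow_slice <- function(m, l) {
  repeat {
    f1 <- dilate8(l == 1L) & m & l == 0L
    f2 <- dilate8(l == 2L) & m & l == 0L
    if (!any(f1) && !any(f2)) break
    l[f1 & !f2] <- 1L
    l[f2 & !f1] <- 2L
    l[f1 & f2] <- 1L
  }
  l
}

# 8-connected binary dilation of a logical matrix by one voxel.
dilate8 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  z <- logical(nc)
  up <- rbind(x[-1, , drop = FALSE], z)
  dn <- rbind(z, x[-nr, , drop = FALSE])
  out <- out | up | dn
  zc <- logical(nr)
  lf <- cbind(out[, -1, drop = FALSE], zc)
  rt <- cbind(zc, out[, -nc, drop = FALSE])
  out | lf | rt
}

#' Restore full vessel lumina from labelled skeleton seeds
#'
#' Each slice along `axis` is processed independently: labelled skeleton
#' voxels in the slice act as seeds, and labels grow over the 8-connected
#' in-slice foreground of the vessel mask. A voxel reachable by both labels
#' takes the label of the geodesically (in-slice, within-mask) nearest
#' seed; exact ties go to class0. Mask voxels in slices without a seed, or
#' unreachable from any seed, stay 0 and are counted in the coverage
#' report.
#'
#' @param mask Binary vessel segmentation (3-D array).
#' @param labeled_skeleton Integer volume from [paint_skeleton()].
#' @param axis Slice axis (default 3, the axial axis).
#' @return The restored labelled volume; `attr(, "coverage")` is a
#'   per-slice tibble (mask/labelled/unreached counts, seeded flag).
#' @export
restore_volume <- function(mask, labeled_skeleton, axis = 3L) {
  mask <- as_binary_volume(mask)
  if (!identical(dim(mask), dim(labeled_skeleton)))
    abort("`mask` and `labeled_skeleton` shapes differ")
  if (!axis %in% 1:3) abort("`axis` must be 1, 2 or 3")
  shape <- dim(mask)
  out <- array(0L, shape)
  slice_index <- function(s) switch(axis,
    list(s, TRUE, TRUE), list(TRUE, s, TRUE), list(TRUE, TRUE, s))
  cov <- vector("list", shape[axis])
  for (s in seq_len(shape[axis])) {
    ix <- slice_index(s)
    m <- do.call(`[`, c(list(mask), ix, list(drop = TRUE)))
    l <- do.call(`[`, c(list(labeled_skeleton), ix, list(drop = TRUE)))
    l[!m & l > 0L] <- 0L      # seeds outside the mask cannot grow
    seeded <- any(l > 0L)
    n_mask <- sum(m)
    if (seeded && n_mask > 0L) {
      l <- grow_slice(m, l)
      out <- do.call(`[<-`, c(list(out), ix, list(l)))
    }
    n_lab <- sum(l > 0L)
    cov[[s]] <- tibble(slice = s, n_mask = n_mask, n_labeled = if (seeded) n_lab else 0L,
                       n_unreached = if (seeded) n_mask - n_lab else n_mask,
                       seeded = seeded)
  }
  res <- vox_volume(out, voxel_spacing(mask))
  attr(res, "coverage") <- bind_rows(cov)
  res
}

#' Coverage summary of a restored volume
#'
#' @param restored Output of [restore_volume()].
#' @return A one-row tibble: total mask voxels, labelled voxels, coverage
#'   fraction, unreached voxels in seeded slices, and unseeded-slice count.
#' @export
restore_coverage <- function(restored) {
  cov <- attr(restored, "coverage")
  if (is.null(cov)) abort("`restored` carries no coverage report")
  summarise(cov,
    n_mask = sum(.data$n_mask),
    n_labeled = sum(.data$n_labeled),
    coverage = ifelse(sum(.data$n_mask) > 0, sum(.data$n_labeled) / sum(.data$n_mask), NA_real_),
    n_unreached_seeded = sum(.data$n_unreached[.data$seeded]),
    n_unseeded_slices = sum(!.data$seeded & .data$n_mask > 0L))
}
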