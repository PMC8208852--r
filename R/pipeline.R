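#' Pipeline configuration
#'
#' Collects the tunable parameters of the separation pipeline with their
#' defaults: adhesion splitting representative mode, peripheral-matching
#' radius `d_max` (mm) and minimum matching strength `ims_min`, path-vote
#' weights, restore slice axis and the lung-split axis used in evaluation.
#'
#' @param adhesion_mode `"endpoint"` or `"k_step"`.
#' @param adhesion_k Step count for `k_step` mode.
#' @param d_max Peripheral-matching radius (mm).
#' @param ims_min Minimum IMS for a different-class relation.
#' @param w_a,w_d Path-vote angle / diameter weights.
#' @param bridge_dist Bridge distance for leftover subtrees (mm); defaults
#'   to `d_max`.
#' @param restore_axis Slice axis for 2-D region growing.
#' @param lung_axis Axis split mid-sagittally for per-lung reporting.
#' @return A named list (class `av_config`).
#' @export
av_config <- function(adhesion_mode = "endpoint", adhesion_k = 5L,
                      d_max = 10, ims_min = 2L, w_a = 1, w_d = 1,
                      bridge_dist = NULL, restore_axis = 3L, lung_axis = 1L) {
  if (d_max <= 0 || ims_min < 1L) abort("thresholds must be positive")
  structure(list(adhesion_mode = adhesion_mode, adhesion_k = adhesion_k,
                 d_max = d_max, ims_min = as.integer(ims_min),
                 w_a = w_a, w_d = w_d, bridge_dist = bridge_dist %||% d_max,
                 restore_axis = as.integer(restore_axis),
                 lung_axis = as.integer(lung_axis)),
            class = "av_config")
}

#' Run the full artery-vein separation pipeline
#'
#' Stages, in order: graph construction, adhesion splitting, subtree
#' grouping, peripheral matching, two-class inference, skeleton painting,
#' per-slice lumen restoration, class statistics, artery/vein call,
#' leftover-subtree recovery by path vote, final repaint/restore with
#' vessel labels, and (when `gold` is given) branch-level evaluation.
#'
#' @param mask Binary vessel segmentation (3-D array).
#' @param skeleton Unit-width binary centerline skeleton (same shape).
#' @param gold Optional gold labelled volume (1 = artery, 2 = vein).
#' @param config An [av_config()].
#' @return An `av_separation` object: graph, subtrees, `ims`, `assignment`,
#'   `av_map`, `stats`, `volume` (final labels, 1 = artery, 2 = vein),
#'   `coverage`, `link_vessels`, `evaluation` (or `NULL`) and a `manifest`
#'   of per-stage entity counts.
#' @export
separate_vessels <- function(mask, skeleton, gold = NULL, config = av_config()) {
  mask <- as_binary_volume(mask)
  skeleton <- as_binary_volume(skeleton)
  if (!identical(dim(mask), dim(skeleton)))
    abort("`mask` and `skeleton` shapes differ")
  manifest <- list()
  tick <- function(stage, ...) manifest[[stage]] <<- list(...)

  graph0 <- build_graph(skeleton)
  tick("build_graph", n_nodes = nrow(graph0$nodes), n_links = nrow(graph0$links),
       n_adhesion_nodes = length(detect_adhesion_nodes(graph0)))

  graph <- split_adhesions(graph0, mode = config$adhesion_mode, k = config$adhesion_k)
  tick("split_adhesions", n_nodes = nrow(graph$nodes), n_links = nrow(graph$links),
       n_residual = sum(graph$nodes$residual),
       n_unresolved_deg4 = length(detect_adhesion_nodes(graph)))

  subtrees <- build_subtrees(graph)
  tick("build_subtrees", n_subtrees = nrow(subtrees))

  ims <- peripheral_match(subtrees, d_max = config$d_max)
  tick("peripheral_match", n_pairs = nrow(ims))

  assignment <- infer_two_classes(ims, ims_min = config$ims_min)
  tick("infer_two_classes",
       n_assigned = sum(assignment$class != "unassigned"),
       n_dropped_edges = nrow(attr(assignment, "dropped_edges")))

  painted <- suppressMessages(paint_skeleton(graph, assignment, subtrees))
  restored <- restore_volume(mask, painted, axis = config$restore_axis)
  stats <- suppressWarnings(class_stats(restored, graph, assignment, subtrees))
  if (any(is.na(stats$volume_per_length))) {
    # degenerate run (a class received no subtree): no anatomical call is
    # possible; vessels stay unlabelled but the pipeline completes
    warn("artery/vein call undefined: a class has no centerline")
    av_map <- tibble(class = stats$class, vessel = NA_character_)
  } else {
    av_map <- assign_artery_vein(stats)
  }
  tick("classify", vein_class = av_map$class[which(av_map$vessel == "vein")])

  assignment2 <- assign_unlabeled_subtrees(
    graph, subtrees, assignment, mask,
    w_a = config$w_a, w_d = config$w_d, bridge_dist = config$bridge_dist)
  n_recovered <- sum(assignment2$provenance == "path_vote")
  tick("assign_unlabeled", n_recovered = n_recovered,
       n_still_unassigned = sum(assignment2$class == "unassigned"))

  if (n_recovered > 0L) {
    painted <- suppressMessages(paint_skeleton(graph, assignment2, subtrees))
    restored <- restore_volume(mask, painted, axis = config$restore_axis)
  }

  # relabel classes as vessels: artery = 1, vein = 2
  class_code <- c(class0 = 1L, class1 = 2L)
  vessel_of_class <- setNames(av_map$vessel, av_map$class)
  vol <- array(0L, dim(mask))
  for (cls in c("class0", "class1")) {
    if (is.na(vessel_of_class[[cls]])) next
    code_in <- class_code[[cls]]
    code_out <- c(artery = 1L, vein = 2L)[[vessel_of_class[[cls]]]]
    vol[restored == code_in] <- code_out
  }
  vol <- vox_volume(vol, voxel_spacing(mask))
  attr(vol, "coverage") <- attr(restored, "coverage")

  link_vessels <- bind_rows(map(seq_len(nrow(subtrees)), function(r) {
    cls <- assignment2$class[match(subtrees$id[r], assignment2$subtree_id)]
    vessel <- if (cls == "unassigned") NA_character_ else vessel_of_class[[cls]]
    tibble(link_id = subtrees$link_ids[[r]], subtree_id = subtrees$id[r],
           class = cls, vessel = vessel)
  }))

  evaluation <- NULL
  if (!is.null(gold)) {
    evaluation <- evaluate_separation(graph, link_vessels, gold,
                                      lung_axis = config$lung_axis)
    ov <- evaluation[evaluation$side == "overall", ]
    tick("evaluate", total = ov$total_branches, misjudged = ov$misjudged_branches,
         accuracy = ov$accuracy_percent)
  }

  structure(list(
    graph = graph, graph_raw = graph0, subtrees = subtrees, ims = ims,
    assignment = assignment2, av_map = av_map, stats = stats,
    volume = vol, coverage = restore_coverage(vol),
    link_vessels = link_vessels, evaluation = evaluation,
    manifest = manifest, config = config
  ), class = "av_separation")
}

#' @export
print.av_separation <- function(x, ...) {
  vein <- x$av_map$class[which(x$av_map$vessel == "vein")]
  cat(sprintf("<av_separation> %d links in %d subtrees; vein = %s\n",
              nrow(x$graph$links), nrow(x$subtrees),
              if (length(vein)) vein else "<undetermined>"))
  if (!is.null(x$evaluation)) {
    ov <- x$evaluation[x$evaluation$side == "overall", ]
    cat(sprintf("  branch accuracy %.2f%% (%d/%d misjudged)\n",
                ov$accuracy_percent, ov$misjudged_branches, ov$total_branches))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-branch summary of a separation run
#'
#' @param x An `av_separation`.
#' @param ... Unused.
#' @return A tibble with one row per link: subtree, class, vessel, and
#'   (when a gold standard was supplied) gold vessel and correctness.
#' @export
tidy.av_separation <- function(x, ...) {
  out <- x$link_vessels
  if (!is.null(x$evaluation)) {
    br <- attr(x$evaluation, "branches")
    out <- left_join(out, select(br, link_id, side, gold, correct), by = "link_id")
  }
  out
}

#' One-row summary of a separation run
#'
#' @param x An `av_separation`.
#' @param ... Unused.
#' @return A one-row tibble: entity counts per stage, the vein class, the
#'   lumen coverage fraction, and overall branch accuracy when evaluated.
#' @export
glance.av_separation <- function(x, ...) {
  m <- x$manifest
  tibble(
    n_links = nrow(x$graph$links),
    n_subtrees = nrow(x$subtrees),
    n_adhesion_nodes = m$build_graph$n_adhesion_nodes,
    n_unresolved_deg4 = m$split_adhesions$n_unresolved_deg4,
    n_assigned = sum(x$assignment$class != "unassigned"),
    n_path_vote = sum(x$assignment$provenance == "path_vote"),
    vein_class = x$av_map$class[which(x$av_map$vessel == "vein")][1] %||% NA_character_,
    coverage = x$coverage$coverage,
    accuracy_percent = if (is.null(x$evaluation)) NA_real_
      else x$evaluation$accuracy_percent[x$evaluation$side == "overall"]
  )
}

#' Maximum-intensity-style projection plot of a separation result
#'
#' Projects the final labelled volume along one axis and renders artery and
#' vein voxels in the conventional red/blue.
#'
#' @param object An `av_separation` (or a labelled volume for `plot_labeled_volume`).
#' @param axis Projection axis (default 3: head-on view of the axial stack).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.av_separation <- function(object, axis = 3L, ...) {
  plot_labeled_volume(object$volume, axis = axis)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.av_separation
#' @param vol An integer labelled volume (1 = artery, 2 = vein).
#' @export
plot_labeled_volume <- function(vol, axis = 3L) {
  keep <- setdiff(1:3, axis)
  art <- apply(vol == 1L, keep, any)
  vei <- apply(vol == 2L, keep, any)
  df <- bind_rows(
    as_proj_df(art, "artery"),
    as_proj_df(vei, "vein")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$vessel)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(artery = "#c0392b", vein = "#2e5fa3")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste("axis", keep[1]), y = paste("axis", keep[2]),
                  fill = NULL, title = "Artery-vein separation (projection)") +
    ggplot2::theme_minimal()
}

as_proj_df <- function(m, vessel) {
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  tibble(a = w[, 1], b = w[, 2], vessel = vessel)
}

#' Write the artifacts of a separation run to a directory
#'
#' Writes the final labelled volume (NIfTI, artery = 1, vein = 2), the IMS
#' matrix and class assignment as CSV, the per-branch table as CSV, the
#' coverage report and manifest as JSON, and the evaluation table (when
#' present) as CSV.
#'
#' @param result An `av_separation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_separation <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(result$volume, file.path(dir, "labels.nii.gz"))
  utils::write.csv(as_tibble(result$ims), file.path(dir, "ims.csv"), row.names = FALSE)
  utils::write.csv(as_tibble(result$assignment), file.path(dir, "assignment.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(result), file.path(dir, "branches.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(coverage = result$coverage, manifest = result$manifest),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$evaluation))
    utils::write.csv(as_tibble(result$evaluation), file.path(dir, "accuracy.csv"),
                     row.names = FALSE)
  invisible(dir)
}
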