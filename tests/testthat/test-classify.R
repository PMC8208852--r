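test_that("class statistics of a straight tube are exact", {
  # tube along axis 3, radius 2, centerline 20 voxels, isotropic 1 mm
  m <- array(FALSE, c(11, 11, 24))
  sk <- array(0L, dim(m))
  for (k in 3:22) {
    for (i in 1:11) for (j in 1:11)
      if ((i - 6)^2 + (j - 6)^2 <= 4) m[i, j, k] <- TRUE
    sk[6, 6, k] <- 1L
  }
  g <- build_graph(sk)
  st <- build_subtrees(g)
  asg <- infer_two_classes(peripheral_match(st, d_max = 5), ims_min = 1)
  asg$class <- "class0"   # single tube: assign manually
  lab <- paint_skeleton(g, asg, st)
  r <- restore_volume(m, lab)
  cs <- suppressWarnings(class_stats(r, g, asg, st))
  c0 <- cs[cs$class == "class0", ]
  expect_equal(c0$centerline_length_mm, 19)
  expect_equal(c0$volume_mm3, sum(m))
  expect_equal(c0$volume_per_length, sum(m) / 19)
  expect_true(is.na(cs$volume_per_length[cs$class == "class1"]))
})

test_that("the bulkier class per unit length is called the vein", {
  mk <- function(v0, v1) tibble::tibble(
    class = c("class0", "class1"), n_voxels = 1L, volume_mm3 = 1,
    centerline_length_mm = 1, volume_per_length = c(v0, v1))
  a <- assign_artery_vein(mk(10, 5))
  expect_equal(a$vessel[a$class == "class0"], "vein")
  b <- assign_artery_vein(mk(5, 10))
  expect_equal(b$vessel[b$class == "class1"], "vein")
  expect_warning(tie <- assign_artery_vein(mk(7, 7)), "tie")
  expect_equal(tie$vessel[tie$class == "class0"], "vein")
  expect_error(assign_artery_vein(mk(NA, 5)), "undefined")
  # antisymmetry
  sw <- mk(10, 5); sw$volume_per_length <- rev(sw$volume_per_length)
  expect_equal(assign_artery_vein(sw)$vessel, rev(a$vessel))
})

test_that("find_root picks the thickest node, with override support", {
  # tapering tube: radius shrinks along axis 3
  m <- array(FALSE, c(15, 15, 30))
  sk <- array(0L, dim(m))
  for (k in 3:27) {
    r <- 5 - 4 * (k - 3) / 24
    for (i in 1:15) for (j in 1:15)
      if ((i - 8)^2 + (j - 8)^2 <= r^2) m[i, j, k] <- TRUE
    sk[8, 8, k] <- 1L
  }
  g <- build_graph(sk)
  root <- find_root(g, g$links$id, m)
  expect_equal(avsep:::node_com(g, root)[3], 3)   # thick trunk end
  # user override picks the nearest node instead
  root2 <- find_root(g, g$links$id, m, override = c(8, 8, 27))
  expect_equal(avsep:::node_com(g, root2)[3], 27)
  expect_error(find_root(g, integer(), m), "no links")
})

test_that("leftover subtrees are recovered by their neighbours' class", {
  case <- small_phantom(seed = 105)
  res <- separate_vessels(case$mask, case$skeleton, gold = case$gt_labels)
  expect_gte(sum(res$assignment$provenance == "path_vote"), 1L)
  expect_equal(sum(res$assignment$class == "unassigned"), 0L)
  # and the recovered subtree matches the planted class (perfect accuracy
  # implies every path-vote call was right)
  expect_gte(res$evaluation$accuracy_percent[res$evaluation$side == "overall"], 90)
})

test_that("a subtree with no spatial neighbour stays unassigned", {
  # two crossing tubes plus one far-away floating segment
  v <- fix_x()
  v2 <- array(0L, c(60, 60, 5))
  v2[1:21, 1:21, ] <- v
  v2[50:55, 50, 3] <- 1L                 # floating spur, > 10 voxels away
  m <- v2 > 0
  gs <- split_adhesions(build_graph(v2))
  st <- build_subtrees(gs)
  asg <- infer_two_classes(peripheral_match(st, d_max = 5), ims_min = 1)
  out <- assign_unlabeled_subtrees(gs, st, asg, m, bridge_dist = 10)
  spur <- st$id[vapply(seq_len(nrow(st)),
                       function(r) all(st$leaf_coords[[r]][, 1] > 40), logical(1))]
  expect_equal(out$class[out$subtree_id == spur], "unassigned")
})

test_that("accuracy arithmetic is exact and monotone", {
  expect_equal(accuracy_from_counts(536, 89), 83.40)
  expect_equal(accuracy_from_counts(472, 74), 84.32)
  expect_equal(accuracy_from_counts(123, 0), 100.00)
  expect_error(accuracy_from_counts(0, 0), "total")
  expect_error(accuracy_from_counts(10, 11), "misjudged")
  accs <- accuracy_from_counts(rep(500, 6), c(0, 10, 50, 100, 250, 500))
  expect_true(all(diff(accs) < 0))
})

test_that("evaluation agrees with a link-by-link brute-force comparison", {
  case <- small_phantom(seed = 106)
  res <- separate_vessels(case$mask, case$skeleton, gold = case$gt_labels)
  ev <- res$evaluation
  # independent recount from the per-branch table
  br <- attr(ev, "branches")
  scored <- br[!is.na(br$gold), ]
  n_mis <- sum(is.na(scored$predicted) | scored$gold != scored$predicted)
  ov <- ev[ev$side == "overall", ]
  expect_equal(ov$misjudged_branches, n_mis)
  expect_equal(ov$accuracy_percent,
               round(100 * (nrow(scored) - n_mis) / nrow(scored), 2))
  # per-side totals partition the overall count
  expect_equal(sum(ev$total_branches[ev$side != "overall"]), ov$total_branches)
})

test_that("perfect and single-flip predictions score as expected", {
  case <- small_phantom(seed = 107)
  g <- split_adhesions(build_graph(case$skeleton))
  # build gold-exact link classes from the ground truth itself
  lv <- tibble::tibble(link_id = g$links$id, vessel = vapply(
    seq_len(nrow(g$links)), function(r) {
      pts <- g$links$points[[r]]
      if (nrow(pts) == 0) return(NA_character_)
      labs <- case$gt_labels[pts]
      labs <- labs[labs > 0]
      if (!length(labs)) return(NA_character_)
      c("artery", "vein")[as.integer(names(which.max(table(labs))))]
    }, character(1)))
  ev <- evaluate_separation(g, lv, case$gt_labels)
  expect_equal(ev$accuracy_percent[ev$side == "overall"], 100)
  # flip one link
  lv2 <- lv
  flip <- which(!is.na(lv2$vessel))[1]
  lv2$vessel[flip] <- setdiff(c("artery", "vein"), lv2$vessel[flip])
  ev2 <- evaluate_separation(g, lv2, case$gt_labels)
  expect_equal(ev2$misjudged_branches[ev2$side == "overall"], 1L)
  # gold covering too little skeleton errors
  sparse_gold <- case$gt_labels
  sparse_gold[] <- 0L
  expect_error(evaluate_separation(g, lv, sparse_gold), "cover")
})
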