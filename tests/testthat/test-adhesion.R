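test_that("bifurcations are not adhesions; crossings are", {
  expect_length(detect_adhesion_nodes(build_graph(fix_y())), 0L)
  gx <- build_graph(fix_x())
  adh <- detect_adhesion_nodes(gx)
  expect_length(adh, 1L)
  expect_equal(gx$nodes$degree[match(adh, gx$nodes$id)], 4L)
})

test_that("branch representatives honour endpoint and k_step modes", {
  v <- fix_line(10)
  g <- build_graph(v)
  leafs <- g$nodes$id[g$nodes$ep == 1L]
  n1 <- leafs[1]
  far <- setdiff(leafs, n1)
  l <- g$links$id[1]
  expect_equal(branch_representative(g, n1, l, "endpoint"),
               avsep:::node_com(g, far))
  pts <- g$links$points[[1]]
  from_start <- g$links$n_start[1] == n1
  k3 <- branch_representative(g, n1, l, "k_step", k = 3)
  expect_equal(as.numeric(k3),
               as.numeric(if (from_start) pts[3, ] else pts[nrow(pts) - 2, ]))
  k50 <- branch_representative(g, n1, l, "k_step", k = 50)
  expect_equal(as.numeric(k50),
               as.numeric(if (from_start) pts[nrow(pts), ] else pts[1, ]))
  expect_error(branch_representative(g, n1, 999L), "no link")
})

test_that("branch_angle matches geometry and its invariances hold", {
  expect_equal(branch_angle(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(branch_angle(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(branch_angle(c(1, 2, 3), c(4, 2, 3), c(1, 6, 3)),
               oracle_angle(c(1, 2, 3), c(4, 2, 3), c(1, 6, 3)))
  expect_error(branch_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), "zero-length")

  withr::with_seed(7, {
    for (i in 1:50) {
      P <- stats::rnorm(3); A <- P + stats::rnorm(3); B <- P + stats::rnorm(3)
      th <- branch_angle(P, A, B)
      expect_gte(th, 0); expect_lte(th, 180)
      expect_equal(branch_angle(P, B, A), th)
      shift <- stats::rnorm(3)
      expect_equal(branch_angle(P + shift, A + shift, B + shift), th,
                   tolerance = 1e-9)
      s <- stats::runif(1, 0.1, 5)
      expect_equal(branch_angle(P * s, A * s, B * s), th, tolerance = 1e-6)
      R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      expect_equal(branch_angle(c(R %*% P), c(R %*% A), c(R %*% B)), th,
                   tolerance = 1e-6)
    }
  })
})

test_that("best_pairing pairs collinear arms of a symmetric crossing", {
  gx <- build_graph(fix_x())
  bp <- best_pairing(gx, detect_adhesion_nodes(gx))
  expect_equal(bp$score, 360, tolerance = 1e-6)
  expect_length(bp$pairs, 2L)
  expect_length(bp$leftover, 0L)
})

test_that("best_pairing picks opposed arms in an asymmetric star", {
  # arms along +x, -x, +y, +z: the collinear pair must be fused together
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  v <- fix_star(dirs, len = 8, size = 21)
  g <- build_graph(v)
  nd <- detect_adhesion_nodes(g)
  bp <- best_pairing(g, nd)
  # identify links by their far-leaf direction
  far_dir <- function(l) {
    far <- setdiff(c(g$links$n_start[match(l, g$links$id)],
                     g$links$n_end[match(l, g$links$id)]), nd)
    d <- avsep:::node_com(g, far) - avsep:::node_com(g, nd)
    which.max(abs(d)) * sign(d[which.max(abs(d))])
  }
  pair_dirs <- lapply(bp$pairs, function(p) sort(vapply(p, far_dir, numeric(1))))
  expect_true(list(c(-1, 1)) %in% pair_dirs)   # +x with -x
  expect_error(best_pairing(build_graph(fix_y()),
                            build_graph(fix_y())$nodes$id[1]), "degree")
})

test_that("degree-4 pairing matches exhaustive enumeration on random stars", {
  withr::with_seed(11, {
    checked <- 0
    while (checked < 60) {
      v <- fix_star(rand_dirs(4, min_sep = 35), len = 9, size = 31)
      g <- build_graph(v)
      nd <- detect_adhesion_nodes(g)
      if (length(nd) != 1L || g$nodes$degree[match(nd, g$nodes$id)] != 4L) next
      P <- avsep:::node_com(g, nd)
      ids <- g$nodes$link_ids[[match(nd, g$nodes$id)]]
      reps <- lapply(ids, function(l) branch_representative(g, nd, l, "endpoint"))
      oc <- oracle_pairing4(P, reps, ids)
      if (oc$gap < 1e-6) next                  # skip genuinely tied layouts
      bp <- best_pairing(g, nd)
      expect_equal(lapply(bp$pairs, sort), oc$pairs)
      expect_equal(bp$score, oc$score, tolerance = 1e-9)
      checked <- checked + 1
    }
  })
})

test_that("split_adhesions resolves the X and is a no-op on the Y", {
  v <- fix_x()
  gs <- split_adhesions(build_graph(v))
  expect_equal(nrow(gs$links), 2L)
  expect_equal(sum(gs$nodes$ep), 4L)
  expect_length(detect_adhesion_nodes(gs), 0L)
  expect_true(all(validate_graph(gs, v)$checks$pass))

  gy <- build_graph(fix_y())
  gy2 <- split_adhesions(gy)
  expect_equal(nrow(gy2$links), nrow(gy$links))
  expect_equal(nrow(gy2$nodes), nrow(gy$nodes))
})

test_that("splitting conserves voxels and leaves across the phantom family", {
  for (s in 1:3) {
    case <- small_phantom(seed = 100 + s)
    g <- build_graph(case$skeleton)
    gs <- split_adhesions(g)
    expect_length(detect_adhesion_nodes(gs), 0L)
    vg <- validate_graph(gs, case$skeleton)
    expect_true(vg$checks$pass[vg$checks$invariant == "conservation"])
    # leaf count is preserved except where a residual node of an
    # odd-degree adhesion is left with a single unpaired link
    new_leaf_residuals <- sum(gs$nodes$residual & gs$nodes$degree == 1L)
    expect_equal(sum(gs$nodes$ep), sum(g$nodes$ep) + new_leaf_residuals)
  }
})

test_that("split decisions are logged to the CSV audit file", {
  p <- withr::local_tempfile(fileext = ".csv")
  split_adhesions(build_graph(fix_x()), audit = p)
  aud <- utils::read.csv(p)
  expect_equal(nrow(aud), 2L)
  expect_true(all(aud$resolved))
  expect_equal(sum(aud$angle), 360, tolerance = 1e-6)
})
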