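test_that("voxel degree counts 26-neighbours, with domain errors", {
  v <- fix_line(3)
  expect_equal(voxel_degree(v, c(4, 3, 3)), 2)        # path interior
  expect_equal(voxel_degree(fix_y(), c(11, 11, 3)), 3) # bifurcation centre
  iso <- array(0L, c(5, 5, 5)); iso[3, 3, 3] <- 1L
  expect_equal(voxel_degree(iso, c(3, 3, 3)), 0)
  expect_error(voxel_degree(v, c(1, 1, 1)), "background")
  expect_error(voxel_degree(v, c(99, 1, 1)), "outside")
})

test_that("build_graph decomposes line, Y and X fixtures correctly", {
  g <- build_graph(fix_line(7))
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(sum(g$nodes$ep), 2L)
  expect_equal(nrow(g$links), 1L)
  expect_equal(nrow(g$links$points[[1]]), 5L)

  gy <- build_graph(fix_y())
  expect_equal(sum(gy$nodes$degree == 3), 1L)
  expect_equal(sum(gy$nodes$ep), 3L)
  expect_equal(nrow(gy$links), 3L)

  gx <- build_graph(fix_x())
  expect_equal(sum(gx$nodes$degree == 4), 1L)
  expect_equal(sum(gx$nodes$ep), 4L)
  expect_equal(nrow(gx$links), 4L)
  vg <- validate_graph(gx, fix_x())
  expect_equal(unname(c(vg$degree_histogram)), c(4L, 1L))
})

test_that("empty, isolated and non-binary inputs behave per contract", {
  expect_equal(nrow(build_graph(array(0L, c(4, 4, 4)))$nodes), 0L)
  iso <- array(0L, c(5, 5, 5)); iso[2, 2, 2] <- 1L; iso[4, 4, 4] <- 1L
  g <- build_graph(iso)
  expect_equal(sum(g$nodes$isolated), 2L)
  expect_true(all(validate_graph(g, iso)$checks$pass))
  bad <- array(0L, c(3, 3, 3)); bad[2, 2, 2] <- 7L
  expect_error(build_graph(bad), "binary")
})

test_that("validate_graph reports all invariants and detects violations", {
  v <- fix_line(7)
  g <- build_graph(v)
  rep <- validate_graph(g, v)
  expect_true(all(rep$checks$pass))
  expect_equal(rep$n_voxels, 7L)
  # constructed violation: delete one path point
  g2 <- g
  g2$links$points[[1]] <- g2$links$points[[1]][-3, , drop = FALSE]
  rep2 <- validate_graph(g2, v)
  expect_false(rep2$checks$pass[rep2$checks$invariant == "conservation"])
})

test_that("graph counts match the brute-force oracle on small random stars", {
  withr::with_seed(42, {
    for (i in 1:10) {
      k <- sample(3:5, 1)
      v <- fix_star(rand_dirs(k, min_sep = 40), len = 7, size = 19)
      g <- build_graph(v)
      oc <- oracle_graph_counts(v)
      expect_equal(nrow(g$nodes), oc$n_junction_clusters + oc$n_leaves)
      expect_equal(sum(g$nodes$ep), oc$n_leaves)
      expect_equal(nrow(g$links), oc$n_path_components)
      expect_true(all(validate_graph(g, v)$checks$pass))
    }
  })
})

test_that("integer translation shifts centroids and preserves topology", {
  v <- fix_y()
  g <- build_graph(v)
  off <- c(2L, 3L, 1L)
  v2 <- array(0L, dim(v) + 4L)
  co <- which(v > 0, arr.ind = TRUE)
  v2[sweep(co, 2, off, `+`)] <- 1L
  g2 <- build_graph(v2)
  expect_equal(sort(g2$nodes$degree), sort(g$nodes$degree))
  o1 <- g$nodes[order(g$nodes$com_i, g$nodes$com_j), ]
  o2 <- g2$nodes[order(g2$nodes$com_i, g2$nodes$com_j), ]
  expect_equal(o2$com_i, o1$com_i + off[1])
  expect_equal(o2$com_j, o1$com_j + off[2])
  expect_equal(o2$com_k, o1$com_k + off[3])
})

test_that("the JSON graph dialect round-trips", {
  v <- fix_x()
  g <- build_graph(v)
  p <- withr::local_tempfile(fileext = ".json")
  graph_to_json(g, p)
  g2 <- graph_from_json(p)
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_equal(sort(g2$nodes$degree), sort(g$nodes$degree))
  expect_equal(g2$n_voxels, g$n_voxels)
  r <- match(1L, g2$links$id)
  expect_equal(g2$links$points[[r]], g$links$points[[match(1L, g$links$id)]])
})
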