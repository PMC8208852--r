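test_that("phantom generation is deterministic and parameter-faithful", {
  a <- small_phantom(seed = 110)
  b <- small_phantom(seed = 110)
  expect_identical(a$mask, b$mask)
  expect_identical(a$skeleton, b$skeleton)
  expect_identical(a$gt_labels, b$gt_labels)
  expect_false(identical(a$mask, small_phantom(seed = 111)$mask))
  expect_equal(a$n_adhesions, 3L)
})

test_that("trees bifurcate to 2^depth leaf tips each", {
  geo <- generate_polyline_trees(phantom_params(depth = 3, shape = c(96, 96, 96),
                                                n_adhesions = 3, seed = 112))
  gens <- vapply(geo$branches, function(b) b$gen, numeric(1))
  trees <- vapply(geo$branches, function(b) b$tree, character(1))
  expect_equal(sum(gens == 3 & trees == "artery"), 8L)
  expect_equal(sum(gens == 3 & trees == "vein"), 8L)
  # same seed twice -> identical polylines
  geo2 <- generate_polyline_trees(phantom_params(depth = 3, shape = c(96, 96, 96),
                                                 n_adhesions = 3, seed = 112))
  expect_identical(geo$branches, geo2$branches)
})

test_that("planted crossings appear as that many skeleton contact clusters", {
  case <- small_phantom(seed = 113)
  # independent scan: artery and vein skeleton voxels within Chebyshev 1
  geo <- case$geometry
  vox_of <- function(tree) {
    pts <- lapply(geo$branches[vapply(geo$branches, function(b) b$tree, "") == tree],
                  function(b) avsep:::bresenham3(b$start, b$end))
    tw <- lapply(geo$twigs[vapply(geo$twigs, function(t) t$tree, "") == tree],
                 function(t) rbind(avsep:::bresenham3(t$Q, t$P),
                                   avsep:::bresenham3(t$P, t$tip)))
    unique(do.call(rbind, c(pts, tw)))
  }
  av <- vox_of("artery"); vv <- vox_of("vein")
  d <- avsep:::cross_dist(av, vv)
  cheb <- outer(seq_len(nrow(av)), seq_len(nrow(vv)), function(i, j) {
    pmax(abs(av[i, 1] - vv[j, 1]), abs(av[i, 2] - vv[j, 2]), abs(av[i, 3] - vv[j, 3]))
  })
  contacts <- av[apply(cheb <= 1, 1, any), , drop = FALSE]
  expect_gt(nrow(contacts), 0)
  cl <- stats::cutree(stats::hclust(stats::dist(contacts, method = "maximum"),
                                    method = "single"), h = 1.5)
  expect_equal(length(unique(cl)), case$n_adhesions)
  expect_equal(nrow(case$adhesion_sites) > 0, TRUE)
})

test_that("the skeleton lies inside the mask and labels tile the mask", {
  case <- small_phantom(seed = 114)
  expect_true(all(case$mask[case$skeleton]))
  expect_true(all((case$gt_labels > 0) == case$mask))
  expect_setequal(unique(c(case$gt_labels)), c(0L, 1L, 2L))
})

test_that("the venous tree dominates arterial volume as configured", {
  case <- small_phantom(seed = 115)
  ratio <- sum(case$gt_labels == 2L) / sum(case$gt_labels == 1L)
  expect_gt(ratio, 1.2)   # venous dominance planted via sqrt(volume_scale)
  # tube cross-sections: a straight polyline of radius 2 rasterizes to
  # discrete disks of radius 2 in every slice it crosses
  geo <- list(branches = list(list(tree = "artery", heap = 1L, gen = 0L,
                                   start = c(10, 10, 4), end = c(10, 10, 16),
                                   dir = c(0, 0, 1), len = 12, radius = 2)),
              twigs = list(), satellites = list(), n_adhesions = 0L,
              params = phantom_params(shape = c(20L, 20L, 20L), n_adhesions = 0))
  tube <- rasterize_phantom(geo)
  sl <- tube$mask[, , 10]
  expect_equal(sum(sl), sum(outer((1:20 - 10)^2, (1:20 - 10)^2, `+`) <= 4))
})

test_that("the default family exercises every pipeline stage", {
  case <- vascular_phantom(seed = 3)
  g <- build_graph(case$skeleton)
  expect_gte(length(detect_adhesion_nodes(g)), 1L)
  st <- build_subtrees(split_adhesions(g))
  expect_gte(nrow(st), 4L)
  expect_gte(case$n_adhesions, 4L)
  expect_lte(case$n_adhesions, 8L)
})

test_that("parameters that cannot fit the grid raise a domain error", {
  expect_error(vascular_phantom(seed = 1, shape = c(24L, 24L, 24L)),
               "fit the grid|phantom")
  expect_error(phantom_params(volume_scale = 0.9), "volume_scale")
  expect_error(phantom_params(depth = 0), "depth")
})
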