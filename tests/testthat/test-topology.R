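# XOY footprints, overlap topology, over-segmentation merge, trunk skeleton.

test_that("XOY footprints are convex hulls of the projection", {
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = c(0, 2, 5, 1))
  fp <- project_xoy(sq)
  expect_false(fp$degenerate)
  expect_equal(fp$area, 1)
  expect_equal(nrow(fp$vertices), 4)

  set.seed(21)
  th <- runif(1000, 0, 2 * pi); rr <- sqrt(runif(1000))
  disc <- tibble::tibble(x = rr * cos(th), y = rr * sin(th), z = 0)
  fp <- project_xoy(disc)
  oracle <- grDevices::chull(as.matrix(disc[, 1:2]))
  expect_equal(sort_rows(fp$vertices),
               sort_rows(as.matrix(disc[oracle, 1:2])))
  expect_gt(fp$area, 0.9 * pi)
  expect_lt(fp$area, pi)
  # every member point inside or on the hull
  expect_true(all(streetseg:::points_in_convex(as.matrix(disc[, 1:2]), fp$vertices)))

  two <- tibble::tibble(x = c(0, 1), y = c(0, 0), z = c(0, 0))
  expect_true(project_xoy(two)$degenerate)
})

test_that("footprint overlap: containment and IoU by exact clipping", {
  sq <- function(x0, y0, s = 1) {
    project_xoy(tibble::tibble(x = x0 + c(0, s, s, 0), y = y0 + c(0, 0, s, s), z = 0))
  }
  same <- footprint_overlap(sq(0, 0), sq(0, 0))
  expect_equal(same$containment, 1)
  expect_equal(same$iou, 1)

  far <- footprint_overlap(sq(0, 0), sq(10, 0))
  expect_equal(far$containment, 0)
  expect_equal(far$iou, 0)

  quad <- footprint_overlap(sq(0, 0), sq(0, 0, 0.5))
  expect_equal(quad$containment, 1, tolerance = 1e-12)
  expect_equal(quad$iou, 0.25, tolerance = 1e-12)

  # degenerate fallback: collinear fragment inside a square
  seg <- project_xoy(tibble::tibble(x = c(0.2, 0.8), y = c(0.5, 0.5), z = 0))
  ov <- footprint_overlap(seg, sq(0, 0))
  expect_equal(ov$containment, 1)
})

test_that("over-segmentation merge is transitive, conservative, idempotent", {
  set.seed(22)
  ring <- function(cx, n, r, zlo, zhi) {
    th <- runif(n, 0, 2 * pi); rr <- r * sqrt(runif(n))
    tibble::tibble(x = cx + rr * cos(th), y = rr * sin(th), z = runif(n, zlo, zhi))
  }
  # crown + two stacked fragments directly above it; distant second tree
  cloud <- dplyr::bind_rows(ring(0, 500, 2, 3, 6), ring(0, 150, 1.2, 7, 8),
                            ring(0, 80, 0.6, 9, 10), ring(12, 500, 2, 3, 6))
  cloud$cluster <- rep(1:4, c(500, 150, 80, 500))
  merged <- merge_oversegmented(cloud, 0.9)
  expect_equal(dplyr::n_distinct(merged$cluster), 2)
  expect_equal(nrow(merged), nrow(cloud))  # conservation
  # the three mutually contained fragments collapsed into one id
  expect_equal(dplyr::n_distinct(merged$cluster[1:730]), 1)
  # side-by-side tree untouched
  expect_false(merged$cluster[1000] == merged$cluster[1])
  # idempotent
  again <- merge_oversegmented(merged, 0.9)
  expect_identical(again$cluster, merged$cluster)
  # union-find closure equals the containment-graph components (oracle via
  # igraph-free transitive closure on the 3-fragment clique)
  map <- attr(merged, "merge_map")
  expect_equal(map$new[map$old %in% 1:3], rep(min(map$new[map$old %in% 1:3]), 3))
})

test_that("trunk skeleton slabs track the stem axis", {
  set.seed(23)
  cyl <- sample_cylinder(4000, r = 0.15, h = 2, center = c(3, -1))
  sk <- build_trunk_skeleton(cyl, slab_height = 0.25)
  expect_true(attr(sk, "available"))
  expect_equal(nrow(sk), 8)
  expect_true(all(abs(sk$cx - 3) < 0.02))
  expect_true(all(abs(sk$cy + 1) < 0.02))
  expect_lt(max(abs(attr(sk, "axis") - c(3, -1))), 0.02)

  # attached offset box pulls slab centroids off-axis detectably
  box <- tibble::tibble(x = runif(800, 3.8, 4.2), y = runif(800, -1.2, -0.8),
                        z = runif(800, 1, 2))
  sk2 <- build_trunk_skeleton(dplyr::bind_rows(cyl, box), slab_height = 0.25)
  hi <- sk2$z_lo >= 1
  expect_gt(max(sk2$cx[hi] - 3, na.rm = TRUE), 0.2)

  # gap slabs are flagged unoccupied
  gap <- cyl[cyl$z < 0.9 | cyl$z > 1.4, ]
  sk3 <- build_trunk_skeleton(gap, slab_height = 0.25)
  expect_true(any(!sk3$occupied))
  expect_equal(sum(sk3$n), nrow(gap))

  # too-short clusters are flagged unavailable
  flat <- sample_cylinder(100, 0.15, 0.3)
  expect_false(attr(build_trunk_skeleton(flat, 0.25), "available"))
})

test_that("interference removal strips a glued sign, spares the tree", {
  tree <- generate_tree(height = 9, trunk_radius = 0.1, crown_radius = 2,
                        crown_base = 3, seed = 31)
  sign <- tibble::tibble(x = runif(400, 0.575, 0.625),
                         y = runif(400, -0.25, 0.25),
                         z = runif(400, 0.8, 1.8), part = "sign")
  cluster <- dplyr::bind_rows(tree, sign)
  sk <- build_trunk_skeleton(cluster[, c("x", "y", "z")])
  out <- remove_interference(cluster, sk, radius_cutoff = 2 * 0.1 + 0.2)
  rej <- cluster$part[out$rejected]
  expect_gte(sum(rej == "sign") / 400, 0.95)
  kept_trunk <- sum(out$tree$part == "trunk") / sum(cluster$part == "trunk")
  expect_gte(kept_trunk, 0.99)
  # partition: tree + rejected = cluster
  expect_equal(nrow(out$tree) + length(out$rejected), nrow(cluster))
})

test_that("interference removal leaves clean trees intact", {
  tree <- generate_tree(height = 8, trunk_radius = 0.12, crown_radius = 1.8,
                        crown_base = 3, noise_sigma = 0.01, seed = 32)
  sk <- build_trunk_skeleton(tree[, c("x", "y", "z")])
  # with the true crown base, a cutoff past the bark (r + 5 sigma) rejects
  # nothing at all, and r + 3 sigma only the rare bark outlier
  out <- remove_interference(tree, sk, radius_cutoff = 0.12 + 5 * 0.01,
                             crown_base = 3)
  expect_length(out$rejected, 0)
  out3 <- remove_interference(tree, sk, radius_cutoff = 0.12 + 3 * 0.01,
                              crown_base = 3)
  expect_lt(length(out3$rejected) / nrow(tree), 0.005)
  # with the estimated crown base (which overshoots into the sparse lower
  # crown) losses at the pipeline's working cutoff stay marginal
  est <- remove_interference(tree, sk, radius_cutoff = 2 * 0.12 + 0.2)
  expect_lt(length(est$rejected) / nrow(tree), 0.02)
  # vacuous filter: everything within the cutoff
  out_all <- remove_interference(tree, sk, radius_cutoff = 50)
  expect_length(out_all$rejected, 0)
  # nothing above the crown base is ever rejected
  cb <- attr(sk, "crown_base")
  tight <- remove_interference(tree, sk, radius_cutoff = 0.01)
  expect_true(all(tree$z[tight$rejected] < cb))
})
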