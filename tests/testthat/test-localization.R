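# Breast-height slicing, circle fitting, trunk localization, axis rotation,
# density-valley boundary search and cluster splitting.

test_that("breast-height slab takes [1.25, 1.35] m above the cluster root", {
  set.seed(41)
  cyl <- sample_cylinder(2000, 0.1, 2)
  slab <- slice_breast_height(cyl)
  zr <- cyl$z - min(cyl$z)
  expect_equal(nrow(slab), sum(zr >= 1.25 & zr <= 1.35))
  expect_equal(nrow(slab) / nrow(cyl), 0.05, tolerance = 0.3)
  expect_false(attr(slab, "empty"))

  low <- sample_cylinder(200, 0.1, 1.0)
  expect_true(attr(slice_breast_height(low), "empty"))

  # root is per-cluster: a translated cluster slices identically
  up <- cyl
  up$z <- up$z + 57.3
  expect_equal(nrow(slice_breast_height(up)), nrow(slab))
})

test_that("Kåsa circle fit is exact on noiseless circles", {
  sym <- fit_circle_lsq(tibble::tibble(x = c(1, 0, -1, 0), y = c(0, 1, 0, -1)))
  expect_equal(sym$a, 0, tolerance = 1e-12)
  expect_equal(sym$b, 0, tolerance = 1e-12)
  expect_equal(sym$r, 1, tolerance = 1e-12)
  expect_lt(sym$rms_residual, 1e-12)

  circ <- fit_circle_lsq(tibble::tibble(x = c(0, 2, 1), y = c(0, 0, 1)))
  expect_equal(c(circ$a, circ$b, circ$r), c(1, 0, 1), tolerance = 1e-12)
  # verify the circumcircle property directly
  d <- sqrt((c(0, 2, 1) - circ$a)^2 + (c(0, 0, 1) - circ$b)^2)
  expect_equal(d, rep(1, 3), tolerance = 1e-12)
})

test_that("circle fit recovers noisy trunk rings and refuses degeneracy", {
  set.seed(42)
  th <- runif(200, 0, 2 * pi)
  r_true <- 0.15
  pts <- tibble::tibble(x = 3 + (r_true + rnorm(200, 0, 0.005)) * cos(th),
                        y = -2 + (r_true + rnorm(200, 0, 0.005)) * sin(th))
  fit <- fit_circle_lsq(pts)
  expect_lt(abs(fit$r - r_true), 0.01)
  expect_lt(abs(fit$a - 3), 0.01)
  expect_lt(abs(fit$b + 2), 0.01)

  expect_error(fit_circle_lsq(tibble::tibble(x = 1:5, y = 2 * (1:5))),
               "collinear")
  expect_error(fit_circle_lsq(pts[1:2, ]), "at least 3")
})

test_that("circle fit is translation and rotation equivariant", {
  set.seed(43)
  th <- runif(100, 0, 2 * pi)
  pts <- cbind(x = 0.4 * cos(th) + rnorm(100, 0, 0.01),
               y = 0.4 * sin(th) + rnorm(100, 0, 0.01))
  base <- fit_circle_lsq(pts)
  shifted <- fit_circle_lsq(sweep(pts, 2, c(-7.5, 12.25), "+"))
  expect_equal(shifted$a, base$a - 7.5, tolerance = 1e-9)
  expect_equal(shifted$b, base$b + 12.25, tolerance = 1e-9)
  expect_equal(shifted$r, base$r, tolerance = 1e-9)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- fit_circle_lsq(pts %*% t(R))
  expect_equal(rot$r, base$r, tolerance = 1e-9)
  expect_equal(c(rot$a, rot$b), as.vector(R %*% c(base$a, base$b)),
               tolerance = 1e-9)
})

test_that("trunk localization finds one fit per stem", {
  tree <- generate_tree(9, 0.12, 1.8, 3, seed = 44)
  cl <- tree
  cl$cluster <- 1L
  fits <- locate_trees(cl)
  expect_equal(nrow(fits), 1)
  expect_lt(sqrt(fits$x^2 + fits$y^2), 0.05)
  expect_lt(abs(fits$r - 0.12), 0.02)
  expect_false(detect_undersegmentation(fits))

  # glued pair: two stems 4 m apart in one cluster
  t2 <- generate_tree(10, 0.1, 2.2, 3, seed = 45)
  t2$x <- t2$x + 4
  both <- dplyr::bind_rows(tree, t2)
  both$cluster <- 1L
  fits2 <- locate_trees(both)
  expect_equal(nrow(fits2), 2)
  expect_true(detect_undersegmentation(fits2))
  expect_equal(sort(round(fits2$x)), c(0, 4))

  # crown-only fragment: no stem in the slab, no fits
  crown <- tree[tree$part == "crown", ]
  crown$cluster <- 1L
  expect_equal(nrow(locate_trees(crown)), 0)
})

test_that("trunk-axis alignment is a pure rotation onto +u", {
  pts <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  al <- align_to_trunk_axis(pts, tibble::tibble(x = c(0, 0), y = c(0, 6)))
  expect_equal(al$centers_u, c(0, 6))
  # 3-4-5 triangle: distance preserved
  al2 <- align_to_trunk_axis(pts, tibble::tibble(x = c(0, 3), y = c(0, 4)))
  expect_equal(al2$centers_u, c(0, 5))
  d_before <- stats::dist(as.matrix(pts))
  d_after <- stats::dist(al2$uv)
  expect_equal(as.vector(d_after), as.vector(d_before), tolerance = 1e-9)
  expect_error(
    align_to_trunk_axis(pts, tibble::tibble(x = c(1, 1), y = c(2, 2))),
    "coincident"
  )
})

test_that("boundary voxel sits at the density valley between crowns", {
  set.seed(46)
  u <- c(rnorm(5000, 0, 1.5), rnorm(5000, 6, 1.5))
  plan <- find_boundary_voxel(u, c(0, 6), 0.5)
  expect_length(plan$boundaries, 1)
  expect_lt(abs(plan$boundaries - 3), 0.5)

  # asymmetric mixture: valley shifts toward the tighter crown; compare to
  # the numeric argmin of the analytic mixture density
  u2 <- c(rnorm(8000, 0, 1), rnorm(8000, 6, 2))
  dens <- function(v) dnorm(v, 0, 1) + dnorm(v, 6, 2)
  grid <- seq(0.5, 5.5, by = 0.001)
  analytic_min <- grid[which.min(dens(grid))]
  plan2 <- find_boundary_voxel(u2, c(0, 6), 0.5)
  expect_lt(plan2$boundaries, 3)
  expect_lt(abs(plan2$boundaries - analytic_min), 0.5)

  # fully disjoint crowns: the boundary lands in an empty voxel
  u3 <- c(runif(500, 0, 2), runif(500, 4, 6))
  plan3 <- find_boundary_voxel(u3, c(1, 5), 0.5)
  b <- plan3$boundaries
  row <- plan3$profile[plan3$profile$is_boundary, ]
  expect_equal(row$n, 0L)
  expect_true(b > 2 && b < 4)

  # trunks closer than two voxels: midpoint with a warning
  expect_warning(p4 <- find_boundary_voxel(runif(100), c(0, 0.7), 0.5),
                 "midpoint")
  expect_equal(p4$boundaries, 0.35)
})

test_that("splitting conserves points and isolates one trunk per child", {
  set.seed(47)
  t1 <- generate_tree(10, 0.1, 2.2, 3, seed = 48)
  t2 <- generate_tree(10, 0.1, 2.2, 3, seed = 49)
  t2$x <- t2$x + 4
  t1$truth <- 1L; t2$truth <- 2L
  both <- dplyr::bind_rows(t1, t2)
  both$cluster <- 1L
  fits <- locate_trees(both)
  expect_equal(nrow(fits), 2)
  al <- align_to_trunk_axis(both, fits[, c("x", "y")])
  plan <- find_boundary_voxel(al$uv[, 1], al$centers_u, 0.5)
  parts <- split_cluster(both, plan, al)
  expect_equal(nrow(parts), nrow(both))            # conservation
  expect_equal(sort(unique(parts$part)), c(1L, 2L))
  # each child contains exactly one fit center
  ctr_u <- al$centers_u
  expect_equal(findInterval(ctr_u, sort(plan$boundaries)) + 1L, c(1L, 2L))
  # children align with ground truth almost perfectly
  agree <- max(mean(parts$part == parts$truth), mean(parts$part == 3L - parts$truth))
  expect_gt(agree, 0.97)
})

test_that("three collinear stems give two boundaries and three children", {
  u <- c(rnorm(3000, 0, 1), rnorm(3000, 5, 1), rnorm(3000, 10, 1))
  plan <- find_boundary_voxel(u, c(0, 5, 10), 0.5)
  expect_length(plan$boundaries, 2)
  expect_lt(abs(plan$boundaries[1] - 2.5), 0.75)
  expect_lt(abs(plan$boundaries[2] - 7.5), 0.75)
  pts <- tibble::tibble(x = u, y = 0, z = 1)
  al <- list(uv = cbind(u, 0))
  parts <- split_cluster(pts, plan, al)
  expect_equal(sort(unique(parts$part)), 1:3)
  expect_equal(nrow(parts), length(u))
})
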