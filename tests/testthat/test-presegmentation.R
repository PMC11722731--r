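# DBSCAN clustering, RANSAC linearity, one-third-of-average noise rule.

test_that("well-separated blobs cluster cleanly, isolates become noise", {
  set.seed(1)
  cloud <- dplyr::bind_rows(make_blob(200, c(0, 0, 0)), make_blob(200, c(10, 0, 0)))
  out <- dbscan_cluster(cloud, eps = 0.5, min_pts = 5)
  expect_equal(dplyr::n_distinct(out$cluster, na.rm = TRUE), 2)
  expect_equal(sum(is.na(out$cluster)), 0)

  lone <- dplyr::bind_rows(make_blob(200, c(0, 0, 0)),
                           tibble::tibble(x = 10, y = 0, z = 0))
  out2 <- dbscan_cluster(lone, eps = 0.5, min_pts = 5)
  expect_true(is.na(out2$cluster[201]))
})

test_that("clustering matches the brute-force density-reachability oracle", {
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(30:200, 1)
    pts <- tibble::tibble(x = runif(n, 0, 6), y = runif(n, 0, 6), z = runif(n, 0, 6))
    eps <- runif(1, 0.4, 1.2)
    min_pts <- sample(3:8, 1)
    out <- dbscan_cluster(pts, eps, min_pts)
    expect_dbscan_equiv(out$cluster, pts, eps, min_pts)
  }
})

test_that("clustering is invariant under permutation and rigid translation", {
  set.seed(2)
  pts <- dplyr::bind_rows(make_blob(80, c(0, 0, 0)), make_blob(60, c(3, 0, 0)),
                          make_blob(20, c(10, 10, 0), sd = 2))
  base <- dbscan_cluster(pts, 0.7, 5)
  # translation: identical partition
  shifted <- pts
  shifted$x <- shifted$x + 42.42
  shifted$y <- shifted$y - 7.7
  tr <- dbscan_cluster(shifted, 0.7, 5)
  expect_identical(base$cluster, tr$cluster)
  # permutation: same partition up to relabeling (checked via the oracle
  # equivalence, which ignores label names and border-order ambiguity)
  perm <- sample(nrow(pts))
  pm <- dbscan_cluster(pts[perm, ], 0.7, 5)
  expect_dbscan_equiv(pm$cluster, pts[perm, ], 0.7, 5)
})

test_that("RANSAC line fit captures jittered lines, rejects spheres", {
  set.seed(3)
  line <- tibble::tibble(x = rnorm(100, 0, 0.05), y = rnorm(100, 0, 0.05),
                         z = seq(0, 5, length.out = 100))
  fit <- fit_line_ransac(line, seed = 7)
  expect_gte(fit$inlier_ratio, 0.99)
  # independent check: count distances to the fitted line directly
  m <- sweep(as.matrix(line), 2, fit$point)
  proj <- as.vector(m %*% fit$direction)
  d <- sqrt(pmax(rowSums(m^2) - proj^2, 0))
  expect_equal(fit$inlier_ratio, mean(d <= 0.4))

  g <- matrix(rnorm(1500), ncol = 3)
  sphere <- tibble::tibble(x = 2 * g[, 1] / sqrt(rowSums(g^2)),
                           y = 2 * g[, 2] / sqrt(rowSums(g^2)),
                           z = 2 * g[, 3] / sqrt(rowSums(g^2)))
  sfit <- fit_line_ransac(sphere, seed = 7)
  expect_lt(sfit$inlier_ratio, 0.7)
  # the best possible line is a diameter: band |sin(theta)| <= 0.2 covers
  # 1 - cos(asin(0.2)) of the sphere surface (both caps)
  analytic <- 1 - cos(asin(0.4 / 2))
  expect_lt(abs(sfit$inlier_ratio - analytic), 0.05)
})

test_that("RANSAC handles two points and is reproducible per seed", {
  two <- tibble::tibble(x = c(0, 1), y = c(0, 2), z = c(0, 2))
  fit <- fit_line_ransac(two)
  expect_equal(fit$inlier_ratio, 1)
  expect_equal(fit$direction, c(1, 2, 2) / 3)

  set.seed(4)
  pts <- make_blob(300, c(0, 0, 0), sd = 1)
  f1 <- fit_line_ransac(pts, seed = 99)
  f2 <- fit_line_ransac(pts, seed = 99)
  expect_identical(f1, f2)
  expect_error(fit_line_ransac(pts[1, ]), "at least 2")
})

test_that("linearity classification separates poles from crowns", {
  set.seed(5)
  pole <- tibble::tibble(x = rnorm(200, 0, 0.05), y = rnorm(200, 0, 0.05),
                         z = runif(200, 0, 4))
  expect_equal(classify_linearity(pole), "linear")
  g <- matrix(rnorm(1500), ncol = 3)
  sphere <- tibble::tibble(x = 2 * g[, 1] / sqrt(rowSums(g^2)),
                           y = 2 * g[, 2] / sqrt(rowSums(g^2)),
                           z = 2 * g[, 3] / sqrt(rowSums(g^2)))
  expect_equal(classify_linearity(sphere), "nonlinear")
  blob <- tibble::tibble(x = rep(1, 10), y = rep(2, 10), z = rep(3, 10))
  expect_equal(classify_linearity(blob), "linear")
})

test_that("noise rule drops clusters below one third of the nonlinear mean", {
  mk <- function(sizes, kinds) {
    tibble::tibble(cluster = seq_along(sizes), n = sizes,
                   inlier_ratio = 0.5, kind = kinds)
  }
  # nonlinear sizes 90/60/30: mean 60, threshold 20, all retained
  out <- filter_noise_clusters(mk(c(90, 60, 30), rep("nonlinear", 3)))
  expect_true(all(out$retained))
  expect_equal(attr(out, "noise_threshold"), 20)
  # nonlinear sizes 90/60/15: mean 55, threshold 55/3, the 15 dropped
  out <- filter_noise_clusters(mk(c(90, 60, 15), rep("nonlinear", 3)))
  expect_identical(out$retained, c(TRUE, TRUE, FALSE))
  expect_equal(attr(out, "noise_threshold"), 55 / 3)
  # exact tie at m/3: sizes 90/70/20 give mean 60, threshold 20 -> retained
  out <- filter_noise_clusters(mk(c(90, 70, 20), rep("nonlinear", 3)))
  expect_equal(attr(out, "noise_threshold"), 20)
  expect_true(out$retained[3])
})

test_that("linear clusters are exempt from the noise rule by default", {
  cls <- tibble::tibble(cluster = 1:3, n = c(900L, 600L, 10L),
                        inlier_ratio = c(0.2, 0.2, 0.99),
                        kind = c("nonlinear", "nonlinear", "linear"))
  out <- filter_noise_clusters(cls)
  expect_true(all(out$retained))           # trunk fragment survives
  strict <- filter_noise_clusters(cls, exempt_linear = FALSE)
  expect_identical(strict$retained, c(TRUE, TRUE, FALSE))
  # the nonlinear mean ignores linear clusters either way
  expect_equal(attr(out, "noise_threshold"), 250)
})

test_that("single nonlinear cluster is retained; all-linear input warns", {
  one <- tibble::tibble(cluster = 1L, n = 7L, inlier_ratio = 0.1,
                        kind = "nonlinear")
  expect_true(filter_noise_clusters(one)$retained)
  lin <- tibble::tibble(cluster = 1:2, n = c(5L, 9L), inlier_ratio = 1,
                        kind = "linear")
  expect_warning(out <- filter_noise_clusters(lin), "no nonlinear")
  expect_true(all(out$retained))
})

test_that("noise threshold scales linearly with uniform count scaling", {
  sizes <- c(40L, 90L, 130L)
  a <- filter_noise_clusters(tibble::tibble(cluster = 1:3, n = sizes,
                                            inlier_ratio = 0, kind = "nonlinear"))
  b <- filter_noise_clusters(tibble::tibble(cluster = 1:3, n = sizes * 5L,
                                            inlier_ratio = 0, kind = "nonlinear"))
  expect_equal(attr(b, "noise_threshold"), 5 * attr(a, "noise_threshold"))
  expect_identical(a$retained, b$retained)
})
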