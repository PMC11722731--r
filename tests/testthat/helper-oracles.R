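# Independent brute-force oracles the implementation is checked against.

# Naive O(N^2) DBSCAN by the density-reachability definition: cores are
# points with >= min_pts neighbours (self included) within eps; clusters are
# the connected components of the core-core eps graph; border points attach
# to any core neighbour's cluster; the rest is noise.
brute_dbscan <- function(pts, eps, min_pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  nb <- D <= eps
  core <- rowSums(nb) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier) > 0) {
      j <- frontier[1]
      frontier <- frontier[-1]
      nxt <- which(nb[j, ] & core & labels == 0L)
      labels[nxt] <- cl
      frontier <- c(frontier, nxt)
    }
  }
  for (i in which(!core)) {
    cn <- which(nb[i, ] & core)
    labels[i] <- if (length(cn) > 0) labels[cn[1]] else 0L
  }
  list(labels = labels, core = core)
}

# Equivalence of a clustering with the oracle under the DBSCAN definition:
# identical noise sets, identical core partitions (up to relabeling), and
# every border point assigned to a cluster holding one of its core
# neighbours (border attachment is legitimately order-dependent).
expect_dbscan_equiv <- function(mine, pts, eps, min_pts) {
  oracle <- brute_dbscan(pts, eps, min_pts)
  lab <- ifelse(is.na(mine), 0L, mine)
  expect_identical(lab == 0L, oracle$labels == 0L)
  core <- oracle$core
  if (any(core)) {
    tab <- table(lab[core], oracle$labels[core])
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
  border <- !core & lab != 0L
  if (any(border)) {
    D <- as.matrix(stats::dist(as.matrix(pts)))
    ok <- vapply(which(border), function(i) {
      any(D[i, ] <= eps & core & lab == lab[i])
    }, logical(1))
    expect_true(all(ok))
  }
  invisible(NULL)
}

# O(N^3) supporting-edge convex hull oracle: a directed edge (i, j) lies on
# the hull iff every other point is on one side of it. Returns the vertex
# coordinate set (unordered). Use with continuous random points only (no
# collinear triples).
brute_hull_vertices <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  verts <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- (xy[j, 1] - xy[i, 1]) * (xy[, 2] - xy[i, 2]) -
        (xy[j, 2] - xy[i, 2]) * (xy[, 1] - xy[i, 1])
      if (all(s >= -1e-9) || all(s <= 1e-9)) verts[c(i, j)] <- TRUE
    }
  }
  xy[verts, , drop = FALSE]
}

# canonical row ordering for vertex-set comparison
sort_rows <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# O(N^2) maximum pairwise distance oracle
brute_max_dist <- function(xy) max(stats::dist(as.matrix(xy)))

# uniformly jittered 3D blob
make_blob <- function(n, center, sd = 0.2) {
  tibble::tibble(
    x = stats::rnorm(n, center[1], sd),
    y = stats::rnorm(n, center[2], sd),
    z = stats::rnorm(n, center[3], sd)
  )
}

# noiseless-or-jittered cylinder surface sample
sample_cylinder <- function(n, r, h, center = c(0, 0), sigma = 0) {
  th <- stats::runif(n, 0, 2 * pi)
  out <- tibble::tibble(
    x = center[1] + r * cos(th),
    y = center[2] + r * sin(th),
    z = stats::runif(n, 0, h)
  )
  if (sigma > 0) {
    out$x <- out$x + stats::rnorm(n, 0, sigma)
    out$y <- out$y + stats::rnorm(n, 0, sigma)
    out$z <- out$z + stats::rnorm(n, 0, sigma)
  }
  out
}
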