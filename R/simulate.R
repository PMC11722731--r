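# Seeded generator of labeled street-tree scenes: trunk cylinders,
# ellipsoidal crowns, touching crowns (under-segmentation), trunk occlusion
# gaps (over-segmentation), pole-like distractors and an optional ground
# plane — each point carrying its ground-truth label.

#' Generate one synthetic street tree
#'
#' Trunk: points on the cylinder surface of radius `trunk_radius` between
#' z = 0 and z = `crown_base`, at `trunk_density` points per m^2 of bark.
#' Crown: points uniform in the axis-aligned ellipsoid with horizontal
#' semi-axis `crown_radius` and vertical semi-axis (height - crown_base)/2,
#' at `crown_density` points per m^3 — MLS crowns return densely from the
#' interior, not just the surface. Isotropic Gaussian jitter of sd
#' `noise_sigma` is added to every coordinate. Reproducible per seed.
#'
#' @param height total tree height, m.
#' @param trunk_radius stem radius, m.
#' @param crown_radius horizontal crown semi-axis, m.
#' @param crown_base height of the lowest crown point, m.
#' @param trunk_density bark sampling density, points/m^2.
#' @param crown_density crown volume density, points/m^3.
#' @param noise_sigma jitter sd, m (0 = noiseless).
#' @param seed integer seed.
#' @return tibble of x, y, z (tree axis at the origin, base at z = 0) with
#'   a `part` column (`"trunk"`/`"crown"`).
#' @export
generate_tree <- function(height, trunk_radius, crown_radius, crown_base,
                          trunk_density = 2000, crown_density = 500,
                          noise_sigma = 0.01, seed = 1L) {
  stopifnot(height > crown_base, crown_base > 0, trunk_radius > 0,
            crown_radius > 0)
  with_local_seed(seed, function() {
    n_trunk <- max(10L, round(trunk_density * 2 * pi * trunk_radius * crown_base))
    theta <- stats::runif(n_trunk, 0, 2 * pi)
    trunk <- tibble::tibble(
      x = trunk_radius * cos(theta),
      y = trunk_radius * sin(theta),
      z = stats::runif(n_trunk, 0, crown_base),
      part = "trunk"
    )

    c_semi <- (height - crown_base) / 2
    vol <- 4 / 3 * pi * crown_radius^2 * c_semi
    n_crown <- max(50L, round(crown_density * vol))
    # uniform in the unit ball, then scaled to the ellipsoid
    g <- matrix(stats::rnorm(3 * n_crown), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    rad <- stats::runif(n_crown)^(1 / 3)
    crown <- tibble::tibble(
      x = g[, 1] * rad * crown_radius,
      y = g[, 2] * rad * crown_radius,
      z = crown_base + c_semi + g[, 3] * rad * c_semi,
      part = "crown"
    )

    out <- dplyr::bind_rows(trunk, crown)
    if (noise_sigma > 0) {
      n <- nrow(out)
      out$x <- out$x + stats::rnorm(n, 0, noise_sigma)
      out$y <- out$y + stats::rnorm(n, 0, noise_sigma)
      out$z <- out$z + stats::rnorm(n, 0, noise_sigma)
    }
    out
  })
}

distractor_points <- function(kind, at, seed) {
  with_local_seed(seed, function() {
    switch(kind,
      sign = {  # thin vertical slab 0.5 x 0.05 x 1 m, base at z = 0.8
        n <- 400L
        tibble::tibble(
          x = at[1] + stats::runif(n, -0.025, 0.025),
          y = at[2] + stats::runif(n, -0.25, 0.25),
          z = stats::runif(n, 0.8, 1.8)
        )
      },
      pole = {  # slender cylinder r = 0.04 m, 3 m tall
        n <- 600L
        th <- stats::runif(n, 0, 2 * pi)
        tibble::tibble(
          x = at[1] + 0.04 * cos(th),
          y = at[2] + 0.04 * sin(th),
          z = stats::runif(n, 0, 3)
        )
      },
      box = {  # parked-vehicle-sized block 1 x 0.5 x 1 m
        n <- 800L
        tibble::tibble(
          x = at[1] + stats::runif(n, -0.5, 0.5),
          y = at[2] + stats::runif(n, -0.25, 0.25),
          z = stats::runif(n, 0, 1)
        )
      },
      abort(paste0("unknown distractor kind: ", kind))
    )
  })
}

#' Generate a labeled street-tree scene
#'
#' Trees stand along the x axis at `spacing` meter intervals (y = 0), each
#' with its own seeded geometry. Defects emulate the two failure modes the
#' segmentation optimizer targets:
#' * `"glued_pair"` — two adjacent trees are moved to `glued_gap` apart
#'   with crown radii large enough to touch, producing one under-segmented
#'   DBSCAN cluster holding two trunks (list it twice for two glued pairs:
#'   trees 1-2 and 4-5);
#' * `"trunk_gap"` — a z-band of one tree's trunk is deleted (occlusion),
#'   detaching its crown as a floating fragment (over-segmentation).
#'
#' Distractors (`"sign"` next to a trunk, free-standing `"pole"`, `"box"`)
#' carry reserved negative labels; the optional ground plane is labeled -2.
#' Per-point labels: tree ids 0..n_trees-1, ground -2, distractors -3, -4,
#' ... in order; every point is labeled.
#'
#' @param n_trees number of trees (>= 1).
#' @param spacing tree spacing along the street axis, m.
#' @param heights,trunk_radii,crown_radii,crown_bases per-tree parameters;
#'   scalars recycle, NULL draws them uniformly from realistic street-tree
#'   ranges (heights 6-13 m, trunk radii 0.05-0.15 m, crown radii
#'   1.6-2.2 m, crown bases 2.5-3.5 m).
#' @param defects character subset of `c("glued_pair", "trunk_gap")`.
#' @param glued_gap trunk spacing of the glued pair, m (crowns are inflated
#'   to `glued_gap/2 + 0.2` so they overlap).
#' @param gap_band z-interval of trunk points removed by `"trunk_gap"`, m.
#' @param distractors character vector of `c("sign", "pole", "box")` kinds.
#' @param ground add a ground plane (z = 0, 100 points/m^2) labeled -2.
#' @param trunk_density,crown_density,noise_sigma see [generate_tree()].
#' @param seed master seed; fixes the whole scene bit-for-bit.
#' @return object of class `tree_scene`: `cloud` (point tibble with
#'   `label`), `trees` (per-tree truth parameters: `tree_id`, `x`, `y`,
#'   `height`, `trunk_radius`, `crown_radius`, `crown_base`), and `spec`
#'   (the arguments, echoed).
#' @export
simulate_scene <- function(n_trees = 10, spacing = 8,
                           heights = NULL, trunk_radii = NULL,
                           crown_radii = NULL, crown_bases = NULL,
                           defects = character(), glued_gap = 4,
                           gap_band = c(1.6, 2.4),
                           distractors = character(), ground = FALSE,
                           trunk_density = 2000, crown_density = 500,
                           noise_sigma = 0.01, seed = 1L) {
  stopifnot(n_trees >= 1, spacing > 0)
  seed <- as.integer(seed %% 1000000L)  # derived per-tree seeds stay < 2^31
  bad <- setdiff(defects, c("glued_pair", "trunk_gap"))
  if (length(bad) > 0) abort(paste0("unknown defects: ", paste(bad, collapse = ", ")))
  draw <- function(x, lo, hi, k) {
    if (is.null(x)) stats::runif(k, lo, hi) else rep_len(x, k)
  }
  pars <- with_local_seed(seed, function() {
    tibble::tibble(
      tree_id = seq_len(n_trees) - 1L,
      x = (seq_len(n_trees) - 1) * spacing,
      y = 0,
      height = draw(heights, 6, 13, n_trees),
      trunk_radius = draw(trunk_radii, 0.05, 0.15, n_trees),
      crown_radius = draw(crown_radii, 1.6, 2.2, n_trees),
      crown_base = draw(crown_bases, 2.5, 3.5, n_trees)
    )
  })

  glued <- NULL
  n_pairs <- sum(defects == "glued_pair")
  if (n_pairs > 0) {
    if (n_pairs > 2) abort("at most two glued pairs are supported")
    if (n_trees < if (n_pairs == 2) 5 else 2) {
      abort("not enough trees for the requested glued pairs")
    }
    pair_starts <- if (n_pairs == 2) c(1L, 4L) else 1L
    glued <- unlist(lapply(pair_starts, function(s) c(s, s + 1L)))
    r_touch <- glued_gap / 2 + 0.2
    for (s in pair_starts) {
      pr <- c(s, s + 1L)
      pars$x[pr[2]] <- pars$x[pr[1]] + glued_gap
      pars$crown_radius[pr] <- pmax(pars$crown_radius[pr], r_touch)
      if (sum(pars$crown_radius[pr]) <= glued_gap) {
        abort("glued pair crowns do not overlap; increase crown radii")
      }
    }
  }
  gap_tree <- if ("trunk_gap" %in% defects) n_trees else NULL
  if (!is.null(gap_tree) && !is.null(glued) && gap_tree %in% glued) {
    abort("cannot apply trunk_gap to the glued pair")
  }
  if (!is.null(gap_tree)) {
    # the gap must clear the breast-height band and disconnect the crown
    stopifnot(gap_band[1] > 1.35, gap_band[2] < min(pars$crown_base))
  }

  clouds <- lapply(seq_len(n_trees), function(i) {
    tr <- generate_tree(
      pars$height[i], pars$trunk_radius[i], pars$crown_radius[i],
      pars$crown_base[i], trunk_density, crown_density, noise_sigma,
      seed = seed * 1000L + i
    )
    if (!is.null(gap_tree) && i == gap_tree) {
      drop <- tr$part == "trunk" & tr$z >= gap_band[1] & tr$z <= gap_band[2]
      tr <- tr[!drop, ]
    }
    tibble::tibble(x = tr$x + pars$x[i], y = tr$y + pars$y[i], z = tr$z,
                   label = pars$tree_id[i])
  })

  d_clouds <- list()
  if (length(distractors) > 0) {
    for (k in seq_along(distractors)) {
      kind <- distractors[k]
      at <- switch(kind,
        # sign stands 0.6 m from the last tree's trunk (inside its crown
        # footprint, close enough for DBSCAN to glue it to the stem)
        sign = c(pars$x[n_trees] + 0.6, 0),
        # free-standing street furniture away from every crown
        pole = c(pars$x[1] + spacing / 2, 4),
        box = c(pars$x[1] - spacing / 2, 4),
        abort(paste0("unknown distractor kind: ", kind))
      )
      dp <- distractor_points(kind, at, seed = seed * 1000L + 500L + k)
      dp$label <- -2L - k  # -3, -4, ...
      d_clouds[[k]] <- dp
    }
  }

  g_cloud <- NULL
  if (ground) {
    xr <- range(pars$x) + c(-5, 5); yr <- c(-6, 6)
    n_g <- round(100 * diff(xr) * diff(yr))
    g_cloud <- with_local_seed(seed * 1000L + 999L, function() {
      tibble::tibble(
        x = stats::runif(n_g, xr[1], xr[2]),
        y = stats::runif(n_g, yr[1], yr[2]),
        z = stats::rnorm(n_g, 0, 0.01),
        label = -2L
      )
    })
  }

  cloud <- dplyr::bind_rows(c(clouds, d_clouds, list(g_cloud)))
  structure(
    list(
      cloud = as_point_cloud_keep(cloud),
      trees = pars,
      spec = list(n_trees = n_trees, spacing = spacing, defects = defects,
                  glued_gap = glued_gap, gap_band = gap_band,
                  distractors = distractors, ground = ground,
                  trunk_density = trunk_density, crown_density = crown_density,
                  noise_sigma = noise_sigma, seed = seed)
    ),
    class = "tree_scene"
  )
}

#' @export
print.tree_scene <- function(x, ...) {
  cat(sprintf("synthetic street scene: %d trees, %d points (seed %d)\n",
              nrow(x$trees), nrow(x$cloud), x$spec$seed))
  if (length(x$spec$defects) > 0) {
    cat("  defects:", paste(x$spec$defects, collapse = ", "), "\n")
  }
  if (length(x$spec$distractors) > 0) {
    cat("  distractors:", paste(x$spec$distractors, collapse = ", "), "\n")
  }
  invisible(x)
}
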