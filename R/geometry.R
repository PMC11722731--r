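#' @useDynLib streetseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats median setNames
#' @keywords internal
"_PACKAGE"

# ---- internal geometry kernel -------------------------------------------
# All polygons are n x 2 matrices of CCW vertices, no repeated closing row.

# robust XY extraction: named columns when present, else first two
xy_of <- function(points) {
  m <- as.matrix(as.data.frame(points))
  m <- if (all(c("x", "y") %in% colnames(m))) {
    m[, c("x", "y"), drop = FALSE]
  } else {
    m[, 1:2, drop = FALSE]
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

#' Convex hull of 2D points by the quickhull recursion
#'
#' Builds the minimum convex polygon of a planar point set by the classic
#' farthest-point ("fast package") recursion: the two extreme points in x
#' (ties broken on y) define a chord; each half-set is expanded by the point
#' farthest from the chord until no point lies outside. This is the hull
#' construction the crown-diameter and crown-area morphometry rests on.
#'
#' @param xy numeric matrix or data frame with two columns (x, y).
#' @return matrix of hull vertices in counter-clockwise order (duplicated
#'   input points collapsed). Degenerate inputs (fewer than 3 distinct
#'   non-collinear points) raise an error.
#' @export
#' @examples
#' quickhull(cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)))
quickhull <- function(xy) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy))) abort("non-finite coordinates in hull input")
  xy <- unique(xy)
  if (nrow(xy) < 3) abort("degenerate hull input: fewer than 3 distinct points")

  # extreme points, prioritising the x coordinate
  ord <- order(xy[, 1], xy[, 2])
  p_lo <- xy[ord[1], ]
  p_hi <- xy[ord[nrow(xy)], ]

  side <- apply(xy, 1, function(p) cross2(p_lo, p_hi, p))
  upper <- xy[side > 1e-12, , drop = FALSE]   # left of lo->hi
  lower <- xy[side < -1e-12, , drop = FALSE]  # right of lo->hi
  if (nrow(upper) == 0 && nrow(lower) == 0) {
    abort("degenerate hull input: all points collinear")
  }

  expand <- function(a, b, pts) {
    # points strictly left of a->b; returns CCW chain between a and b (exclusive)
    if (nrow(pts) == 0) return(NULL)
    d <- apply(pts, 1, function(p) cross2(a, b, p))
    keep <- d > 1e-12
    if (!any(keep)) return(NULL)
    pts <- pts[keep, , drop = FALSE]
    d <- d[keep]
    far <- pts[which.max(d), ]
    rbind(expand(a, far, pts), far, expand(far, b, pts))
  }

  hull <- rbind(p_lo, expand(p_lo, p_hi, upper), p_hi, expand(p_hi, p_lo, lower))
  hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]  # orient CCW
  rownames(hull) <- NULL
  colnames(hull) <- c("x", "y")
  hull
}

#' Signed/absolute polygon area (shoelace formula)
#' @param poly matrix of polygon vertices (ordered, not closed).
#' @return area in squared input units (absolute value).
#' @export
shoelace_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex `clip`.
# Both CCW. Returns matrix (possibly 0-row).
clip_convex <- function(subject, clip) {
  out <- as.matrix(subject)
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    inside <- apply(out, 1, function(p) cross2(a, b, p) >= -1e-12)
    nxt <- matrix(numeric(0), ncol = 2)
    no <- nrow(out)
    for (j in seq_len(no)) {
      k <- if (j == no) 1 else j + 1
      p <- out[j, ]; q <- out[k, ]
      if (inside[j]) nxt <- rbind(nxt, p)
      if (inside[j] != inside[k]) {
        # segment crosses the clip edge: line-line intersection
        d1 <- cross2(a, b, p); d2 <- cross2(a, b, q)
        t <- d1 / (d1 - d2)
        nxt <- rbind(nxt, p + t * (q - p))
      }
    }
    out <- nxt
  }
  out
}

# Intersection area of two convex CCW polygons.
convex_intersection_area <- function(p1, p2) {
  if (is.null(p1) || is.null(p2) || nrow(p1) < 3 || nrow(p2) < 3) return(0)
  shoelace_area(clip_convex(p1, p2))
}

# point-in-convex-polygon (boundary counts as inside)
points_in_convex <- function(xy, poly) {
  xy <- as.matrix(xy)
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(xy))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    s <- (b[1] - a[1]) * (xy[, 2] - a[2]) - (b[2] - a[2]) * (xy[, 1] - a[1])
    inside <- inside & (s >= -1e-9)
  }
  inside
}

# Evaluate f() with a temporary RNG state seeded from `seed`; global
# .Random.seed is restored afterwards so callers' RNG streams are untouched.
with_local_seed <- function(seed, f) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}
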