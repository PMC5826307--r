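# Hull and alpha-complex geometry primitives.

#' Area of the 2-D convex hull of projected points
#'
#' @param xy two-column matrix of planar coordinates.
#' @return hull area; 0 if fewer than 3 distinct points.
#' @export
hull_area_2d <- function(xy) {
  xy <- unique(as.matrix(xy)[, 1:2, drop = FALSE])
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# signed volume of one tetrahedron given a 4 x 3 coordinate matrix
tet_volume <- function(p) {
  a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]; d <- p[4, ] - p[1, ]
  (a[1] * (b[2] * d[3] - b[3] * d[2]) -
   a[2] * (b[1] * d[3] - b[3] * d[1]) +
   a[3] * (b[1] * d[2] - b[2] * d[1])) / 6
}

# circumradius of one tetrahedron; Inf when degenerate (flat)
tet_circumradius <- function(p) {
  m <- sweep(p[2:4, , drop = FALSE], 2, p[1, ])
  rhs <- 0.5 * rowSums(m^2)
  det <- det(m)
  if (abs(det) < 1e-13 * (sum(m^2) + 1e-300)^1.5) return(Inf)
  u <- solve(m, rhs)
  sqrt(sum(u^2))
}

#' Delaunay tetrahedralization of a 3-D point set
#'
#' Incremental Bowyer-Watson triangulation.  Degenerate configurations
#' (cospherical or coplanar subsets) are resolved by a deterministic
#' symbolic-style jitter applied internally; the returned tetrahedra always
#' partition the convex hull of the input points.
#'
#' @param points n x 3 numeric matrix.
#' @return integer matrix with one row per tetrahedron and four 1-based
#'   vertex indices per row.
#' @export
delaunay_tetrahedra <- function(points) {
  points <- as.matrix(points)[, 1:3, drop = FALSE]
  storage.mode(points) <- "double"
  cpp_delaunay(points)
}

#' Convex-hull and alpha-complex volumes of a point cloud
#'
#' Both volumes are evaluated on the Delaunay tetrahedralization: the hull
#' volume is the total volume of all tetrahedra, the alpha volume keeps only
#' tetrahedra whose circumradius is at most `alpha` (the alpha complex).
#' `alpha = Inf` therefore recovers the convex hull, and
#' `alpha_volume(p, a) <= convex_hull_volume(p)` for every `a`.
#'
#' @param points n x 3 numeric matrix (needs at least 4 non-coplanar
#'   points for a positive volume).
#' @param alpha alpha radius in metres; `Inf` for the convex hull.
#' @return volume in cubic metres.  Coplanar/collinear inputs yield 0 with a
#'   warning rather than an error.
#' @export
alpha_volume <- function(points, alpha) {
  crown_volumes(points, alpha)$alpha
}

#' @rdname alpha_volume
#' @export
convex_hull_volume <- function(points) {
  crown_volumes(points, Inf)$hull
}

#' @rdname alpha_volume
#' @return `crown_volumes()` returns both as `list(alpha =, hull =)`,
#'   computing the triangulation once.
#' @export
crown_volumes <- function(points, alpha) {
  points <- as.matrix(points)[, 1:3, drop = FALSE]
  storage.mode(points) <- "double"
  if (nrow(points) < 4L || coplanar_points(points)) {
    warning("fewer than 4 non-coplanar points: volumes are zero", call. = FALSE)
    return(list(alpha = 0, hull = 0))
  }
  tets <- cpp_delaunay(points)
  if (nrow(tets) == 0L) {
    warning("degenerate point configuration: volumes are zero", call. = FALSE)
    return(list(alpha = 0, hull = 0))
  }
  # signed volumes (tets arrive positively oriented up to degeneracy, so
  # folded slivers cancel and the total is the exact hull volume)
  vols <- numeric(nrow(tets))
  keep <- logical(nrow(tets))
  for (t in seq_len(nrow(tets))) {
    p <- points[tets[t, ], , drop = FALSE]
    vols[t] <- tet_volume(p)
    keep[t] <- is.infinite(alpha) || tet_circumradius(p) <= alpha
  }
  list(alpha = max(0, sum(vols[keep])), hull = sum(vols))
}

# TRUE when the point set spans fewer than 3 dimensions
coplanar_points <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sv[3] <= max(sv[1], 1e-300) * 1e-10
}
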