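#' Estimate the stem axis of a tree
#'
#' The axis is the first principal component of the extracted stem points,
#' re-oriented to point upward.  Stem extraction keeps the points in the
#' lowest `lower_fraction` of the tree's height range that lie within
#' `stem_radius` metres (horizontally) of the cloud's horizontal median —
#' for deep-crowned trees the lower cloud is otherwise foliage-dominated
#' and the leading component no longer tracks the trunk.  If the resulting
#' axis deviates from the vertical by more than `max_tilt_deg`, the
#' estimate falls back to the vertical line through the horizontal centroid
#' of all points, with a warning.
#'
#' @param tree a [tree_cloud()].
#' @param lower_fraction fraction of the height range whose points enter the
#'   stem extraction (default 0.25).
#' @param stem_radius horizontal stem-extraction radius, metres (default 1).
#' @param max_tilt_deg maximum accepted deviation from vertical, degrees.
#' @param max_stem_spread maximum root-mean-square spread of the extracted
#'   points around the fitted axis, metres (default 0.35); a larger spread
#'   means the extraction caught foliage rather than a stem, and the
#'   estimate falls back to the vertical.
#' @return object of class `stem_axis`: list with `point` (a point on the
#'   axis), `direction` (upward unit vector) and `method`
#'   (`"pca"` or `"vertical_fallback"`).
#' @export
estimate_stem_axis <- function(tree, lower_fraction = 0.25, stem_radius = 1,
                               max_tilt_deg = 30, max_stem_spread = 0.35) {
  stopifnot(inherits(tree, "tree_cloud"))
  pts <- tree$points
  zr <- range(pts[, "z"])
  sel <- pts[, "z"] <= zr[1] + lower_fraction * (zr[2] - zr[1])
  low <- pts[sel, , drop = FALSE]
  if (nrow(low) >= 3L && is.finite(stem_radius)) {
    ctr <- c(stats::median(low[, "x"]), stats::median(low[, "y"]))
    near <- sqrt((low[, "x"] - ctr[1])^2 + (low[, "y"] - ctr[2])^2) <= stem_radius
    low <- low[near, , drop = FALSE]
  }

  fallback <- function(reason) {
    warning(sprintf("tree '%s': stem axis fell back to vertical (%s)",
                    tree$tree_id, reason), call. = FALSE)
    structure(list(point = c(mean(pts[, "x"]), mean(pts[, "y"]), zr[1]),
                   direction = c(0, 0, 1), method = "vertical_fallback"),
              class = "stem_axis")
  }

  if (nrow(low) < 10L) {
    return(fallback("too few extracted stem points for a reliable axis"))
  }
  if (diff(range(low[, "z"])) < 2) {
    return(fallback("extracted stem segment spans < 2 m"))
  }
  sds <- apply(low, 2, stats::sd)
  if (all(sds < 1e-12)) return(fallback("degenerate lower cloud"))
  pc <- stats::prcomp(low, center = TRUE, scale. = FALSE)
  d <- pc$rotation[, 1]
  d <- d / sqrt(sum(d^2))
  if (d[3] < 0) d <- -d
  tilt <- acos(pmin(1, abs(d[3]))) * 180 / pi
  if (!is.finite(tilt) || tilt > max_tilt_deg) {
    return(fallback(sprintf("axis tilt %.1f deg exceeds %.0f deg",
                            tilt, max_tilt_deg)))
  }
  spread <- sqrt(sum(pc$sdev[2:3]^2))
  if (!is.finite(spread) || spread > max_stem_spread) {
    return(fallback(sprintf(
      "extracted points spread %.2f m around the axis (not stem-like)",
      spread)))
  }
  structure(list(point = unname(pc$center), direction = unname(d),
                 method = "pca"),
            class = "stem_axis")
}

# horizontal (x, y) position of the axis at elevation z
axis_xy_at <- function(axis, z) {
  p <- axis$point
  d <- axis$direction
  t <- (z - p[3]) / d[3]
  cbind(p[1] + t * d[1], p[2] + t * d[2])
}

#' @export
print.stem_axis <- function(x, ...) {
  cat(sprintf("<stem_axis> through (%.2f, %.2f, %.2f), dir (%.3f, %.3f, %.3f), %s\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3], x$method))
  invisible(x)
}
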