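#' Azimuthal sector of horizontal offsets
#'
#' Sector 1 covers azimuths \[0, 45) degrees measured from geographic east,
#' counter-clockwise; sectors 2..8 follow every 45 degrees.  The convention
#' is arbitrary but fixed, so that sector-indexed features are reproducible.
#'
#' @param dx,dy horizontal offsets from the stem axis.
#' @return integer vector of sector indices in 1..8.
#' @export
azimuth_sector <- function(dx, dy) {
  az <- atan2(dy, dx) * 180 / pi
  az <- az %% 360
  as.integer(floor(az / 45)) + 1L
}

#' Detect the crown base from the vertical point-density profile
#'
#' Points are binned into `bin` metre height slices from the lowest point
#' upward and the profile is smoothed with a 3-bin moving average; the crown
#' base is the lower edge of the first bin from which the smoothed count
#' stays at or above the threshold for three consecutive bins.  The
#' threshold is `min_fraction` of the smoothed maximum, with an absolute
#' floor of `min_count` points.  Sparse stem returns below the live crown
#' stay under that threshold (the sustained-crossing requirement keeps
#' isolated stray returns from triggering it), while the contiguous crown
#' profile exceeds it from its base upward.
#'
#' @param z point elevations (metres).
#' @param bin slice thickness, metres (default 0.5).
#' @param min_fraction density threshold as a fraction of the maximum
#'   smoothed bin count (default 0.05).
#' @param min_count absolute threshold floor in points (default 2).
#' @return crown base elevation, metres.
#' @export
detect_crown_base <- function(z, bin = 0.5, min_fraction = 0.05,
                              min_count = 2) {
  z0 <- min(z)
  idx <- floor((z - z0) / bin)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  sm <- smooth3(counts)
  thr <- max(min_fraction * max(sm), min(min_count, max(sm)))
  above <- sm >= thr
  nb <- length(above)
  run <- 3L
  sustained <- which(vapply(seq_len(nb), function(i) {
    all(above[i:min(nb, i + run - 1L)])
  }, TRUE))
  first <- if (length(sustained)) sustained[1] else which(above)[1]
  z0 + (first - 1L) * bin
}

#' Build the geometric scaffolding of a tree crown
#'
#' Derives, from a [tree_cloud()], everything the structural feature
#' formulas consume: crown extent, projected crown area and radius, an
#' axis-aligned voxel grid over the crown points, the partition of the
#' occupied voxels into 8 azimuthal sectors around the stem axis, and
#' `n_layers` equal-thickness vertical crown layers.
#'
#' Voxels are cubes of `voxel_size` anchored at the crown points' minimum
#' corner, with half-open `[min, max)` intervals per axis; a voxel is
#' occupied if at least one point falls in it.
#'
#' @param tree a [tree_cloud()].
#' @param voxel_size voxel edge length, metres (default 0.5).
#' @param n_layers number of vertical crown layers (default 8).
#' @param crown_base optional crown base elevation (metres); if `NULL`
#'   (default) it is detected with [detect_crown_base()].
#' @param axis optional [estimate_stem_axis()] result; estimated if `NULL`.
#' @return object of class `crown_frame`: list with elements `tree_id`,
#'   `dtm_z`, `axis`, `voxel_size`, `n_layers`, `crown_base_z`,
#'   `crown_top_z`, `Lc` (crown length), `Rc` (crown radius), `A_base`
#'   (projected crown area), `crown_points` (points with z >= crown base),
#'   `voxels` (data frame: grid indices, point count, centre coordinates,
#'   height above crown base, horizontal axis distance, sector, layer) and
#'   `layer_voxel_counts`.
#' @export
build_crown_frame <- function(tree, voxel_size = 0.5, n_layers = 8L,
                              crown_base = NULL, axis = NULL) {
  stopifnot(inherits(tree, "tree_cloud"))
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop("'voxel_size' must be positive")
  }
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 2L) stop("'n_layers' must be >= 2")
  if (is.null(axis)) axis <- estimate_stem_axis(tree)

  pts <- tree$points
  crown_top_z <- max(pts[, "z"])
  crown_base_z <- if (is.null(crown_base)) {
    detect_crown_base(pts[, "z"])
  } else {
    as.numeric(crown_base)
  }
  crown <- pts[pts[, "z"] >= crown_base_z, , drop = FALSE]
  if (nrow(crown) < 3L) {
    stop(sprintf("tree '%s': degenerate crown, fewer than 3 points at or above the crown base",
                 tree$tree_id))
  }
  Lc <- crown_top_z - crown_base_z
  if (Lc <= 0) {
    stop(sprintf("tree '%s': degenerate crown, non-positive crown length",
                 tree$tree_id))
  }

  ax_xy <- axis_xy_at(axis, crown[, "z"])
  dists <- sqrt((crown[, "x"] - ax_xy[, 1])^2 + (crown[, "y"] - ax_xy[, 2])^2)
  Rc <- max(dists)
  if (Rc <= 0) {
    stop(sprintf("tree '%s': degenerate crown, zero crown radius", tree$tree_id))
  }
  A_base <- hull_area_2d(crown[, c("x", "y"), drop = FALSE])

  anchor <- c(min(crown[, "x"]), min(crown[, "y"]), min(crown[, "z"]))
  ii <- floor(sweep(crown, 2, anchor) / voxel_size)
  key <- paste(ii[, 1], ii[, 2], ii[, 3], sep = "_")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  ijk <- do.call(rbind, strsplit(agg$key, "_", fixed = TRUE))
  vox <- data.frame(ix = as.integer(ijk[, 1]), iy = as.integer(ijk[, 2]),
                    iz = as.integer(ijk[, 3]), count = agg$Freq)
  vox$cx <- anchor[1] + (vox$ix + 0.5) * voxel_size
  vox$cy <- anchor[2] + (vox$iy + 0.5) * voxel_size
  vox$cz <- anchor[3] + (vox$iz + 0.5) * voxel_size
  vax <- axis_xy_at(axis, vox$cz)
  vox$height <- vox$cz - crown_base_z
  vox$axis_dist <- sqrt((vox$cx - vax[, 1])^2 + (vox$cy - vax[, 2])^2)
  vox$sector <- azimuth_sector(vox$cx - vax[, 1], vox$cy - vax[, 2])
  layer_h <- Lc / n_layers
  vox$layer <- pmin(pmax(floor((vox$cz - crown_base_z) / layer_h), 0), n_layers - 1L) + 1L

  structure(
    list(tree_id = tree$tree_id, dtm_z = tree$dtm_z, axis = axis,
         voxel_size = voxel_size, n_layers = n_layers,
         crown_base_z = crown_base_z, crown_top_z = crown_top_z,
         Lc = Lc, Rc = Rc, A_base = A_base,
         crown_points = crown, voxels = vox,
         layer_voxel_counts = tabulate(vox$layer, nbins = n_layers)),
    class = "crown_frame"
  )
}

#' @export
print.crown_frame <- function(x, ...) {
  cat(sprintf(
    "<crown_frame '%s'> Lc = %.2f m, Rc = %.2f m, A_base = %.2f m^2, %d voxels (%.2g m), %d layers\n",
    x$tree_id, x$Lc, x$Rc, x$A_base, nrow(x$voxels), x$voxel_size, x$n_layers))
  invisible(x)
}
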