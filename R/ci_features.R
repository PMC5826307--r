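#' Names of the crown-internal feature parameters
#' @return character vector `P1`..`P13`.
#' @export
ci_feature_names <- function() paste0("P", 1:13)

# population (n-denominator) standard deviation; fixed for reproducibility
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Pearson correlation that treats zero-variance vectors as uncorrelated
cor_or_zero <- function(a, b) {
  if (pop_sd(a) <= 1e-12 || pop_sd(b) <= 1e-12) return(0)
  stats::cor(a, b)
}

#' Crown-internal (CI) structural feature parameters
#'
#' Computes the 13 crown-internal parameters `P1`..`P13` that quantify the
#' branch/leaf organization a tree architecture model predicts: sector-wise
#' voxel centroid positions and their spreads, point clustering, stem-space
#' occupancy, layer-profile regularity, alpha-shape compactness and
#' profile symmetry.
#'
#' Parameter contracts (heights are measured above the crown base wherever
#' they are normalized by the crown length `Lc`, so ratios land in `[0, 1]`):
#' * `P1`: mean over the 8 azimuthal sectors of (mean occupied-voxel-centre
#'   height within the sector) / `Lc`; empty sectors are excluded from the
#'   outer mean.
#' * `P2`: as `P1` but with mean horizontal voxel-centre distance to the
#'   stem axis, normalized by the crown radius `Rc`.
#' * `P3`: projected-hull area of the points in the lower third of the crown
#'   divided by the whole-crown projected area `A_base`; 0 if fewer than 3
#'   such points.
#' * `P4`: largest fraction of the crown's points falling into any single
#'   1 m super-voxel.
#' * `P5`, `P6`: population standard deviation of the 8 per-sector values
#'   entering `P1` and `P2`.
#' * `P7`: occupied voxels in the stem space (lower third of the crown,
#'   within `Rc / 2` of the axis) as a fraction of all occupied voxels.
#' * `P8`: whole-crown occupied-voxel centroid height / `Lc`.
#' * `P9`: population standard deviation of occupied-voxel counts across the
#'   vertical crown layers.
#' * `P10`: sum of absolute occupied-voxel count differences between
#'   adjacent layers, divided by the total occupied voxel count.
#' * `P11`: alpha-complex volume (default alpha 0.5 m) over convex-hull
#'   volume of the crown points.
#' * `P12`: sum of Pearson correlations of the per-layer voxel-count
#'   profiles of the 4 opposite sector pairs, divided by the same sum over
#'   the 8 adjacent pairs; zero-variance profiles contribute 0.
#' * `P13`: `P5 / P6`, with a sentinel 0 (and a warning) when `P6` is
#'   numerically zero.
#'
#' @param frame a [build_crown_frame()] result.
#' @param alpha alpha radius for `P11`, metres (default 0.5).
#' @param supervoxel super-voxel edge length for `P4`, metres (default 1).
#' @return named numeric vector of class `ci_features` with elements
#'   `P1`..`P13`; attribute `sentinel` flags parameters forced to their
#'   degenerate-denominator sentinel.
#' @export
compute_ci_features <- function(frame, alpha = 0.5, supervoxel = 1) {
  stopifnot(inherits(frame, "crown_frame"))
  vox <- frame$voxels
  if (nrow(vox) < 1L) stop("degenerate crown frame: no occupied voxels")
  Lc <- frame$Lc
  Rc <- frame$Rc
  V <- frame$n_layers
  crown <- frame$crown_points
  sentinel <- character(0)

  # per-sector relative centroid height and radius
  mh <- mr <- rep(NA_real_, 8)
  for (s in 1:8) {
    sv <- vox[vox$sector == s, , drop = FALSE]
    if (nrow(sv)) {
      mh[s] <- mean(sv$height) / Lc
      mr[s] <- mean(sv$axis_dist) / Rc
    }
  }
  present <- !is.na(mh)
  if (!all(present)) {
    message(sprintf("tree '%s': %d empty sector(s) excluded from P1/P2/P5/P6",
                    frame$tree_id, sum(!present)))
  }
  P1 <- mean(mh[present])
  P2 <- mean(mr[present])
  P5 <- pop_sd(mh[present])
  P6 <- pop_sd(mr[present])

  lower <- crown[crown[, "z"] <= frame$crown_base_z + Lc / 3, , drop = FALSE]
  P3 <- if (nrow(lower) < 3L) 0 else hull_area_2d(lower[, c("x", "y")]) / frame$A_base

  sv_anchor <- c(min(crown[, "x"]), min(crown[, "y"]), min(crown[, "z"]))
  sk <- floor(sweep(crown, 2, sv_anchor) / supervoxel)
  P4 <- max(table(paste(sk[, 1], sk[, 2], sk[, 3], sep = "_"))) / nrow(crown)

  in_stem_space <- vox$height <= Lc / 3 & vox$axis_dist <= Rc / 2
  P7 <- sum(in_stem_space) / nrow(vox)

  P8 <- mean(vox$height) / Lc

  lay <- frame$layer_voxel_counts
  P9 <- pop_sd(lay)
  P10 <- sum(abs(diff(lay))) / nrow(vox)

  cv <- crown_volumes(crown, alpha)
  if (cv$hull <= 0) {
    P11 <- 0
    sentinel <- c(sentinel, "P11")
  } else {
    P11 <- cv$alpha / cv$hull
  }

  S <- matrix(0, nrow = 8, ncol = V)
  tab <- table(factor(vox$sector, levels = 1:8), factor(vox$layer, levels = 1:V))
  S[] <- as.numeric(tab)
  opp <- sum(vapply(1:4, function(i) cor_or_zero(S[i, ], S[i + 4, ]), 0))
  adj <- sum(vapply(1:8, function(i) cor_or_zero(S[i, ], S[(i %% 8) + 1, ]), 0))
  if (abs(adj) <= 1e-12) {
    warning(sprintf("tree '%s': P12 denominator is zero; sentinel 0 reported",
                    frame$tree_id), call. = FALSE)
    P12 <- 0
    sentinel <- c(sentinel, "P12")
  } else {
    P12 <- opp / adj
  }

  if (P6 > 1e-9) {
    P13 <- P5 / P6
  } else {
    warning(sprintf("tree '%s': P6 is numerically zero; P13 sentinel 0 reported",
                    frame$tree_id), call. = FALSE)
    P13 <- 0
    sentinel <- c(sentinel, "P13")
  }

  out <- c(P1 = P1, P2 = P2, P3 = P3, P4 = P4, P5 = P5, P6 = P6, P7 = P7,
           P8 = P8, P9 = P9, P10 = P10, P11 = P11, P12 = P12, P13 = P13)
  structure(out, class = "ci_features", sentinel = sentinel)
}
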