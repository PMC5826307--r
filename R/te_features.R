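#' Names of the tree-external feature parameters
#' @return character vector of the 10 TE column names.
#' @export
te_feature_names <- function() {
  c("Ht", "LcHt", "D_EA", "Alpha", "LcD_EA",
    "llls_lhls_proxy", "ls_lcs_proxy", "Gc", "P_L", "LAI_proj")
}

#' Fit a unit-amplitude Gaussian to a vertical density profile
#'
#' Fits `g(h) = exp(-(h - u)^2 / (2 a^2))` by least squares to a profile
#' normalized to maximum 1 (the amplitude is fixed, only location `u` and
#' spread `a` are free).  Starting values come from the profile's weighted
#' moments; if the optimizer fails, those moment estimates are returned with
#' a warning.
#'
#' @param h profile bin mid-heights.
#' @param y profile values (any nonnegative scale; normalized internally).
#' @return list with `u`, `alpha`, `converged`.
#' @export
fit_gaussian_profile <- function(h, y) {
  stopifnot(length(h) == length(y), length(h) >= 3L)
  if (max(y) <= 0) stop("profile has no mass")
  y <- y / max(y)
  w <- pmax(y, 0)
  u0 <- sum(h * w) / sum(w)
  a0 <- sqrt(sum(w * (h - u0)^2) / sum(w))
  if (!is.finite(a0) || a0 <= 0) a0 <- diff(range(h)) / 4
  df <- data.frame(h = h, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ exp(-(h - u)^2 / (2 * a^2)), data = df,
      start = list(u = u0, a = a0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("Gaussian profile fit did not converge; second-moment spread used",
            call. = FALSE)
    return(list(u = u0, alpha = a0, converged = FALSE))
  }
  cf <- stats::coef(fit)
  p <- c(unname(cf["u"]), unname(cf["a"]))
  # a few Gauss-Newton steps polish the LM solution to machine precision
  sse <- function(q) sum((y - exp(-(h - q[1])^2 / (2 * q[2]^2)))^2)
  for (it in 1:25) {
    g <- exp(-(h - p[1])^2 / (2 * p[2]^2))
    J <- cbind(g * (h - p[1]) / p[2]^2, g * (h - p[1])^2 / p[2]^3)
    step <- tryCatch(solve(crossprod(J), crossprod(J, y - g)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    p_new <- p + as.vector(step)
    if (sse(p_new) <= sse(p)) p <- p_new else break
    if (max(abs(step)) < 1e-14) break
  }
  list(u = p[1], alpha = abs(p[2]), converged = TRUE)
}

# counts of crown points in nb equal height bins over [crown base, top];
# returns bin mid elevations and counts
crown_profile <- function(frame, nb) {
  z <- frame$crown_points[, "z"]
  edges <- seq(frame$crown_base_z, frame$crown_top_z, length.out = nb + 1L)
  idx <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L), nb)
  list(mid = (edges[-1] + edges[-(nb + 1L)]) / 2,
       count = tabulate(idx, nbins = nb))
}

# 3-bin moving average (window shrinks at the edges)
smooth3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - 1L):min(n, i + 1L)])
  }, 0)
}

# indices of strict local maxima of a profile
local_maxima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n)) {
    left <- if (i > 1L) x[i] > x[i - 1L] else x[i] > x[2L]
    right <- if (i < n) x[i] > x[i + 1L] else x[i] > x[n - 1L]
    if (left && right) out <- c(out, i)
  }
  out
}

# fraction of a 2-D projection's convex-hull area covered by occupied grid
# cells (count x cell area); clamped at 1 since straddling boundary cells
# otherwise overshoot slightly
grid_coverage <- function(uv, cell) {
  uv <- as.matrix(uv)
  hull <- hull_area_2d(uv)
  if (hull <= 0) {
    warning("degenerate 2-D projection; coverage reported as 1", call. = FALSE)
    return(1)
  }
  anchor <- c(min(uv[, 1]), min(uv[, 2]))
  ii <- floor(sweep(uv, 2, anchor) / cell)
  n_occ <- nrow(unique(ii))
  min(1, n_occ * cell^2 / hull)
}

#' Tree-external (TE) structural feature parameters
#'
#' Computes the 10 tree-external parameters: tree height `Ht`, crown
#' length/height ratio `LcHt`, area-equivalent crown diameter `D_EA`
#' (diameter of the circle whose area equals the projected crown area), the
#' spread `Alpha` of a Gaussian fitted to the vertical crown point profile,
#' `LcD_EA`, the relative positions of the lowest/highest density peaks
#' (`llls_lhls_proxy`) and of the maximum-density layer (`ls_lcs_proxy`),
#' the mean occupied-voxel height `Gc`, the side-projection grid coverage
#' `P_L` (laser penetration proxy) and the vertical-projection grid
#' coverage `LAI_proj`.
#'
#' `llls_lhls_proxy` and `ls_lcs_proxy` carry proxy names deliberately:
#' their defining quantities are identified here with the lowest/highest
#' local maxima of the smoothed (3-bin moving average) vertical density
#' profile and with the maximum-density profile bin.
#'
#' @param tree a [tree_cloud()].
#' @param frame the matching [build_crown_frame()].
#' @param grid_cell cell size of the 2-D projection grids, metres
#'   (default 0.5).
#' @param profile_bins number of vertical profile bins used for the Gaussian
#'   fit and the density-peak parameters (default 40).
#' @return named numeric vector of class `te_features` (see
#'   [te_feature_names()]).
#' @export
compute_te_features <- function(tree, frame, grid_cell = 0.5,
                                profile_bins = 40L) {
  stopifnot(inherits(tree, "tree_cloud"), inherits(frame, "crown_frame"))
  if (!is.numeric(grid_cell) || grid_cell <= 0) stop("'grid_cell' must be positive")
  crown <- frame$crown_points

  Ht <- max(tree$points[, "z"]) - tree$dtm_z
  LcHt <- frame$Lc / Ht
  D_EA <- 2 * sqrt(frame$A_base / pi)
  LcD_EA <- frame$Lc / D_EA

  prof <- crown_profile(frame, profile_bins)
  gfit <- fit_gaussian_profile(prof$mid - frame$crown_base_z, prof$count)
  Alpha <- gfit$alpha

  sm <- smooth3(prof$count)
  peaks <- local_maxima(sm)
  if (length(peaks) <= 1L) {
    llls <- 1
  } else {
    h_lls <- prof$mid[min(peaks)] - tree$dtm_z
    h_hls <- prof$mid[max(peaks)] - tree$dtm_z
    llls <- (Ht - h_lls) / (Ht - h_hls)
  }
  ls_lcs <- (prof$mid[which.max(prof$count)] - frame$crown_base_z) / frame$Lc

  Gc <- mean(frame$voxels$cz - tree$dtm_z)

  P_L <- (grid_coverage(crown[, c("x", "z")], grid_cell) +
          grid_coverage(crown[, c("y", "z")], grid_cell)) / 2
  LAI_proj <- grid_coverage(crown[, c("x", "y")], grid_cell)

  out <- c(Ht = Ht, LcHt = LcHt, D_EA = D_EA, Alpha = Alpha, LcD_EA = LcD_EA,
           llls_lhls_proxy = llls, ls_lcs_proxy = ls_lcs, Gc = Gc,
           P_L = P_L, LAI_proj = LAI_proj)
  structure(out, class = "te_features", gaussian_converged = gfit$converged)
}
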