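# Constructed point clouds used across the tests.

# vertical axis through the origin, as a stem_axis object
origin_axis <- function() {
  structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                 method = "manual"),
            class = "stem_axis")
}

# A perfectly 8-fold-symmetric crown for the symmetry-forcing checks.
#
# Voxel (0.5 m) centres are engineered onto the half-integer lattice so that
# every sector receives voxels with exactly the same heights and the same
# horizontal distances: each "ring" is a set of 8 lattice positions
# (+-a, +-b), (+-b, +-a) with a^2 + b^2 constant, one per 45-degree sector.
# Two anchor pins at (-5.25, 0.5) and (0.5, -5.25) pin the grid anchor so
# that those lattice positions are the actual voxel centres; the pins' own
# voxels complete the d = sqrt(25.25) ring in sectors 4 and 7.
#
# Layers carry varying ring counts, so every sector's per-layer profile is
# identical but non-constant: all profile correlations are exactly 1,
# P12 = 4/8, and the per-sector spreads P5 and P6 are exactly zero.
sym_crown <- function() {
  ring <- function(a, b, z) {
    rbind(c(a, b, z), c(b, a, z), c(-b, a, z), c(-a, b, z),
          c(-a, -b, z), c(-b, -a, z), c(b, -a, z), c(a, -b, z))
  }
  # ring "R1" (d^2 = 25.25): 6 explicit lattice points + 2 pins
  r1 <- function(z) {
    rbind(c(5, 0.5, z), c(0.5, 5, z), c(-0.5, 5, z),
          c(-5, -0.5, z), c(-0.5, -5, z), c(5, -0.5, z),
          c(-5.25, 0.5, z),    # pin; voxel centre (-5, 0.5), sector 4
          c(0.5, -5.25, z))    # pin; voxel centre (0.5, -5), sector 7
  }
  r2 <- function(z) ring(4, 1, z)
  r3 <- function(z) ring(3, 2, z)
  # vertical levels 0.3 + k, varying ring counts 2,1,3,1,2,1,3,1 per level
  pts <- rbind(
    r1(0.3), r2(0.3),
    r1(1.3),
    r1(2.3), r2(2.3), r3(2.3),
    r2(3.3),
    r1(4.3), r3(4.3),
    r3(5.3),
    r1(6.3), r2(6.3), r3(6.3),
    r2(7.3)
  )
  tree_cloud(pts, dtm_z = 0, tree_id = "sym8")
}

# frame for the symmetric crown: vertical axis, explicit crown base at 0
sym_crown_frame <- function(n_layers = 8L) {
  build_crown_frame(sym_crown(), voxel_size = 0.5, n_layers = n_layers,
                    crown_base = 0, axis = origin_axis())
}

# uniform solid cylinder crown centred on the origin
cylinder_cloud <- function(n, radius, height, z0 = 0, center = c(0, 0),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th),
        z0 + runif(n) * height)
}

# solid cone crown (apex up) centred on the origin
cone_cloud <- function(n, radius, height, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- height * (1 - runif(n)^(1 / 3))   # denser toward the wide base
  rmax <- radius * (1 - z / height)
  r <- rmax * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), z)
}

# generic irregular cloud in general position (for oracle comparisons)
generic_cloud <- function(n, seed, scale = c(4, 4, 8)) {
  set.seed(seed)
  sweep(matrix(runif(3 * n), ncol = 3), 2, scale, "*")
}

# a small deterministic feature table with well-separated classes
toy_feature_table <- function(n_per_class = 10, k_classes = 4, sep = 10,
                              seed = 2, p = 3) {
  set.seed(seed)
  rows <- list()
  for (cl in seq_len(k_classes)) {
    X <- matrix(rnorm(n_per_class * p, mean = sep * cl), ncol = p)
    colnames(X) <- paste0("F", seq_len(p))
    rows[[cl]] <- data.frame(
      tree_id = sprintf("c%d_%02d", cl, seq_len(n_per_class)),
      species = paste0("S", cl), X, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
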