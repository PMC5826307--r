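test_that("tree_cloud validates degenerate inputs", {
  pts <- cbind(runif(12), runif(12), runif(12, 3, 9))
  tc <- tree_cloud(pts, dtm_z = 0, tree_id = "ok")
  expect_s3_class(tc, "tree_cloud")
  expect_equal(nrow(tc$points), 12L)

  expect_error(tree_cloud(pts[1:3, ], 0, "tiny"), "tiny")
  expect_error(tree_cloud(pts[1:3, ], 0, "tiny"), "10 points")
  bad <- pts; bad[4, 2] <- NA
  expect_error(tree_cloud(bad, 0, "nonfinite"), "finite")
  expect_error(tree_cloud(pts, dtm_z = 100, tree_id = "below"), "dtm_z")
})

test_that("XYZ text and binary LAS readers round-trip coordinates", {
  set.seed(4)
  pts <- cbind(runif(60, 100, 110), runif(60, 200, 210), runif(60, 5, 25))

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write.table(pts, xyz, row.names = FALSE, col.names = FALSE)
  tc1 <- read_tree_cloud(xyz, dtm_z = 2)
  expect_equal(nrow(tc1$points), 60L)
  expect_equal(unname(tc1$points), unname(pts), tolerance = 1e-7)

  las <- withr::local_tempfile(fileext = ".las")
  write_las(pts, las)
  tc2 <- read_tree_cloud(las, dtm_z = 2, tree_id = "t2")
  expect_equal(nrow(tc2$points), 60L)
  expect_equal(unname(tc2$points), unname(pts), tolerance = 2e-3)

  # determinism: reading the same file twice gives identical point sets
  tc3 <- read_tree_cloud(las, dtm_z = 2, tree_id = "t3")
  expect_identical(tc2$points, tc3$points)

  # degenerate gate: three rows parse but fail the minimum point count
  small <- withr::local_tempfile(fileext = ".xyz")
  write.table(pts[1:3, ], small, row.names = FALSE, col.names = FALSE)
  expect_error(read_tree_cloud(small, dtm_z = 0, tree_id = "t4"), "t4")

  expect_error(read_tree_cloud("no/such/file.xyz", 0), "not found")
  laz <- withr::local_tempfile(fileext = ".laz")
  writeBin(c(charToRaw("LASZ"), raw(100)), laz)
  expect_error(read_tree_cloud(laz, 0), "LAZ")
})

test_that("manifest resolves relative paths and load_stand labels trees", {
  dir <- withr::local_tempdir()
  for (id in c("a", "b")) {
    pts <- cbind(runif(20), runif(20), runif(20, 2, 8))
    write.table(pts, file.path(dir, paste0(id, ".xyz")),
                row.names = FALSE, col.names = FALSE)
  }
  man <- data.frame(tree_id = c("a", "b"), path = c("a.xyz", "b.xyz"),
                    dtm_z = c(0, 1), species = c("PA", "QR"))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(man, mpath, row.names = FALSE)

  trees <- load_stand(mpath)
  expect_named(trees, c("a", "b"))
  expect_equal(trees$b$dtm_z, 1)
  expect_equal(trees$a$species, "PA")

  bad <- man[, c("tree_id", "dtm_z")]
  bpath <- file.path(dir, "bad.csv")
  write.csv(bad, bpath, row.names = FALSE)
  expect_error(read_manifest(bpath), "path")
})

test_that("stem axis: exact vertical stems, cylinder centring, degenerate fallback", {
  # points on the vertical line x = 1, y = 2
  line <- cbind(rep(1, 50), rep(2, 50), seq(0, 10, length.out = 50))
  tc <- tree_cloud(line, dtm_z = 0, tree_id = "line")
  ax <- estimate_stem_axis(tc)
  expect_equal(ax$direction, c(0, 0, 1))
  expect_equal(axis_xy_at(ax, 5)[1, ], c(1, 2), ignore_attr = TRUE)

  # noisy vertical cylinder: axis within 5 cm of the least-squares centre
  cyl <- cylinder_cloud(500, radius = 0.1, height = 12, center = c(1.3, -0.7),
                        seed = 7)
  tcyl <- tree_cloud(cyl, dtm_z = 0, tree_id = "cyl")
  axc <- estimate_stem_axis(tcyl)
  ls_center <- colMeans(cyl[, 1:2])   # least-squares centre of a full cylinder
  expect_lt(max(abs(axis_xy_at(axc, 6)[1, ] - ls_center)), 0.05)

  # a horizontal plane of points has no stem: vertical fallback, logged
  set.seed(1)
  plane <- cbind(runif(200, -5, 5), runif(200, -5, 5), 3 + runif(200, 0, 1e-4))
  tpl <- tree_cloud(plane, dtm_z = 0, tree_id = "plane")
  expect_warning(axp <- estimate_stem_axis(tpl), "fell back")
  expect_equal(axp$method, "vertical_fallback")
  expect_equal(axp$direction, c(0, 0, 1))
  expect_equal(axp$point[1:2], colMeans(plane[, 1:2]), tolerance = 1e-8)
})

test_that("crown frame partitions voxels into sectors and layers", {
  # one point per 45-degree sector plus sparse stem returns below the base
  az <- c(10, 55, 100, 145, 190, 235, 280, 325) * pi / 180
  pts <- rbind(cbind(3 * cos(az), 3 * sin(az), 5 + seq(0, 0.28, by = 0.04)),
               cbind(runif(3, -0.05, 0.05), runif(3, -0.05, 0.05), c(1, 2, 3)))
  tc <- tree_cloud(pts, dtm_z = 0, tree_id = "sectors")
  fr <- build_crown_frame(tc, crown_base = 4, axis = origin_axis())
  expect_equal(nrow(fr$voxels), 8L)
  expect_equal(sort(fr$voxels$sector), 1:8)
  expect_equal(as.integer(table(fr$voxels$sector)), rep(1L, 8))

  # sectors partition the voxels and layer counts sum to the voxel total
  sim <- simulate_tree(archetype_config("QR"), seed = 3)
  frq <- build_crown_frame(sim)
  expect_true(all(frq$voxels$sector %in% 1:8))
  expect_equal(sum(frq$layer_voxel_counts), nrow(frq$voxels))
  for (V in c(2L, 5L, 13L)) {
    frv <- build_crown_frame(sim, n_layers = V)
    expect_length(frv$layer_voxel_counts, V)
    expect_equal(sum(frv$layer_voxel_counts), nrow(frv$voxels))
  }

  # degenerate crown: a manual base above every point
  expect_error(build_crown_frame(sim, crown_base = 1e4), "degenerate crown")
})

test_that("voxel grid arithmetic on a unit cube and hull-area oracle", {
  set.seed(9)
  cube <- matrix(runif(600), ncol = 3)
  tc <- tree_cloud(cube, dtm_z = -1, tree_id = "cube")
  fr <- build_crown_frame(tc, voxel_size = 0.5, crown_base = 0,
                          axis = origin_axis())
  expect_equal(nrow(fr$voxels), 8L)

  cone <- cone_cloud(2000, radius = 4, height = 10, seed = 3)
  tcn <- tree_cloud(cone, dtm_z = 0, tree_id = "cone")
  frc <- build_crown_frame(tcn, crown_base = 0, axis = origin_axis())
  ora <- oracle_hull_area(cone[, 1:2])
  expect_lt(abs(frc$A_base - ora) / ora, 0.05)
  expect_equal(frc$A_base, ora, tolerance = 1e-9)
})

test_that("voxel occupancy is invariant to point order", {
  sim <- simulate_tree(archetype_config("PS"), seed = 5)
  fr1 <- build_crown_frame(sim)
  set.seed(1)
  shuf <- sim
  shuf$points <- sim$points[sample(nrow(sim$points)), ]
  fr2 <- build_crown_frame(shuf, axis = fr1$axis,
                           crown_base = fr1$crown_base_z)
  key <- function(f) {
    v <- f$voxels[order(f$voxels$ix, f$voxels$iy, f$voxels$iz), ]
    rownames(v) <- NULL
    v
  }
  expect_equal(key(fr1), key(fr2))
})

test_that("rotating a cloud 90 degrees shifts sector labels by 2", {
  set.seed(8)
  dx <- runif(300, -5, 5)
  dy <- runif(300, -5, 5)
  s0 <- azimuth_sector(dx, dy)
  s90 <- azimuth_sector(-dy, dx)
  expect_equal(s90, (s0 + 2 - 1) %% 8 + 1)

  # per-sector voxel counts of the 8-fold-symmetric crown are one multiset
  fr <- sym_crown_frame()
  counts <- table(factor(fr$voxels$sector, levels = 1:8))
  expect_true(all(counts == counts[1]))
})

test_that("alpha and convex hull volumes: identities, degeneracies, ordering", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-9)
  expect_equal(alpha_volume(cube, Inf), 1, tolerance = 1e-9)

  flat <- cbind(runif(10), runif(10), 0)
  expect_warning(v <- convex_hull_volume(flat), "coplanar")
  expect_equal(v, 0)

  set.seed(1)
  sph <- matrix(rnorm(1500), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2)) * runif(500)^(1 / 3)
  expect_lte(alpha_volume(sph, 0.5), convex_hull_volume(sph))

  # monotone in alpha, bounded by the hull, on random clouds
  for (s in 1:10) {
    pts <- generic_cloud(40, seed = 100 + s, scale = c(2, 2, 2))
    v <- vapply(c(0.4, 0.8, 1.6, Inf), function(a) alpha_volume(pts, a), 0)
    expect_true(all(diff(v) >= -1e-9))
    expect_equal(v[4], convex_hull_volume(pts), tolerance = 1e-9)
  }
})

test_that("Delaunay volumes match the brute-force enumeration oracle", {
  for (s in c(31, 32, 33, 34, 35)) {
    set.seed(s)
    n <- sample(12:20, 1)
    pts <- matrix(runif(3 * n, 0, 2), ncol = 3)
    o <- oracle_volumes(pts, 0.8)
    m <- crown_volumes(pts, 0.8)
    expect_equal(m$hull, o$hull, tolerance = 1e-10)
    expect_equal(m$alpha, o$alpha, tolerance = 1e-10)
  }
})
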