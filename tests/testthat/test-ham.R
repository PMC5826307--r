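ref_models <- c(PA = "Massart", PS = "Rauh", PT = "Roux", QR = "Attim")

test_that("the packaged knowledge base is complete and consistent", {
  kb <- load_ham_knowledge()
  expect_setequal(names(kb$models), c("Massart", "Rauh", "Roux", "Attim"))
  expect_equal(as.character(kb$feature_pair), c("P4", "P7"))
  centers <- t(vapply(kb$models, function(m) as.numeric(m$center), numeric(2)))
  expect_equal(anyDuplicated(centers), 0L)
  expect_error(load_ham_knowledge("no/such.yaml"), "not found")
})

test_that("species centres are plain arithmetic means over the scoped trees", {
  tab <- data.frame(tree_id = c("a", "b", "c"),
                    species = c("PA", "PA", "QR"),
                    P4 = c(0.1, 0.3, 0.9), P7 = c(0.2, 0.4, 0.8))
  expect_equal(species_center(tab, "PA", c("P4", "P7")),
               c(P4 = 0.2, P7 = 0.3))
  expect_equal(species_center(tab, "QR", c("P4", "P7")),
               c(P4 = 0.9, P7 = 0.8))

  set.seed(4)
  big <- data.frame(tree_id = sprintf("t%02d", 1:50),
                    species = sample(c("PA", "PS"), 50, replace = TRUE),
                    P4 = runif(50), P7 = runif(50))
  ctr <- species_center(big, "PS", c("P4", "P7"))
  sel <- big$species == "PS"
  expect_equal(unname(ctr),
               c(sum(big$P4[sel]) / sum(sel), sum(big$P7[sel]) / sum(sel)))

  # correct_only on perfect predictions equals the plain group mean
  expect_equal(species_center(big, "PS", c("P4", "P7"),
                              predictions = big$species,
                              scope = "correct_only"), ctr)
  expect_error(species_center(tab, "PT", c("P4", "P7")), "PT")
})

test_that("nearest-centre assignment hits exact prototypes and is affine-invariant", {
  kb <- load_ham_knowledge()
  for (m in names(kb$models)) {
    asg <- assign_ham(as.numeric(kb$models[[m]]$center), kb)
    expect_equal(asg$ham, m)
    expect_gt(asg$margin, 0)
  }

  # rescaling both feature axes leaves assignments unchanged
  set.seed(6)
  for (i in 1:20) {
    ctr <- c(runif(1, 0.01, 0.15), runif(1, 0.005, 0.18))
    a1 <- assign_ham(ctr, kb)
    kb2 <- kb
    sc <- c(runif(1, 0.2, 50), runif(1, 0.2, 50))
    off <- c(runif(1, -3, 3), runif(1, -3, 3))
    for (m in names(kb2$models)) {
      kb2$models[[m]]$center <- as.numeric(kb2$models[[m]]$center) * sc + off
    }
    a2 <- assign_ham(ctr * sc + off, kb2)
    expect_equal(a2$ham, a1$ham)
    expect_equal(a2$margin, a1$margin, tolerance = 1e-9)
  }
})

test_that("the quadrant rule maps constructed quadrants and tie-breaks down", {
  kb <- load_ham_knowledge()
  map <- list(low_low = "Massart", high_low = "Rauh",
              low_high = "Attim", high_high = "Roux")
  asg <- assign_ham(c(0.9, 0.1), kb, rule = "quadrant",
                    thresholds = c(0.5, 0.5), quadrant_map = map)
  expect_equal(asg$ham, "Rauh")
  expect_equal(assign_ham(c(0.2, 0.9), kb, rule = "quadrant",
                          thresholds = c(0.5, 0.5),
                          quadrant_map = map)$ham, "Attim")
  expect_warning(
    tie <- assign_ham(c(0.5, 0.1), kb, rule = "quadrant",
                      thresholds = c(0.5, 0.5), quadrant_map = map),
    "cut line")
  expect_equal(tie$ham, "Massart")   # boundary counts as the lower quadrant
})

test_that("clustered species centres recover all four archetypes", {
  kb <- load_ham_knowledge()
  protos <- t(vapply(kb$models, function(m) as.numeric(m$center), numeric(2)))
  set.seed(6)
  hams <- rownames(protos)
  for (i in seq_along(hams)) {
    pts <- sweep(matrix(rnorm(40, sd = 0.004), ncol = 2), 2, protos[i, ], "+")
    ctr <- colMeans(pts)
    expect_equal(assign_ham(ctr, kb)$ham, hams[i])
  }
})

test_that("growth-habit records come back verbatim from the knowledge file", {
  kb <- load_ham_knowledge()
  roux <- habits_for("Roux", kb)
  expect_equal(roux$branches, "plagiotropic, monopodial, non-phyllomorphic")
  expect_equal(roux$growth, "continuous")
  expect_equal(habits_for("Attim", kb)$growth, "more or less continuous")
  expect_error(habits_for("Foo", kb), "Massart")
})

test_that("Gaussian divergence summary is zero on perfect predictions", {
  set.seed(8)
  tab <- data.frame(tree_id = sprintf("t%02d", 1:24),
                    species = rep(c("PA", "PS", "PT"), each = 8),
                    P4 = runif(24), P7 = runif(24))
  gs <- gaussian_summary(tab, tab$species, c("P4", "P7"))
  expect_equal(gs$delta_mu_pct, rep(0, nrow(gs)))
  expect_equal(gs$delta_sigma_pct, rep(0, nrow(gs)))
})

test_that("Gaussian divergences match a hand computation with one mislabel", {
  tab <- data.frame(tree_id = paste0("t", 1:6),
                    species = c("A", "A", "A", "B", "B", "B"),
                    P4 = c(1, 2, 3, 10, 11, 12))
  pred <- c("A", "A", "B", "B", "B", "B")   # t3 misassigned to B
  gs <- gaussian_summary(tab, pred, "P4")

  gt_a <- c(mu = 2, sigma = sqrt(2 / 3))
  dp_a <- c(mu = 1.5, sigma = 0.5)
  gt_b <- c(mu = 11, sigma = sqrt(2 / 3))
  dp_b <- c(mu = 9, sigma = sqrt(mean((c(3, 10, 11, 12) - 9)^2)))
  a <- gs[gs$species == "A", ]
  b <- gs[gs$species == "B", ]
  expect_equal(a$mu_dp, 1.5)
  expect_equal(a$delta_mu_pct, (gt_a["mu"] - dp_a["mu"]) / gt_a["mu"] * 100,
               ignore_attr = TRUE)
  expect_equal(a$delta_sigma_pct,
               (gt_a["sigma"] - dp_a["sigma"]) / gt_a["sigma"] * 100,
               ignore_attr = TRUE)
  expect_equal(b$mu_dp, 9)
  expect_equal(b$delta_mu_pct, (gt_b["mu"] - dp_b["mu"]) / gt_b["mu"] * 100,
               ignore_attr = TRUE)

  # singleton group: sigma collapses to zero with a warning
  expect_warning(gaussian_summary(tab, c("A", "A", "A", "A", "A", "B"), "P4"),
                 "size < 2")
})

test_that("divergences stay bounded at realistic classification accuracy", {
  sim <- simulate_stand(seed = 8, counts = c(PA = 10, PS = 10, PT = 10, QR = 10))
  tab <- suppressWarnings(compute_feature_table(sim$trees))
  set.seed(8)
  pred <- tab$species
  flip <- sample(nrow(tab), 6)              # 85% accuracy
  pred[flip] <- sample(unique(tab$species), 6, replace = TRUE)
  gs <- suppressWarnings(gaussian_summary(tab, pred, c("P1", "P2", "P8")))
  expect_true(all(abs(gs$delta_mu_pct) < 15, na.rm = TRUE))
})

test_that("identify_ham attaches models and habits per classified species", {
  sim <- simulate_stand(seed = 9, counts = c(PA = 4, PS = 4, PT = 4, QR = 4))
  tab <- suppressWarnings(compute_feature_table(sim$trees))
  asg <- identify_ham(tab)
  expect_equal(nrow(asg), 4L)
  expect_equal(asg$ham[match(names(ref_models), asg$species)],
               unname(ref_models))
  expect_true(all(nzchar(asg$growth)))
})
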