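# Synthetic ALS-like crown archetypes.
#
# The four point-placement recipes are structural caricatures of the four
# architecture models, designed so that their crown-internal signatures
# (tiered vs clustered vs layered vs columnar foliage) are expressed at
# airborne scanning densities.  They are a test harness for the pipeline,
# not a claim about real species.

#' Default simulation configuration for a species archetype
#'
#' Height and crown-length ranges follow the descriptive statistics of a
#' 40-tree boreal reference stand (Norway spruce PA, Scots pine PS,
#' European aspen PT, English oak QR); point density defaults to 10
#' points/m2, a typical airborne scanning density.
#'
#' @param species `"PA"`, `"PS"`, `"PT"` or `"QR"`.
#' @param ... overrides for any configuration field (`archetype`,
#'   `ht_range`, `lc_range`, `rc_range`, `density`, `noise_sd`,
#'   `tier_spacing`, `n_tiers`, `n_clusters`, `n_branches`,
#'   `stem_fraction`, `dtm_z`).
#' @return list of class `archetype_config`.
#' @export
archetype_config <- function(species = c("PA", "PS", "PT", "QR"), ...) {
  species <- match.arg(species)
  base <- switch(species,
    PA = list(archetype = "massart_tiered", ht_range = c(17.60, 28.38),
              lc_range = c(14.02, 27.38), rc_range = c(2.0, 3.5)),
    PS = list(archetype = "rauh_clustered", ht_range = c(16.66, 23.73),
              lc_range = c(5.67, 18.83), rc_range = c(2.5, 4.0)),
    PT = list(archetype = "roux_layered", ht_range = c(20.39, 25.98),
              lc_range = c(11.64, 20.11), rc_range = c(2.5, 4.5)),
    QR = list(archetype = "attim_columnar", ht_range = c(15.17, 25.94),
              lc_range = c(13.81, 18.94), rc_range = c(3.0, 5.0))
  )
  cfg <- c(list(species = species), base,
           list(density = 10, noise_sd = 0.15, tier_spacing = 1.6,
                n_tiers = NULL, n_clusters = 6, n_branches = 12,
                stem_fraction = 0.02, dtm_z = 0))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  ranges <- cfg[c("ht_range", "lc_range", "rc_range")]
  ok <- vapply(ranges, function(r) length(r) == 2 && all(r > 0) && r[1] <= r[2], TRUE)
  if (!all(ok)) stop("ranges must be positive and ordered (min, max)")
  if (cfg$density <= 0) stop("'density' must be positive")
  structure(cfg, class = "archetype_config")
}

# ---- archetype point recipes (axis at the origin, z = elevation) --------

# horizontal tiers of branch whorls inside a conical envelope; foliage sits
# on the outer part of each whorl, keeping the stem space empty
gen_massart <- function(n, cb, top, rc, spacing, n_tiers) {
  lc <- top - cb
  if (is.null(n_tiers)) n_tiers <- max(3L, floor(lc / spacing))
  tier_z <- cb + (seq_len(n_tiers) - 0.5) * lc / n_tiers
  tier_r <- rc * (1 - 0.85 * (tier_z - cb) / lc)     # cone, 15% radius at top
  w <- tier_r^1.5                                    # larger whorls carry more
  ti <- sample.int(n_tiers, n, replace = TRUE, prob = w / sum(w))
  r <- tier_r[ti] * (0.80 + 0.20 * sqrt(runif(n)))   # outer-shell annuli
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), tier_z[ti] + stats::rnorm(n, 0, 0.12))
}

# tight upward-elongated clusters in the upper crown
gen_rauh <- function(n, cb, top, rc, k) {
  lc <- top - cb
  czs <- runif(k, cb + 0.50 * lc, cb + 0.90 * lc)
  crs <- runif(k, 0.15, 0.70) * rc
  cth <- runif(k, 0, 2 * pi)
  wts <- runif(k, 0.4, 2)^3                          # strongly unequal clusters
  n_cl <- round(0.65 * n)
  ci <- sample.int(k, n_cl, replace = TRUE, prob = wts / sum(wts))
  cl <- cbind(crs[ci] * cos(cth[ci]) + stats::rnorm(n_cl, 0, 0.26),
              crs[ci] * sin(cth[ci]) + stats::rnorm(n_cl, 0, 0.26),
              czs[ci] + stats::rnorm(n_cl, 0, min(0.45, 0.06 * lc)))
  n_bg <- n - n_cl          # sparse outer-weighted fill over the full crown
  r <- rc * (0.35 + 0.65 * sqrt(runif(n_bg)))
  th <- runif(n_bg, 0, 2 * pi)
  bg <- cbind(r * cos(th), r * sin(th), runif(n_bg, cb, top))
  out <- rbind(cl, bg)
  out[, 3] <- pmin(pmax(out[, 3], cb), top)
  out
}

# continuous regular plagiotropic branching: evenly spaced horizontal branch
# layers at regular azimuths, foliage strung along the whole branch length
gen_roux <- function(n, cb, top, rc, n_branches) {
  lc <- top - cb
  m <- n_branches
  phi0 <- runif(1, 0, 2 * pi)                        # whole-tree rotation
  bth <- phi0 + (seq_len(m) - 1) * 2 * pi / m + stats::rnorm(m, 0, 0.08)
  bz <- cb + (seq_len(m) - 0.5) * lc / m + stats::rnorm(m, 0, lc / (4 * m))
  blen <- rc * (1 - 0.30 * (bz - cb) / lc)           # mild taper
  n_br <- round(0.7 * n)
  bi <- sample.int(m, n_br, replace = TRUE)
  t <- sqrt(runif(n_br))                             # mildly tip-weighted
  br <- cbind(t * blen[bi] * cos(bth[bi]) + stats::rnorm(n_br, 0, 0.15),
              t * blen[bi] * sin(bth[bi]) + stats::rnorm(n_br, 0, 0.15),
              bz[bi] + stats::rnorm(n_br, 0, 0.20))
  n_bg <- n - n_br          # twig fill, moderately outer-weighted
  r <- rc * (0.2 + 0.8 * sqrt(runif(n_bg)))
  th <- runif(n_bg, 0, 2 * pi)
  bg <- cbind(r * cos(th), r * sin(th), runif(n_bg, cb, top))
  out <- rbind(br, bg)
  out[, 3] <- pmin(pmax(out[, 3], cb), top)
  out
}

# dense near-uniform columnar fill: an inner core plus a handful of vertical
# sub-columns (main branches morphogenetically equivalent to the trunk)
gen_attim <- function(n, cb, top, rc) {
  n_core <- round(0.40 * n)
  r1 <- 0.40 * rc * sqrt(runif(n_core))
  th1 <- runif(n_core, 0, 2 * pi)
  core <- cbind(r1 * cos(th1), r1 * sin(th1), runif(n_core, cb, top))
  k <- 6L                                            # vertical sub-columns
  colr <- runif(k, 0.35, 0.75) * rc
  colth <- runif(k, 0, 2 * pi)
  n_col <- round(0.25 * n)
  ci <- sample.int(k, n_col, replace = TRUE)
  cols <- cbind(colr[ci] * cos(colth[ci]) + stats::rnorm(n_col, 0, 0.30),
                colr[ci] * sin(colth[ci]) + stats::rnorm(n_col, 0, 0.30),
                runif(n_col, cb, top))
  n_out <- n - n_core - n_col
  r2 <- 0.85 * rc * sqrt(runif(n_out))
  th2 <- runif(n_out, 0, 2 * pi)
  outer <- cbind(r2 * cos(th2), r2 * sin(th2), runif(n_out, cb, top))
  rbind(core, cols, outer)
}

#' Simulate one ALS-like tree point cloud
#'
#' Samples tree height, crown length and crown radius uniformly within the
#' configured ranges, places crown points according to the archetype recipe,
#' thins them to the target areal density over the projected crown, adds
#' sparse stem returns below the crown and isotropic Gaussian positional
#' noise.  Deterministic for a fixed configuration and seed.
#'
#' @param config an [archetype_config()].
#' @param seed integer random seed.
#' @param tree_id identifier; defaults to `"<species>_<seed>"`.
#' @return a [tree_cloud()] with the configured species label.
#' @export
simulate_tree <- function(config, seed, tree_id = NULL) {
  stopifnot(inherits(config, "archetype_config"))
  if (is.null(tree_id)) tree_id <- sprintf("%s_%d", config$species, seed)
  set.seed(seed)

  ht <- runif(1, config$ht_range[1], config$ht_range[2])
  lc <- runif(1, config$lc_range[1], config$lc_range[2])
  lc <- min(lc, 0.95 * ht)
  rc <- runif(1, config$rc_range[1], config$rc_range[2])
  cb <- config$dtm_z + (ht - lc)
  top <- config$dtm_z + ht

  n_target <- round(config$density * pi * rc^2)
  if (n_target < 10L) {
    stop(sprintf("tree '%s': configured density yields fewer than 10 points",
                 tree_id))
  }
  n_raw <- 3L * n_target
  raw <- switch(config$archetype,
    massart_tiered = gen_massart(n_raw, cb, top, rc, config$tier_spacing,
                                 config$n_tiers),
    rauh_clustered = gen_rauh(n_raw, cb, top, rc, config$n_clusters),
    roux_layered = gen_roux(n_raw, cb, top, rc, config$n_branches),
    attim_columnar = gen_attim(n_raw, cb, top, rc),
    stop("unknown archetype '", config$archetype, "'")
  )
  crown <- raw[sample.int(n_raw, n_target), , drop = FALSE]  # density thinning

  n_stem <- round(config$stem_fraction * n_target)
  stem <- if (n_stem > 0 && cb - config$dtm_z > 1) {
    cbind(stats::rnorm(n_stem, 0, 0.10), stats::rnorm(n_stem, 0, 0.10),
          runif(n_stem, config$dtm_z + 0.3, cb))
  } else {
    matrix(numeric(0), ncol = 3)
  }

  pts <- rbind(crown, stem)
  pts <- pts + matrix(stats::rnorm(length(pts), 0, config$noise_sd),
                      ncol = 3)
  if (nrow(pts) < 10L) {
    stop(sprintf("tree '%s': configured density yields fewer than 10 points",
                 tree_id))
  }
  out <- tree_cloud(pts, dtm_z = config$dtm_z, tree_id = tree_id,
                    species = config$species)
  # generating parameters, for inspection and testing
  attr(out, "truth") <- list(ht = ht, lc = lc, rc = rc, crown_base_z = cb)
  out
}

#' Simulate a labeled stand of archetype trees
#'
#' Default composition is 9 PA + 14 PS + 7 PT + 10 QR = 40 trees, the
#' reference boreal sample this pipeline is dimensioned for.  Per-tree
#' seeds are drawn from the master seed, so the stand is reproducible as a
#' whole.  Optionally writes the clouds (XYZ text or LAS) plus a manifest
#' CSV compatible with [load_stand()].
#'
#' @param counts named integer vector of trees per species.
#' @param seed master random seed.
#' @param configs optional named list of [archetype_config()] overrides per
#'   species.
#' @param out_dir if non-NULL, write per-tree files and `manifest.csv` here.
#' @param format `"xyz"` or `"las"` (only used when writing).
#' @return list with `trees` (list of [tree_cloud()]) and `manifest`
#'   (data frame: tree_id, path, dtm_z, species; `path` is NA when not
#'   written).
#' @export
simulate_stand <- function(counts = c(PA = 9, PS = 14, PT = 7, QR = 10),
                           seed = 1, configs = NULL, out_dir = NULL,
                           format = c("xyz", "las")) {
  format <- match.arg(format)
  if (any(counts < 0)) stop("'counts' must be nonnegative")
  species <- rep(names(counts), times = counts)
  if (length(species) == 0L) stop("empty stand: all counts are zero")
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, length(species))

  ids <- unlist(lapply(names(counts), function(sp) {
    if (counts[[sp]] > 0) sprintf("%s_%02d", sp, seq_len(counts[[sp]])) else character(0)
  }))
  trees <- vector("list", length(species))
  for (i in seq_along(species)) {
    cfg <- if (!is.null(configs) && species[i] %in% names(configs)) {
      configs[[species[i]]]
    } else {
      archetype_config(species[i])
    }
    trees[[i]] <- simulate_tree(cfg, seed = tree_seeds[i], tree_id = ids[i])
  }
  names(trees) <- ids

  paths <- rep(NA_character_, length(trees))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "xyz") ".xyz" else ".las"
    for (i in seq_along(trees)) {
      paths[i] <- file.path(out_dir, paste0(ids[i], ext))
      if (format == "xyz") {
        utils::write.table(trees[[i]]$points, paths[i], row.names = FALSE,
                           col.names = FALSE)
      } else {
        write_las(trees[[i]]$points, paths[i])
      }
    }
  }
  manifest <- data.frame(tree_id = ids, path = paths,
                         dtm_z = vapply(trees, function(t) t$dtm_z, 0),
                         species = species, stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(trees = trees, manifest = manifest)
}
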