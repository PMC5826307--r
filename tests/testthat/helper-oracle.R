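# Independent brute-force reference implementations.  These deliberately
# share no code with the package internals: plain loops, naive enumeration
# and textbook formulas, used to pin the package's vectorized/compiled
# results.

# Delaunay by empty-circumsphere enumeration of all 4-subsets (valid for
# point sets in general position).
oracle_volumes <- function(pts, alpha) {
  n <- nrow(pts)
  hull <- 0
  av <- 0
  combs <- utils::combn(n, 4)
  for (j in seq_len(ncol(combs))) {
    id <- combs[, j]
    p <- pts[id, , drop = FALSE]
    m <- sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    rhs <- 0.5 * rowSums(m^2)
    if (abs(det(m)) < 1e-12) next
    u <- solve(m, rhs)
    ctr <- p[1, ] + u
    r2 <- sum(u^2)
    others <- setdiff(seq_len(n), id)
    d2 <- rowSums(sweep(pts[others, , drop = FALSE], 2, ctr)^2)
    if (any(d2 < r2 * (1 - 1e-9))) next
    v <- abs(det(m)) / 6
    hull <- hull + v
    if (sqrt(r2) <= alpha) av <- av + v
  }
  list(alpha = av, hull = hull)
}

# 2-D convex hull area by gift wrapping (Jarvis march) + shoelace
oracle_hull_area <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  if (n < 3) return(0)
  start <- which.min(xy[, 1] + 1e-12 * xy[, 2])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- 1L
    for (k in 2:n) {
      if (k == cur) next
      if (cand == cur) { cand <- k; next }
      cr <- (xy[cand, 1] - xy[cur, 1]) * (xy[k, 2] - xy[cur, 2]) -
            (xy[cand, 2] - xy[cur, 2]) * (xy[k, 1] - xy[cur, 1])
      d_cand <- sum((xy[cand, ] - xy[cur, ])^2)
      d_k <- sum((xy[k, ] - xy[cur, ])^2)
      if (cr < 0 || (abs(cr) < 1e-14 && d_k > d_cand)) cand <- k
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n) stop("jarvis march failed")
  }
  hx <- xy[hull, 1]
  hy <- xy[hull, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# population sd by definition
oracle_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

# Pearson correlation by definition, 0 for flat vectors
oracle_cor <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  va <- sum((a - ma)^2)
  vb <- sum((b - mb)^2)
  if (va <= 1e-24 || vb <= 1e-24) return(0)
  sum((a - ma) * (b - mb)) / sqrt(va * vb)
}

# all 13 crown-internal parameters by explicit loops over points and voxels
oracle_ci <- function(pts, crown_base_z, voxel_size = 0.5, V = 8L,
                      alpha = 0.5, supervoxel = 1) {
  crown <- pts[pts[, 3] >= crown_base_z, , drop = FALSE]
  top <- max(pts[, 3])
  Lc <- top - crown_base_z
  Rc <- max(sqrt(crown[, 1]^2 + crown[, 2]^2))
  A_base <- oracle_hull_area(crown[, 1:2])

  anchor <- c(min(crown[, 1]), min(crown[, 2]), min(crown[, 3]))
  keys <- list()
  for (i in seq_len(nrow(crown))) {
    idx <- floor((crown[i, ] - anchor) / voxel_size)
    keys[[paste(idx, collapse = "_")]] <- idx
  }
  vox <- do.call(rbind, keys)
  centers <- sweep(vox * voxel_size + voxel_size / 2, 2, anchor, "+")
  hts <- centers[, 3] - crown_base_z
  dst <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  az <- (atan2(centers[, 2], centers[, 1]) * 180 / pi) %% 360
  sec <- floor(az / 45) + 1
  lay <- pmin(pmax(floor(hts / (Lc / V)), 0), V - 1) + 1

  mh <- mr <- rep(NA_real_, 8)
  for (s in 1:8) {
    if (any(sec == s)) {
      mh[s] <- mean(hts[sec == s]) / Lc
      mr[s] <- mean(dst[sec == s]) / Rc
    }
  }
  ok <- !is.na(mh)
  P1 <- mean(mh[ok]); P2 <- mean(mr[ok])
  P5 <- oracle_sd(mh[ok]); P6 <- oracle_sd(mr[ok])

  low_pts <- crown[crown[, 3] <= crown_base_z + Lc / 3, , drop = FALSE]
  P3 <- if (nrow(low_pts) < 3) 0 else oracle_hull_area(low_pts[, 1:2]) / A_base

  skey <- character(0)
  for (i in seq_len(nrow(crown))) {
    idx <- floor((crown[i, ] - anchor) / supervoxel)
    skey <- c(skey, paste(idx, collapse = "_"))
  }
  P4 <- max(table(skey)) / nrow(crown)

  P7 <- sum(hts <= Lc / 3 & dst <= Rc / 2) / nrow(vox)
  P8 <- mean(hts) / Lc

  laycount <- sapply(1:V, function(l) sum(lay == l))
  P9 <- oracle_sd(laycount)
  P10 <- sum(abs(laycount[-1] - laycount[-V])) / nrow(vox)

  ov <- oracle_volumes(crown, alpha)
  P11 <- if (ov$hull > 0) ov$alpha / ov$hull else 0

  S <- matrix(0, 8, V)
  for (s in 1:8) for (l in 1:V) S[s, l] <- sum(sec == s & lay == l)
  opp <- 0; adj <- 0
  for (i in 1:4) opp <- opp + oracle_cor(S[i, ], S[i + 4, ])
  for (i in 1:8) adj <- adj + oracle_cor(S[i, ], S[(i %% 8) + 1, ])
  P12 <- if (abs(adj) <= 1e-12) 0 else opp / adj
  P13 <- if (P6 > 1e-9) P5 / P6 else 0

  c(P1 = P1, P2 = P2, P3 = P3, P4 = P4, P5 = P5, P6 = P6, P7 = P7, P8 = P8,
    P9 = P9, P10 = P10, P11 = P11, P12 = P12, P13 = P13)
}

# least-squares unit-amplitude Gaussian fit by multi-start quasi-Newton
oracle_gaussian_fit <- function(h, y) {
  y <- y / max(y)
  sse <- function(p) sum((y - exp(-(h - p[1])^2 / (2 * p[2]^2)))^2)
  u0 <- sum(h * y) / sum(y)
  a0 <- sqrt(sum(y * (h - u0)^2) / sum(y))
  best <- NULL
  for (fac in c(0.5, 1, 2)) {
    fit <- stats::optim(c(u0, a0 * fac), sse, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # Gauss-Newton polish to machine precision (analytic Jacobian)
  p <- best$par
  for (it in 1:100) {
    g <- exp(-(h - p[1])^2 / (2 * p[2]^2))
    r <- y - g
    J <- cbind(g * (h - p[1]) / p[2]^2, g * (h - p[1])^2 / p[2]^3)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    p_new <- p + as.vector(step)
    if (sse(p_new) <= sse(p)) p <- p_new else break
    if (max(abs(step)) < 1e-14) break
  }
  list(u = p[1], alpha = abs(p[2]))
}

# all 10 tree-external parameters by explicit loops (vertical axis at the
# origin, explicit crown base)
oracle_te <- function(pts, dtm_z, crown_base_z, voxel_size = 0.5,
                      grid_cell = 0.5, profile_bins = 40L) {
  crown <- pts[pts[, 3] >= crown_base_z, , drop = FALSE]
  top <- max(pts[, 3])
  Lc <- top - crown_base_z
  A_base <- oracle_hull_area(crown[, 1:2])

  Ht <- max(pts[, 3]) - dtm_z
  LcHt <- Lc / Ht
  D_EA <- 2 * sqrt(A_base / pi)
  LcD_EA <- Lc / D_EA

  edges <- seq(crown_base_z, top, length.out = profile_bins + 1)
  counts <- numeric(profile_bins)
  for (z in crown[, 3]) {
    b <- findInterval(z, edges, rightmost.closed = TRUE)
    b <- min(max(b, 1), profile_bins)
    counts[b] <- counts[b] + 1
  }
  mids <- (edges[-1] + edges[-(profile_bins + 1)]) / 2
  Alpha <- oracle_gaussian_fit(mids - crown_base_z, counts)$alpha

  sm <- numeric(profile_bins)
  for (i in seq_len(profile_bins)) {
    lo <- max(1, i - 1); hi <- min(profile_bins, i + 1)
    sm[i] <- mean(counts[lo:hi])
  }
  peaks <- integer(0)
  for (i in seq_len(profile_bins)) {
    left <- if (i > 1) sm[i] > sm[i - 1] else sm[i] > sm[2]
    right <- if (i < profile_bins) sm[i] > sm[i + 1] else sm[i] > sm[profile_bins - 1]
    if (left && right) peaks <- c(peaks, i)
  }
  llls <- if (length(peaks) <= 1) 1 else {
    (Ht - (mids[min(peaks)] - dtm_z)) / (Ht - (mids[max(peaks)] - dtm_z))
  }
  ls_lcs <- (mids[which.max(counts)] - crown_base_z) / Lc

  anchor <- c(min(crown[, 1]), min(crown[, 2]), min(crown[, 3]))
  keys <- new.env()
  for (i in seq_len(nrow(crown))) {
    idx <- floor((crown[i, ] - anchor) / voxel_size)
    assign(paste(idx, collapse = "_"), idx, envir = keys)
  }
  czs <- vapply(ls(keys), function(k) {
    get(k, envir = keys)[3] * voxel_size + voxel_size / 2 + anchor[3]
  }, 0)
  Gc <- mean(czs) - dtm_z

  cover <- function(u, v) {
    hull <- oracle_hull_area(cbind(u, v))
    if (hull <= 0) return(1)
    au <- min(u); av <- min(v)
    cells <- unique(paste(floor((u - au) / grid_cell),
                          floor((v - av) / grid_cell)))
    min(1, length(cells) * grid_cell^2 / hull)
  }
  P_L <- (cover(crown[, 1], crown[, 3]) + cover(crown[, 2], crown[, 3])) / 2
  LAI_proj <- cover(crown[, 1], crown[, 2])

  c(Ht = Ht, LcHt = LcHt, D_EA = D_EA, Alpha = Alpha, LcD_EA = LcD_EA,
    llls_lhls_proxy = llls, ls_lcs_proxy = ls_lcs, Gc = Gc, P_L = P_L,
    LAI_proj = LAI_proj)
}
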