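# Independent brute-force oracles used to cross-check the package's texture,
# ADC and ROC machinery. These deliberately use explicit loops / enumeration
# and share no code with the implementation.

oracle_offsets <- function(connectivity = 26L) {
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (connectivity == 6L && sum(abs(c(dx, dy, dz))) != 1) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  offs
}

# Half set (modulo sign): keep the first offset whose leading nonzero is +1.
oracle_half_offsets <- function() {
  Filter(function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  }, oracle_offsets(26L))
}

# GLCM by looping over every voxel and offset; counts ordered pairs, then
# symmetrizes, normalizes per direction and averages. `offsets` is a list of
# integer length-3 lags.
oracle_glcm <- function(lev, L, offsets = oracle_half_offsets()) {
  d <- dim(lev)
  acc <- matrix(0, L, L)
  used <- 0
  for (off in offsets) {
    cmat <- matrix(0, L, L)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (is.na(a)) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      b <- lev[x2, y2, z2]
      if (is.na(b)) next
      cmat[a, b] <- cmat[a, b] + 1
    }
    cmat <- cmat + t(cmat)
    if (sum(cmat) == 0) next
    acc <- acc + cmat / sum(cmat)
    used <- used + 1
  }
  if (used == 0) stop("oracle: no valid pair")
  acc / used
}

oracle_glcm_features <- function(p) {
  L <- nrow(p)
  en <- 0; ent <- 0; ctr <- 0; hom <- 0; mp <- 0; eij <- 0
  px <- numeric(L)
  for (i in 1:L) for (j in 1:L) px[i] <- px[i] + p[i, j]
  mu <- 0
  for (i in 1:L) mu <- mu + i * px[i]
  s2 <- 0
  for (i in 1:L) s2 <- s2 + (i - mu)^2 * px[i]
  vr <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    en <- en + pij^2
    if (pij > 0) ent <- ent - pij * log(pij)
    ctr <- ctr + (i - j)^2 * pij
    hom <- hom + pij / (1 + abs(i - j))
    vr <- vr + (i - mu)^2 * pij
    eij <- eij + i * j * pij
    if (pij > mp) mp <- pij
  }
  corr <- if (s2 == 0) NA_real_ else (eij - mu^2) / s2
  c(energy = en, entropy = ent, correlation = corr, contrast = ctr,
    homogeneity = hom, variance = vr, max_probability = mp)
}

# GLSZM by iterative flood fill over equal-level neighbours.
oracle_glszm <- function(lev, connectivity = 26L) {
  d <- dim(lev)
  offs <- oracle_offsets(connectivity)
  visited <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lev[x, y, z]) || visited[x, y, z]) next
    val <- lev[x, y, z]
    stack <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (off in offs) {
        w <- v + off
        if (any(w < 1) || any(w > d)) next
        if (visited[w[1], w[2], w[3]]) next
        lw <- lev[w[1], w[2], w[3]]
        if (is.na(lw) || lw != val) next
        visited[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(level = val, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(zone_tab) {
  nz <- nrow(zone_tab)
  iv <- 0
  for (m in unique(zone_tab[, "level"])) {
    iv <- iv + sum(zone_tab[, "level"] == m)^2
  }
  szv <- 0
  for (n in unique(zone_tab[, "size"])) {
    szv <- szv + sum(zone_tab[, "size"] == n)^2
  }
  c(intensity_variability = iv / nz, size_zone_variability = szv / nz)
}

# 1-D grid search for the log-domain least-squares decay rate, profiling out
# the intercept (for fixed D, ln S0 = mean(y + b D)). Two-stage scan reaching
# 1e-9 resolution on [lo, hi].
oracle_adc_grid <- function(signals, b, lo = 0, hi = 4e-3) {
  y <- log(signals)
  cy <- y - mean(y)
  cb <- b - mean(b)
  scan <- function(grid) {
    sse <- colSums((matrix(cy, length(y), length(grid)) + outer(cb, grid))^2)
    grid[which.min(sse)]
  }
  d1 <- scan(seq(lo, hi, by = 1e-6))
  scan(seq(max(lo, d1 - 2e-6), min(hi, d1 + 2e-6), by = 1e-9))
}

# Pair-counting AUC: P(case > control) + 0.5 P(tie), fixed orientation.
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (ca in cases) for (co in controls) {
    wins <- wins + (ca > co) + 0.5 * (ca == co)
  }
  wins / (length(cases) * length(controls))
}

# Exhaustive Youden scan mirroring the documented decision rules.
oracle_youden <- function(cases, controls, dir) {
  cand <- sort(unique(c(cases, controls)))
  best <- NULL
  for (t in cand) {
    if (dir == ">") {
      se <- mean(cases >= t); sp <- mean(controls < t)
    } else {
      se <- mean(cases <= t); sp <- mean(controls > t)
    }
    j <- se + sp - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sp > best$sp)) {
      best <- list(threshold = t, j = j, se = se, sp = sp)
    }
  }
  best
}

# Random small quantized ROI for oracle-equivalence sweeps.
random_quantized_roi <- function(max_dim = c(6, 6, 4), max_levels = 8) {
  repeat {
    d <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
           sample(1:max_dim[3], 1))
    L <- sample(2:max_levels, 1)
    lev <- array(sample(1:L, prod(d), replace = TRUE), d)
    drop <- stats::runif(prod(d)) < 0.3
    lev[drop] <- NA_integer_
    if (sum(!is.na(lev)) >= 5) break
  }
  structure(list(levels = lev, n_levels = as.integer(L), adc_range = c(0, 1),
                 voxel_spacing_mm = c(1, 1, 1)),
            class = "quantized_roi")
}

# 90-degree rotations of a 3D array about each axis.
rotate90 <- function(a, axis) {
  d <- dim(a)
  switch(axis,
         x = aperm(a[, , d[3]:1, drop = FALSE], c(1, 3, 2)),
         y = aperm(a[d[1]:1, , , drop = FALSE], c(3, 2, 1)),
         z = aperm(a[, d[2]:1, , drop = FALSE], c(2, 1, 3)))
}

make_quantized <- function(lev, L) {
  structure(list(levels = lev, n_levels = as.integer(L), adc_range = c(0, 1),
                 voxel_spacing_mm = c(1, 1, 1)),
            class = "quantized_roi")
}

# Count clearly separated density modes: local maxima of a kernel density
# estimate rising above 5% of the global peak.
count_modes <- function(x) {
  d <- stats::density(x)
  y <- d$y
  n <- length(y)
  peaks <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  sum(y[peaks] > 0.05 * max(y))
}
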