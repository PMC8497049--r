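# Brute-force geometric oracles: exhaustive per-voxel checks, written as
# plain distance-matrix computations independent of the package's
# running-minimum mask construction.

# world coordinates of every voxel center of a grid, as an n x 3 matrix
bf_voxel_centers <- function(grid) {
  d <- dim(grid$values)
  sp <- grid$spacing; or <- grid$origin
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  sweep(sweep(idx - 1, 2, sp, `*`), 2, or, `+`)
}

# dense resampling of a centerline at <= step mm (same definition as the
# package documents: even arc-length samples including both endpoints)
bf_resample <- function(cl, step = 0.25) {
  total <- max(cl$arclen)
  s <- seq(0, total, length.out = max(2, ceiling(total / step) + 1))
  pts <- sapply(1:3, function(ax) approx(cl$arclen, cl$points[, ax],
                                         xout = s)$y)
  list(points = pts, arclen = s)
}

# exhaustive tube membership: for every voxel, the full distance matrix
# to all centerline samples, min + first argmin
bf_tube_mask <- function(grid, cl, section, step = 0.25) {
  rs <- bf_resample(cl, step)
  ctr <- bf_voxel_centers(grid)
  n <- nrow(ctr)
  inside <- logical(n)
  chunk <- 2000L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    dmat <- outer(ctr[rows, 1], rs$points[, 1], `-`)^2 +
      outer(ctr[rows, 2], rs$points[, 2], `-`)^2 +
      outer(ctr[rows, 3], rs$points[, 3], `-`)^2
    jmin <- apply(dmat, 1, which.min)
    dmin <- sqrt(dmat[cbind(seq_along(rows), jmin)])
    smin <- rs$arclen[jmin]
    inside[rows] <- dmin <= section$voi_radius &
      smin >= section$a & smin < section$b
  }
  array(inside, dim = dim(grid$values))
}

bf_sphere_mask <- function(grid, center, volume = 2) {
  r <- (3 * volume * 1000 / (4 * pi))^(1 / 3)
  ctr <- bf_voxel_centers(grid)
  d <- sqrt(rowSums(sweep(ctr, 2, center)^2))
  array(d <= r, dim = dim(grid$values))
}

# random smooth polyline inside a grid's inner region, for oracle tests
random_centerline <- function(grid, n_ctrl = 5) {
  d <- dim(grid$values)
  ext <- (d - 1) * grid$spacing
  lo <- grid$origin + 0.25 * ext
  hi <- grid$origin + 0.75 * ext
  ctrl <- sapply(1:3, function(ax) sort(runif(n_ctrl, lo[ax], hi[ax])))
  # interpolate control points into a gently curved polyline
  t0 <- seq(0, 1, length.out = n_ctrl)
  t1 <- seq(0, 1, length.out = 25)
  pts <- sapply(1:3, function(ax) spline(t0, ctrl[, ax], xout = t1)$y)
  centerline(pts)
}

# brute-force 3-slice-window search used against most_diseased_segment
bf_best_window <- function(v, width = 3) {
  means <- sapply(seq_len(length(v) - width + 1),
                  function(i) mean(v[i:(i + width - 1)]))
  list(start = which(means == max(means))[1], value = max(means))
}

# agreement statistics recomputed from first principles
bf_bland_altman <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(mean_error = m, loa = c(m - 1.96 * s, m + 1.96 * s),
       cr = 1.96 * s, cr_pct = 100 * 1.96 * s / (sum(a + b) / (2 * n)))
}

# ICC(2,1) through R's ANOVA machinery as the independent route
bf_icc_aov <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}
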