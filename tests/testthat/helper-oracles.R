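# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: root-finding on the parametric circle instead of the
# quadratic formula, grid search instead of normal equations, explicit
# binomial-coefficient enumeration instead of dhyper summation.

# intersections of a line and a circle by sign changes of the signed
# point-to-line distance along the parametric circle, refined by uniroot
sweep_line_circle <- function(l, circ, n_grid = 4096) {
  d <- c(cos(l$direction * pi / 180), sin(l$direction * pi / 180))
  f <- function(theta) {
    p <- cbind(circ$center[1] + circ$radius * cos(theta),
               circ$center[2] + circ$radius * sin(theta))
    d[1] * (p[, 2] - l$anchor[2]) - d[2] * (p[, 1] - l$anchor[1])
  }
  th <- seq(0, 2 * pi, length.out = n_grid + 1)
  v <- f(th)
  roots <- numeric(0)
  for (i in seq_len(n_grid)) {
    if (v[i] == 0) roots <- c(roots, th[i])
    else if (v[i] * v[i + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(th[i], th[i + 1]),
                                       tol = 1e-14)$root)
  }
  pts <- lapply(roots, function(t)
    circ$center + circ$radius * c(cos(t), sin(t)))
  # drop duplicates from a root sitting exactly on a grid node
  if (length(pts) > 1) {
    keep <- rep(TRUE, length(pts))
    for (i in seq_along(pts)[-1])
      for (j in seq_len(i - 1))
        if (keep[j] && sqrt(sum((pts[[i]] - pts[[j]])^2)) < 1e-8 * circ$radius)
          keep[i] <- FALSE
    pts <- pts[keep]
  }
  pts
}

# two-stage grid search for the least-squares concurrency point
grid_ls_point <- function(lines, lo, hi, coarse = 0.05, fine = 1e-3) {
  eval_grid <- function(xs, ys) {
    total <- matrix(0, length(xs), length(ys))
    for (l in lines) {
      d <- c(cos(l$direction * pi / 180), sin(l$direction * pi / 180))
      dist <- outer(xs - l$anchor[1], ys - l$anchor[2],
                    function(px, py) d[1] * py - d[2] * px)
      total <- total + dist^2
    }
    total
  }
  xs <- seq(lo[1], hi[1], by = coarse); ys <- seq(lo[2], hi[2], by = coarse)
  g <- eval_grid(xs, ys)
  ij <- arrayInd(which.min(g), dim(g))
  cx <- xs[ij[1]]; cy <- ys[ij[2]]
  xs <- seq(cx - 2 * coarse, cx + 2 * coarse, by = fine)
  ys <- seq(cy - 2 * coarse, cy + 2 * coarse, by = fine)
  g <- eval_grid(xs, ys)
  ij <- arrayInd(which.min(g), dim(g))
  c(xs[ij[1]], ys[ij[2]])
}

# grid minimizer of summed squared angular deviation (mod 180)
grid_mean_direction <- function(angles, step = 1e-4) {
  cand <- seq(0, 180 - step, by = step)
  dev <- vapply(cand, function(t) {
    d <- abs(t - angles) %% 180
    sum(pmin(d, 180 - d)^2)
  }, numeric(1))
  cand[which.min(dev)]
}

# ICC(3,k) by explicit sums over cells (written from the ANOVA identities,
# not shared with the implementation)
hand_icc3k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  mu <- sum(m) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(m[i, ]) - mu)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - mu)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + mu)^2
  msb <- ssb / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msb - mse) / msb
}

# Fisher two-sided p by explicit enumeration with binomial coefficients
fisher_enum_p <- function(tab, rel_tol = 1e-7) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- vapply(support, function(x)
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1), numeric(1))
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# random well-conditioned line/circle pair for property tests
random_line <- function() {
  line2d(stats::runif(2, -50, 50), stats::runif(1, 0, 180))
}
random_circle <- function() {
  circle2d(stats::runif(2, -50, 50), stats::runif(1, 0.5, 60))
}

# landmark set fixture with bilateral pairs, written in code
bilateral_fixture <- function() {
  tpl <- make_ideal_template()
  go <- tpl$points$Go
  tpl$points$Go <- NULL
  tpl$side_pairs <- list(Go = list(L = go + c(-2, -2), R = go + c(2, 2)))
  tpl
}
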