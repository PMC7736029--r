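# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# --- steam-table reference points for saturation pressure (Pa), IAPWS
# values at the printed precision of standard tables
steam_table <- data.frame(
  temp_c = c(0.01, 10, 20, 25, 40, 60, 80, 100),
  psat_pa = c(611.7, 1228.1, 2339.3, 3169.9, 7384.9,
              19946, 47390, 101420))

# --- dip oracle: per-mode bisection with feasibility decided by a
# quadratic program over the unimodal-CDF tube constraints (quadprog),
# exact for any n but used at small n for speed
dip_side_feasible_qp <- function(xs, bu, bl, d) {
  t <- length(xs)
  if (t == 0) return(TRUE)
  up <- pmin(bu + d, 1)
  lo <- pmax(bl - d, 0)
  if (t == 1) return(lo[1] <= up[1] + 1e-12)
  a_mat <- rbind(diag(t), -diag(t))
  b_vec <- c(lo, -up)
  s1 <- rep(0, t); s1[1] <- -1; s1[2] <- 1
  a_mat <- rbind(a_mat, s1 / (xs[2] - xs[1]))
  b_vec <- c(b_vec, 0)
  if (t >= 3) {
    for (i in 2:(t - 1)) {
      r <- rep(0, t)
      r[i - 1] <- 1 / (xs[i] - xs[i - 1])
      r[i] <- -1 / (xs[i] - xs[i - 1]) - 1 / (xs[i + 1] - xs[i])
      r[i + 1] <- 1 / (xs[i + 1] - xs[i])
      a_mat <- rbind(a_mat, r)
      b_vec <- c(b_vec, 0)
    }
  }
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(t), dvec = rep(0, t),
                       Amat = t(a_mat), bvec = b_vec),
    error = function(e) NULL)
  !is.null(res)
}

dip_oracle <- function(x) {
  x <- sort(x); n <- length(x)
  v <- unique(x); cnt <- tabulate(match(x, v)); cum <- cumsum(cnt)
  k <- length(v)
  bu <- c(0, cum[-k]) / n
  bl <- cum / n
  mode_min_d <- function(m) {
    lf <- function(d) dip_side_feasible_qp(v[seq_len(m - 1)],
                                           bu[seq_len(m - 1)],
                                           bl[seq_len(m - 1)], d)
    rf <- function(d) {
      if (m + 1 > k) return(TRUE)
      idx <- k:(m + 1)
      dip_side_feasible_qp(-v[idx], 1 - bl[idx], 1 - bu[idx], d)
    }
    lo <- 0; hi <- 1
    for (it in 1:42) {
      mid <- (lo + hi) / 2
      if (lf(mid) && rf(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  min(vapply(seq_len(k), mode_min_d, 0))
}

# --- brute-force convex hull volume for tiny general-position clouds:
# enumerate supporting facets, sum tetrahedra against the centroid
brute_hull_volume <- function(pts) {
  n <- nrow(pts); ctr <- colMeans(pts); vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c3 <- pts[k, ]
    nn <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
            (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
            (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    d <- sweep(pts, 2, a) %*% nn
    if (all(d <= 1e-12) || all(d >= -1e-12)) {
      va <- a - ctr; vb <- b - ctr; vc <- c3 - ctr
      vol <- vol + abs(va[1] * (vb[2] * vc[3] - vb[3] * vc[2]) -
                       va[2] * (vb[1] * vc[3] - vb[3] * vc[1]) +
                       va[3] * (vb[1] * vc[2] - vb[2] * vc[1])) / 6
    }
  }
  vol
}

# --- numerical-quadrature oblate spheroid area (surface of revolution
# about the polar axis): a_eq, c_pol are SEMI-axes
spheroid_area_quadrature <- function(a_eq, c_pol) {
  f <- function(z) {
    r <- a_eq * sqrt(pmax(1 - z^2 / c_pol^2, 0))
    drdz <- -a_eq * z / (c_pol^2 * sqrt(pmax(1 - z^2 / c_pol^2, 1e-300)))
    2 * pi * r * sqrt(1 + drdz^2)
  }
  stats::integrate(f, -c_pol * (1 - 1e-10), c_pol * (1 - 1e-10),
                   rel.tol = 1e-10)$value
}

# --- digitized shapes
rasterize_ball <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ax <- seq_len(n) - (r + pad + 1L)
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  array(d2 <= r^2, dim = c(n, n, n))
}

rasterize_disk_mask <- function(r, pad = 5L) {
  n <- 2L * (r + pad) + 1L
  ax <- seq_len(n) - (r + pad + 1L)
  outer(ax^2, ax^2, "+") <= r^2
}

# axis-aligned or rotated ellipse mask (semi-axes a, b, angle radians)
rasterize_ellipse_mask <- function(a, b, angle = 0, pad = 5L) {
  m <- ceiling(max(a, b)) + pad
  n <- 2L * m + 1L
  ax <- seq_len(n) - (m + 1L)
  xx <- matrix(ax, n, n, byrow = TRUE)
  yy <- matrix(ax, n, n)
  xr <- xx * cos(angle) + yy * sin(angle)
  yr <- -xx * sin(angle) + yy * cos(angle)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# analytic lognormal-mixture quantile by root finding on the CDF
lognormal_mixture_quantile <- function(p, medians, gsds, fracs) {
  cdf <- function(x) sum(fracs * stats::pnorm(log(x), log(medians),
                                              log(gsds)))
  stats::uniroot(function(x) cdf(x) - p,
                 interval = c(min(medians) / 1e3, max(medians) * 1e3),
                 tol = 1e-12)$root
}
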