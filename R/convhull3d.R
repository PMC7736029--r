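# Minimal 3D quickhull. Only what the morphology descriptors need:
# exact facets of the convex hull of a point cloud, the polytope
# volume, and a lattice-point count inside the hull.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Facets of the convex hull (quickhull). Returns a list with `facets`
# (integer matrix, one CCW-outward vertex triple per row), `points`,
# and `interior` (a strictly interior point).
.quickhull_facets <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (ncol(pts) != 3 || n < 4)
    stop("need at least 4 points in 3 dimensions")
  scale <- max(apply(pts, 2, function(x) diff(range(x))), 1)
  eps <- tol * scale

  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (max(abs(pts[i1, ] - pts[i2, ])) < eps) stop("degenerate point set")
  d12 <- pts[i2, ] - pts[i1, ]
  v <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(v[, 2] * d12[3] - v[, 3] * d12[2],
              v[, 3] * d12[1] - v[, 1] * d12[3],
              v[, 1] * d12[2] - v[, 2] * d12[1])
  dline <- sqrt(rowSums(cr^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps * sqrt(sum(d12^2))) stop("collinear point set")
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- as.numeric(v %*% nrm)
  i4 <- which.max(abs(dplane))
  if (abs(dplane[i4]) < eps * sqrt(sum(nrm^2)))
    stop("coplanar point set: hull is degenerate")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(tri) {
    nn <- .cross3(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
    if (sum(nn * (interior - pts[tri[1], ])) > 0) tri[c(1, 3, 2)] else tri
  }
  facet_norm <- function(tri)
    list(n = .cross3(pts[tri[2], ] - pts[tri[1], ],
                     pts[tri[3], ] - pts[tri[1], ]),
         a = pts[tri[1], ])
  above <- function(fn, idx) {
    if (!length(idx)) return(numeric(0))
    as.numeric(sweep(pts[idx, , drop = FALSE], 2, fn$a) %*% fn$n)
  }

  facets <- list(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                 orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))
  norms <- lapply(facets, facet_norm)
  live <- rep(TRUE, 4)
  outside <- vector("list", 4)
  cand <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (f in 1:4) {
    if (!length(cand)) { outside[[f]] <- integer(0); next }
    d <- above(norms[[f]], cand)
    sel <- cand[d > eps * sqrt(sum(norms[[f]]$n^2))]
    outside[[f]] <- sel
    cand <- setdiff(cand, sel)
  }

  repeat {
    fidx <- which(live & lengths(outside) > 0)
    if (!length(fidx)) break
    f <- fidx[1]
    d <- above(norms[[f]], outside[[f]])
    p <- outside[[f]][which.max(d)]
    vis <- logical(length(facets))
    for (g in which(live)) {
      dn <- sum(norms[[g]]$n * (pts[p, ] - norms[[g]]$a))
      if (dn > eps * sqrt(sum(norms[[g]]$n^2))) vis[g] <- TRUE
    }
    ecount <- new.env(parent = emptyenv())
    for (g in which(vis)) {
      tri <- facets[[g]]
      for (e in list(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])) {
        k <- paste(sort(e), collapse = "-")
        ecount[[k]] <- if (is.null(ecount[[k]])) list(e)
                       else c(ecount[[k]], list(e))
      }
    }
    horizon <- list()
    for (k in ls(ecount))
      if (length(ecount[[k]]) == 1) horizon <- c(horizon, ecount[[k]])
    pool <- unique(unlist(outside[vis]))
    pool <- pool[pool != p]
    for (g in which(vis)) { live[g] <- FALSE; outside[[g]] <- integer(0) }
    for (e in horizon) {
      tri <- orient(c(e[1], e[2], p))
      facets[[length(facets) + 1]] <- tri
      norms[[length(facets)]] <- facet_norm(tri)
      live[length(facets)] <- TRUE
      if (length(pool)) {
        d2 <- above(norms[[length(facets)]], pool)
        sel <- pool[d2 > eps * sqrt(sum(norms[[length(facets)]]$n^2))]
        outside[[length(facets)]] <- sel
        pool <- setdiff(pool, sel)
      } else outside[[length(facets)]] <- integer(0)
    }
  }

  list(facets = do.call(rbind, facets[live]), points = pts,
       interior = interior)
}

#' Volume of the convex hull of a 3D point cloud
#'
#' Exact polytope volume via quickhull facets and signed tetrahedra
#' against an interior point.
#'
#' @param pts Numeric matrix with three columns (x, y, z).
#' @return Hull volume in the cube of the point units.
#' @export
convex_hull_volume <- function(pts) {
  h <- .quickhull_facets(pts)
  vol <- 0
  for (g in seq_len(nrow(h$facets))) {
    tri <- h$facets[g, ]
    a <- h$points[tri[1], ] - h$interior
    b <- h$points[tri[2], ] - h$interior
    c3 <- h$points[tri[3], ] - h$interior
    vol <- vol + abs(a[1] * (b[2] * c3[3] - b[3] * c3[2]) -
                     a[2] * (b[1] * c3[3] - b[3] * c3[1]) +
                     a[3] * (b[1] * c3[2] - b[2] * c3[1])) / 6
  }
  unname(vol)
}

# Count integer lattice points inside the hull of `pts` (used to
# measure the hull volume in the same voxel-counting convention as the
# ROI volume, so convexity stays <= 1 by construction).
.hull_lattice_count <- function(pts, tol = 1e-7) {
  h <- .quickhull_facets(pts)
  facets <- h$facets
  p <- h$points
  nf <- nrow(facets)
  nn <- t(vapply(seq_len(nf), function(g)
    .cross3(p[facets[g, 2], ] - p[facets[g, 1], ],
            p[facets[g, 3], ] - p[facets[g, 1], ]), numeric(3)))
  offs <- rowSums(nn * p[facets[, 1], ])
  nrm <- sqrt(rowSums(nn^2))
  nn <- nn / nrm; offs <- offs / nrm

  xs <- seq(ceiling(min(p[, 1])), floor(max(p[, 1])))
  ys <- seq(ceiling(min(p[, 2])), floor(max(p[, 2])))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  zlo <- rep(-Inf, length(gx)); zhi <- rep(Inf, length(gx))
  feasible <- rep(TRUE, length(gx))
  for (g in seq_len(nf)) {
    a <- nn[g, 1]; b <- nn[g, 2]; c3 <- nn[g, 3]; d <- offs[g]
    if (abs(c3) < 1e-12) {
      feasible <- feasible & (a * gx + b * gy <= d + tol)
    } else {
      z <- (d - a * gx - b * gy) / c3
      if (c3 > 0) zhi <- pmin(zhi, z) else zlo <- pmax(zlo, z)
    }
  }
  lo <- ceiling(zlo - tol); hi <- floor(zhi + tol)
  cnt <- hi - lo + 1
  sum(pmax(cnt[feasible & is.finite(cnt)], 0))
}
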