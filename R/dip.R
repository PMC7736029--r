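# Hartigan dip statistic: the smallest sup-norm distance between the
# empirical CDF and any unimodal CDF.
#
# Computation: condition on the mode location. A unimodal CDF is convex
# left of the mode and concave right of it (an atom at the mode is
# allowed), so the two sides decouple. For the left side, a convex
# nondecreasing CDF branch staying within the d-tube around the ECDF
# exists iff the lower convex hull of the tube's upper bounds dominates
# the lower bounds at every data point; since the whole tube shifts
# linearly with d, the minimal feasible d per side has a closed form:
# half the largest deficit between the ECDF lower corners and that
# hull. The right side is the mirror image. The minimal left-side d is
# nondecreasing in the mode position and the right-side d is
# nonincreasing, so the best mode is found at their crossing.

# groups of tied values: x values, cumulative counts
.dip_groups <- function(x) {
  x <- sort(as.numeric(x))
  v <- unique(x)
  cnt <- tabulate(match(x, v))
  list(v = v, cum = cumsum(cnt), n = length(x))
}

# Minimal d so that a convex CDF branch rising from zero fits the tube
# over the first `t` groups. `xs` are group positions, `bu` the tube
# upper-bound bases (left ECDF corners, (c_{s-1})/n) and `bl` the
# lower-bound bases (right corners, c_s/n); bounds at distance d are
# bu + d and bl - d.
.side_min_d <- function(xs, bu, bl, t) {
  if (t == 0L) return(0)
  if (t == 1L) return(max(0, (bl[1] - bu[1]) / 2))
  xs <- xs[seq_len(t)]; bu <- bu[seq_len(t)]; bl <- bl[seq_len(t)]
  hull <- .lower_hull_values(xs, bu)
  d <- max(0, max(bl - hull) / 2)
  if (bu[t] + d <= 1 + 1e-12) return(d)
  # rare: the G <= 1 cap binds; bisect with capped upper bounds
  feasible <- function(dd) {
    hv <- .lower_hull_values(xs, pmin(bu + dd, 1))
    all(hv >= bl - dd - 1e-15)
  }
  lo <- d; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

# lower convex hull of (x, y), evaluated at every x (monotone chain)
.lower_hull_values <- function(x, y) {
  t <- length(x)
  stack <- integer(t)
  top <- 0L
  for (i in seq_len(t)) {
    while (top >= 2L) {
      a <- stack[top - 1L]; b <- stack[top]
      # pop b if it lies on or above segment a-i
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
        top <- top - 1L
      else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  hv <- numeric(t)
  for (k in seq_len(top - 1L)) {
    a <- stack[k]; b <- stack[k + 1L]
    seg <- a:b
    hv[seg] <- y[a] + (y[b] - y[a]) * (x[seg] - x[a]) / (x[b] - x[a])
  }
  hv[stack[top]] <- y[stack[top]]
  hv
}

#' Hartigan dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and the closest unimodal CDF. It is scale and shift
#' invariant, at least `1/(2n)` for samples with at least two distinct
#' values, and large values indicate multimodality.
#'
#' @param x Numeric sample, `n >= 2`, finite, with at least two
#'   distinct values.
#' @return The dip statistic (dimensionless).
#' @export
dip_statistic <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (any(!is.finite(x))) stop("sample must be finite")
  g <- .dip_groups(x)
  k <- length(g$v)
  if (k < 2) stop("all values identical: dip is undefined")
  n <- g$n
  bu <- c(0, g$cum[-k]) / n   # left ECDF corners
  bl <- g$cum / n             # right ECDF corners
  left <- function(t) .side_min_d(g$v, bu, bl, t)
  right <- function(t) {
    # mirror: suffix groups t..k, reflected and complemented
    if (t > k) return(0)
    idx <- k:t
    .side_min_d(-g$v[idx], 1 - bl[idx], 1 - bu[idx], length(idx))
  }
  phi <- function(m) max(left(m - 1L), right(m + 1L))
  if (k <= 64L) return(min(vapply(1:k, phi, 0)))
  # left() is nondecreasing and right() nonincreasing in the mode
  # position, so phi is quasiconvex: binary-search the crossing
  lo <- 1L; hi <- k
  while (hi - lo > 2L) {
    mid <- (lo + hi) %/% 2L
    if (left(mid - 1L) >= right(mid + 1L)) hi <- mid else lo <- mid
  }
  min(vapply(max(1L, lo - 1L):min(k, hi + 1L), phi, 0))
}

#' Null distribution of the dip under uniform sampling
#'
#' Bootstrap calibration sample of dip statistics for samples of size
#' `n` drawn from the uniform distribution (the canonical unimodal null
#' of the dip test). Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param n Sample size.
#' @param reps Number of bootstrap replicates (>= 200).
#' @param seed Integer seed.
#' @return Numeric vector of `reps` dip values, sorted.
#' @export
dip_null_distribution <- function(n, reps = 2000, seed = 1) {
  if (reps < 200) stop("use at least 200 bootstrap replicates")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  sort(vapply(seq_len(reps), function(i) dip_statistic(stats::runif(n)), 0))
}

#' Bootstrap probability of unimodality (dip test)
#'
#' Compares the sample's dip statistic against `bootstrap_reps` uniform
#' null samples of the same size: the reported probability is the
#' fraction of null dips at least as large as the observed one. High
#' values are consistent with a unimodal sample; low values indicate
#' multimodality.
#'
#' @param x Numeric sample.
#' @param bootstrap_reps Number of null replicates (>= 200).
#' @param seed Integer seed (results are reproducible bit for bit).
#' @return An object of class `dip_result`: list with `dip_statistic`,
#'   `unimodality_probability`, `n`, `bootstrap_reps`, `seed`.
#' @export
unimodality_probability <- function(x, bootstrap_reps = 2000, seed = 1) {
  d <- dip_statistic(x)
  null <- dip_null_distribution(length(x), bootstrap_reps, seed)
  p <- mean(null >= d)
  structure(list(dip_statistic = d, unimodality_probability = p,
                 n = length(x), bootstrap_reps = bootstrap_reps,
                 seed = seed),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip test: dip = %.4f (n = %d), P(unimodal) = %.3f (%d bootstrap reps)\n",
              x$dip_statistic, x$n, x$unimodality_probability,
              x$bootstrap_reps))
  invisible(x)
}
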