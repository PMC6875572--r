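# Layman community-wide metrics and standard ellipse machinery on
# delta13C-delta15N point sets

as_point_matrix <- function(ps) {
  x <- if (is.list(ps) && !is.null(ps$points)) ps$points else ps
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("point set must have two columns (x, y)", call. = FALSE)
  if (!all(is.finite(x))) stop("point set contains non-finite coordinates", call. = FALSE)
  x
}

#' Layman community-wide metrics
#'
#' Six descriptors of a delta13C-delta15N point cloud: CR (delta13C range,
#' basal-resource diversification), NR (delta15N range, trophic length),
#' CD (mean Euclidean distance to the centroid, trophic diversity), MNND
#' (mean nearest-neighbour distance, density of taxa packing; low values
#' signal trophic redundancy), SDNND (its standard deviation, packing
#' evenness) and TA (convex hull total area, permil^2).
#'
#' @param ps a two-column matrix/data.frame of points, or a list with a
#'   `points` element.
#' @param sdnnd `"sample"` (n-1 denominator, default) or `"population"`.
#' @return list of class `layman_metrics` with fields `CR`, `NR`, `CD`,
#'   `MNND`, `SDNND`, `TA`, `n` and `degenerate_hull` (TRUE when fewer than
#'   three distinct non-collinear points; `TA` is then `NA`).
#' @export
layman_metrics <- function(ps, sdnnd = c("sample", "population")) {
  sdnnd <- match.arg(sdnnd)
  x <- as_point_matrix(ps)
  n <- nrow(x)
  if (n < 2L)
    stop("layman_metrics needs at least 2 points, got ", n, call. = FALSE)
  centroid <- colMeans(x)
  cd <- mean(sqrt((x[, 1] - centroid[1])^2 + (x[, 2] - centroid[2])^2))
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  nnd <- apply(dm, 1L, min)
  sd_nnd <- if (sdnnd == "sample") stats::sd(nnd) else
    sqrt(mean((nnd - mean(nnd))^2))
  ta <- hull_area(x)
  structure(list(
    CR = diff(range(x[, 1])), NR = diff(range(x[, 2])),
    CD = cd, MNND = mean(nnd), SDNND = sd_nnd,
    TA = if (is.na(ta)) NA_real_ else ta,
    n = n, degenerate_hull = is.na(ta)
  ), class = "layman_metrics")
}

# convex hull area by the shoelace formula; NA when the hull is degenerate
hull_area <- function(x) {
  ux <- unique(x)
  if (nrow(ux) < 3L) return(NA_real_)
  h <- grDevices::chull(ux)
  if (length(h) < 3L) return(NA_real_)
  v <- ux[h, , drop = FALSE]
  i2 <- c(2:nrow(v), 1L)
  a <- abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
  if (a <= .Machine$double.eps * max(abs(ux))^2 * nrow(ux)) NA_real_ else a
}

#' Standard ellipse area (SEA) and its small-sample correction (SEA_C)
#'
#' The standard ellipse of a bivariate point cloud is the 1-SD contour of
#' the fitted bivariate normal; its area is `pi * sqrt(det(S))` for sample
#' covariance `S` (equivalently `pi * sqrt(lambda1 * lambda2)`). SEA_C
#' rescales by `(n - 1) / (n - 2)` to reduce small-sample bias.
#'
#' @param ps point set as in [layman_metrics()]; needs `n >= 3`.
#' @return `sea()`: area in permil^2 (0 with attribute `degenerate = TRUE`
#'   when the covariance is singular); `sea_c()`: the corrected area.
#' @export
sea <- function(ps) {
  x <- as_point_matrix(ps)
  if (nrow(x) < 3L)
    stop("sea needs at least 3 points, got ", nrow(x), call. = FALSE)
  d <- det(stats::cov(x))
  if (d <= 0) return(structure(0, degenerate = TRUE))
  pi * sqrt(d)
}

#' @rdname sea
#' @export
sea_c <- function(ps) {
  x <- as_point_matrix(ps)
  n <- nrow(x)
  s <- sea(x)
  out <- as.numeric(s) * (n - 1) / (n - 2)
  if (isTRUE(attr(s, "degenerate"))) attr(out, "degenerate") <- TRUE
  out
}

#' Bayesian standard ellipse area (SEA_B)
#'
#' Posterior of the standard ellipse area under a bivariate-normal model
#' with the Jeffreys reference prior `p(mu, Sigma) ~ |Sigma|^-(3/2)`. The
#' posterior of `Sigma` is inverse-Wishart with `n - 1` degrees of freedom
#' and scale equal to the centred sum of squares, and is sampled by direct
#' Monte Carlo (one independent draw per retained iteration; the configured
#' burn-in and thinning are applied to the raw draw stream so run lengths
#' match MCMC-based workflows). Each draw yields
#' `SEA_B = pi * sqrt(det(Sigma))`.
#'
#' @param ps point set, `n >= 3` (and `n >= 4` for a proper posterior).
#' @param cfg an [iso_config()]; `cfg$mcmc` fixes draw counts, `cfg$seed`
#'   (xor `seed`) the RNG.
#' @param seed optional seed overriding `cfg$seed`.
#' @return list of class `ellipse_posterior`: `sea_b_draws`, point
#'   estimates `mode` (histogram-peak) and `median`, central credible
#'   intervals `ci` (50/75/95%), posterior mean vector `mu`, posterior mean
#'   covariance `sigma`, and `n`.
#' @export
sea_b <- function(ps, cfg = iso_config(), seed = NULL) {
  x <- as_point_matrix(ps)
  n <- nrow(x)
  if (n < 3L) stop("sea_b needs at least 3 points, got ", n, call. = FALSE)
  set.seed(if (is.null(seed)) cfg$seed else seed)
  m <- cfg$mcmc
  keep <- seq.int(m$burn + 1L, m$iterations, by = m$thin)
  n_draw <- length(keep)
  xbar <- colMeans(x)
  ss <- crossprod(sweep(x, 2, xbar))        # centred sum of squares
  nu <- n - 1
  # draw Sigma ~ InvWishart(nu, ss): invert Wishart(nu, ss^-1) draws
  w <- stats::rWishart(m$iterations, df = nu, Sigma = solve(ss))
  w <- w[, , keep, drop = FALSE]
  dets <- w[1, 1, ] * w[2, 2, ] - w[1, 2, ] * w[2, 1, ]
  if (any(!is.finite(dets)) || any(dets <= 0))
    stop("sampler fault: non-positive-definite draw (n = ", n, ")", call. = FALSE)
  sea_draws <- pi / sqrt(dets)              # det(Sigma) = 1/det(W)
  sigma_mean <- ss / (nu - 3)               # posterior mean, needs n >= 5
  structure(list(
    sea_b_draws = sea_draws,
    mode = histogram_mode(sea_draws),
    median = stats::median(sea_draws),
    mean = mean(sea_draws),
    ci = list(
      `50` = stats::quantile(sea_draws, c(0.25, 0.75), names = FALSE),
      `75` = stats::quantile(sea_draws, c(0.125, 0.875), names = FALSE),
      `95` = stats::quantile(sea_draws, c(0.025, 0.975), names = FALSE)
    ),
    mu = xbar,
    sigma = if (nu > 3) sigma_mean else ss / nu,
    n = n, n_draws = n_draw
  ), class = "ellipse_posterior")
}

# kernel-free histogram-peak point estimate (midpoint of the modal bin,
# Freedman-Diaconis widths)
histogram_mode <- function(x) {
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Area and proportion of overlap between two standard ellipses
#'
#' Intersection area of two ellipses `(p - mu)' Sigma^-1 (p - mu) <= c`
#' computed by grid integration over the intersection of their bounding
#' boxes; the proportion is Jaccard-style,
#' `overlap / (area_a + area_b - overlap)`.
#'
#' @param mu_a,sigma_a,mu_b,sigma_b ellipse centres (length-2) and 2x2
#'   positive-definite covariances.
#' @param scale quadratic-form level `c`; 1 is the standard (1-SD) ellipse.
#'   Use `stats::qchisq(p, 2)` for a p-level ellipse.
#' @param grid_n grid resolution per axis.
#' @return list with `overlap` (permil^2), `proportion`, `area_a`, `area_b`.
#' @export
ellipse_overlap <- function(mu_a, sigma_a, mu_b, sigma_b, scale = 1,
                            grid_n = 401L) {
  check_pd <- function(s, nm) {
    e <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (any(e <= 0)) stop(nm, " covariance is not positive-definite", call. = FALSE)
  }
  check_pd(sigma_a, "first"); check_pd(sigma_b, "second")
  area_a <- pi * scale * sqrt(det(sigma_a))
  area_b <- pi * scale * sqrt(det(sigma_b))
  bbox <- function(mu, s) {
    half <- sqrt(diag(s) * scale)
    rbind(mu - half, mu + half)
  }
  ba <- bbox(mu_a, sigma_a); bb <- bbox(mu_b, sigma_b)
  lo <- pmax(ba[1, ], bb[1, ]); hi <- pmin(ba[2, ], bb[2, ])
  if (any(hi <= lo))
    return(list(overlap = 0, proportion = 0, area_a = area_a, area_b = area_b))
  gx <- seq(lo[1], hi[1], length.out = grid_n)
  gy <- seq(lo[2], hi[2], length.out = grid_n)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  pts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  inside <- function(mu, s) {
    d <- sweep(pts, 2, mu)
    si <- solve(s)
    q <- si[1, 1] * d[, 1]^2 + 2 * si[1, 2] * d[, 1] * d[, 2] + si[2, 2] * d[, 2]^2
    q <= scale
  }
  overlap <- sum(inside(mu_a, sigma_a) & inside(mu_b, sigma_b)) * cell
  list(overlap = overlap,
       proportion = overlap / (area_a + area_b - overlap),
       area_a = area_a, area_b = area_b)
}
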