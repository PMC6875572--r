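# shared fixtures and independent brute-force oracles

rand_points <- function(n, seed = NULL, scale = 3) {
  if (!is.null(seed)) set.seed(seed)
  cbind(rnorm(n, 0, scale), rnorm(n, 0, scale))
}

# O(n^2) nearest-neighbour / centroid oracle, independent of the package path
layman_oracle <- function(x) {
  n <- nrow(x)
  cen <- c(mean(x[, 1]), mean(x[, 2]))
  cd <- mean(sapply(seq_len(n), function(i)
    sqrt((x[i, 1] - cen[1])^2 + (x[i, 2] - cen[2])^2)))
  nnd <- sapply(seq_len(n), function(i) {
    min(sapply(setdiff(seq_len(n), i), function(j)
      sqrt((x[i, 1] - x[j, 1])^2 + (x[i, 2] - x[j, 2])^2)))
  })
  list(CR = max(x[, 1]) - min(x[, 1]), NR = max(x[, 2]) - min(x[, 2]),
       CD = cd, MNND = mean(nnd), SDNND = sd(nnd),
       TA = hull_area_oracle(x))
}

# gift-wrapping (Jarvis march) hull + shoelace, independent of grDevices::chull
hull_area_oracle <- function(x) {
  ux <- unique(x)
  n <- nrow(ux)
  if (n < 3L) return(NA_real_)
  start <- which.min(ux[, 1] + 1e-9 * ux[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    nxt <- cand[1]
    for (q in cand[-1]) {
      cr <- (ux[nxt, 1] - ux[p, 1]) * (ux[q, 2] - ux[p, 2]) -
        (ux[nxt, 2] - ux[p, 2]) * (ux[q, 1] - ux[p, 1])
      d_nxt <- sum((ux[nxt, ] - ux[p, ])^2)
      d_q <- sum((ux[q, ] - ux[p, ])^2)
      if (cr < 0 || (cr == 0 && d_q > d_nxt)) nxt <- q
    }
    if (nxt == start) break
    if (length(hull) > n) break
    hull <- c(hull, nxt)
  }
  if (length(hull) < 3L) return(NA_real_)
  v <- ux[hull, , drop = FALSE]
  i2 <- c(2:nrow(v), 1L)
  a <- abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
  if (a < 1e-12) NA_real_ else a
}

# random snapshot pair with controllable taxon sharing
rand_snapshot_pair <- function(max_taxa = 10L) {
  pool <- paste0("t", 1:(max_taxa + 4L))
  n1 <- sample(1:max_taxa, 1); n2 <- sample(1:max_taxa, 1)
  g1 <- sample(pool, n1); g2 <- sample(pool, n2)
  mk <- function(g) {
    q <- runif(length(g)); q <- q / sum(q)
    community_snapshot(g, q, rnorm(length(g), 2, 1))
  }
  list(c1 = mk(g1), c2 = mk(g2))
}

# covariance with unit determinant and some correlation
unit_det_sigma <- function(rho = 0.5) {
  s <- matrix(c(2, rho, rho, 1), 2, 2)
  s / sqrt(det(s))
}

rmvn2 <- function(n, mu, sigma) {
  l <- chol(sigma)
  matrix(rnorm(2 * n), n, 2) %*% l + matrix(mu, n, 2, byrow = TRUE)
}

quick_cfg <- function(seed = 1L, draws = 900L) {
  iso_config(seed = seed, iterations = 3L * draws + 300L, burn = 300L,
             thin = 3L, chains = 2L)
}
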