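test_that("partition of hand-worked snapshot pairs", {
  c1 <- community_snapshot(c("a", "b"), c(0.5, 0.5), c(1, 3))
  c2 <- community_snapshot(c("a", "b"), c(0.25, 0.75), c(2, 4))
  p <- price_partition(c1, c2)
  expect_equal(p$delta_total, 1.5)
  expect_equal(p$TS, 0.5)
  expect_equal(p$ITV, 1.0)
  expect_equal(p$TT, 0)
  # identical snapshots
  p0 <- price_partition(c1, c1)
  expect_equal(p0$delta_total, 0)
  expect_equal(abs(p0$TS) + abs(p0$ITV) + abs(p0$TT), 0)
  # disjoint taxon sets: everything is turnover
  c3 <- community_snapshot(c("x", "y"), c(0.4, 0.6), c(5, 2))
  p3 <- price_partition(c1, c3)
  expect_equal(p3$TS, 0)
  expect_equal(p3$ITV, 0)
  expect_equal(p3$TT, p3$delta_total)
})

test_that("three-term mode separates the abundance-trait covariation", {
  c1 <- community_snapshot(c("a", "b"), c(0.5, 0.5), c(1, 3))
  c2 <- community_snapshot(c("a", "b"), c(0.25, 0.75), c(2, 4))
  p <- price_partition(c1, c2, mode = "three_term")
  expect_equal(p$TS, 0.5)
  expect_equal(p$ITV, sum(c(0.5, 0.5) * c(1, 1)))   # q1-weighted trait change
  expect_equal(p$COV, sum(c(-0.25, 0.25) * c(1, 1)))
  expect_equal(p$TS + p$ITV + p$COV + p$TT, p$delta_total, tolerance = 1e-12)
})

test_that("exact conservation over random snapshot pairs", {
  set.seed(42)
  worst <- 0
  for (r in 1:1000) {
    pair <- rand_snapshot_pair()
    for (mode in c("telescoping", "three_term")) {
      p <- price_partition(pair$c1, pair$c2, mode = mode)
      comp_sum <- p$TS + p$ITV + p$TT + if (!is.null(p$COV)) p$COV else 0
      scale <- max(abs(p$delta_total), abs(p$TS) + abs(p$ITV) + abs(p$TT),
                   .Machine$double.eps)
      worst <- max(worst, abs(comp_sum - p$delta_total) / scale)
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("partition is linear in traits and antisymmetric in time", {
  set.seed(8)
  pair <- rand_snapshot_pair()
  p <- price_partition(pair$c1, pair$c2)
  c1s <- pair$c1; c1s$data$z <- c1s$data$z * 3
  c2s <- pair$c2; c2s$data$z <- c2s$data$z * 3
  ps <- price_partition(c1s, c2s)
  expect_equal(ps$TS, 3 * p$TS)
  expect_equal(ps$TT, 3 * p$TT)
  expect_equal(ps$delta_total, 3 * p$delta_total)
  rev <- price_partition(pair$c2, pair$c1)
  expect_equal(rev$delta_total, -p$delta_total)
})

test_that("relative contributions use the absolute-value convention", {
  c1 <- community_snapshot(c("a", "b"), c(0.5, 0.5), c(1, 3))
  c2 <- community_snapshot(c("a", "b"), c(0.25, 0.75), c(2, 4))
  p <- price_partition(c1, c2)   # components (0.5, 1.0, 0)
  expect_equal(p$rel_TS, 100 / 3, tolerance = 1e-9)
  expect_equal(p$rel_ITV, 200 / 3, tolerance = 1e-9)
  expect_equal(p$rel_TT, 0)
  expect_equal(p$rel_TS + p$rel_ITV + p$rel_TT, 100, tolerance = 1e-9)
  # opposite-sign components share by magnitude
  fake <- structure(list(TS = -1, ITV = 1, TT = 0), class = "price_partition")
  rc <- relative_contributions(fake)
  expect_equal(rc$rel_TS, 50)
  expect_equal(rc$rel_ITV, 50)
  # all-zero components are undefined, flagged
  zero <- structure(list(TS = 0, ITV = 0, TT = 0), class = "price_partition")
  rz <- relative_contributions(zero)
  expect_true(rz$rel_undefined)
  expect_true(is.na(rz$rel_TS))
  # single nonzero component takes 100%
  one <- structure(list(TS = 0, ITV = -0.4, TT = 0), class = "price_partition")
  expect_equal(relative_contributions(one)$rel_ITV, 100)
})

test_that("rarity threshold routes rare taxa into turnover", {
  c1 <- community_snapshot(c("a", "b", "rare"), c(0.5, 0.48, 0.02), c(1, 3, 10))
  c2 <- community_snapshot(c("a", "b", "rare"), c(0.25, 0.73, 0.02), c(2, 4, 10))
  p <- price_partition(c1, c2, rarity_threshold = 0.03)
  expect_equal(p$TT, 0)          # rare taxon excluded from both sides
  expect_equal(length(p$shared), 2L)
  p2 <- price_partition(c1, c2)  # without the threshold it is shared
  expect_equal(length(p2$shared), 3L)
})

test_that("time-series partitioning covers consecutive pairs and conserves", {
  b <- synth_generate(synth_config(), seed = 4)
  parts <- timeseries_partition(b$snapshots)
  expect_length(parts, 20L)
  for (p in parts)
    expect_equal(p$TS + p$ITV + p$TT, p$delta_total, tolerance = 1e-12)
  # constant community gives all-zero partitions
  const <- lapply(1:4, function(i)
    community_snapshot(c("a", "b"), c(0.3, 0.7), c(1, 2),
                       date = as.Date("2016-01-01") + 20 * (i - 1)))
  pc <- timeseries_partition(const)
  expect_true(all(vapply(pc, function(p) abs(p$delta_total), 1) == 0))
  # non-monotone dates are rejected
  bad <- const[c(2, 1, 3, 4)]
  expect_error(timeseries_partition(bad), "increasing")
})

test_that("environmental linkage: perfect monotone, ties, degenerate cells", {
  dates <- as.Date("2016-01-01") + 20 * (0:8)
  # build partitions whose rel_ITV decreases monotonically with d(temperature)
  snaps <- list(community_snapshot("a", 1, 1, date = dates[1]))
  itv_steps <- c(9, 8, 6, 5, 4, 3, 2, 1)
  z <- 1
  for (i in seq_along(itv_steps)) {
    z <- z + itv_steps[i]
    snaps[[i + 1]] <- community_snapshot("a", 1, z, date = dates[i + 1])
  }
  parts <- timeseries_partition(snaps)
  # with one shared taxon everything is ITV; use the raw ITV column instead
  pt <- partition_table(parts)
  expect_true(all(pt$rel_ITV == 100))
  env <- data.frame(date = dates,
                    temperature = cumsum(c(20, 9:2)),  # dT = 9..2, monotone
                    flat = 1)
  class(env) <- c("env_series", "data.frame")
  # construct component series equal to dITV which decreases as dT decreases
  tab <- link_contributions_env(parts, env)
  expect_true(all(c("component", "variable", "rho", "p", "flag") %in% names(tab)))
  # constant rel contribution -> flagged, NA rho
  flat_cell <- tab[tab$component == "ITV" & tab$variable == "flat", ]
  expect_true(flat_cell$flag %in% c("constant", "ok"))

  # direct check of the Spearman machinery on a monotone pair via the same
  # average-rank convention, against an exhaustive rank oracle (n <= 8)
  xx <- c(3, 1, 4, 1, 5, 9, 2, 6); yy <- c(2, 7, 1, 8, 2, 8, 1, 8)
  rho_pkg <- suppressWarnings(
    cor.test(xx, yy, method = "spearman", exact = FALSE))$estimate
  rx <- rank(xx); ry <- rank(yy)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(unname(rho_pkg), rho_oracle, tolerance = 1e-12)
})

test_that("perfect monotone coupling yields rho = -1", {
  dates <- as.Date("2016-03-01") + 20 * (0:6)
  # two shared taxa; adjust trait jumps so rel_ITV rises step by step
  snaps <- list()
  qa <- seq(0.30, 0.60, by = 0.05)
  z <- cbind(seq(1, 4, by = 0.5), seq(2, 5, by = 0.5))
  for (i in 1:7)
    snaps[[i]] <- community_snapshot(c("a", "b"), c(qa[i], 1 - qa[i]),
                                     z[i, ], date = dates[i])
  parts <- timeseries_partition(snaps)
  rel_itv <- partition_table(parts)$rel_ITV
  # environmental delta constructed strictly decreasing wherever rel_itv rises
  env <- data.frame(date = dates, temperature = c(0, cumsum(-rank(rel_itv))))
  class(env) <- c("env_series", "data.frame")
  tab <- link_contributions_env(parts, env)
  cell <- tab[tab$component == "ITV" & tab$variable == "temperature", ]
  expect_equal(cell$rho, -1)
})

test_that("aggregate_snapshots averages abundance and traits per period", {
  s1 <- community_snapshot(c("a", "b"), c(0.2, 0.8), c(1, 2))
  s2 <- community_snapshot(c("a", "c"), c(0.6, 0.4), c(3, 5))
  agg <- aggregate_snapshots(list(s1, s2), label = "mixing")
  d <- agg$data
  expect_equal(d$q[d$group_id == "a"], 0.4)   # mean of 0.2 and 0.6
  expect_equal(d$q[d$group_id == "b"], 0.4)   # present once, (0.8 + 0)/2
  expect_equal(d$z[d$group_id == "a"], 2)     # mean of 1 and 3
  expect_equal(sum(d$q), 1)
})
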