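test_that("generation is a pure function of (config, seed)", {
  a <- synth_generate(synth_config(), seed = 12)
  b <- synth_generate(synth_config(), seed = 12)
  expect_identical(a$consumers, b$consumers)
  expect_identical(a$env, b$env)
  expect_identical(a$ground_truth$q_real, b$ground_truth$q_real)
  c2 <- synth_generate(synth_config(), seed = 13)
  expect_false(identical(a$consumers$d13C, c2$consumers$d13C))
})

test_that("bundle satisfies basic structural invariants", {
  b <- synth_generate(synth_config(), seed = 2)
  expect_length(b$snapshots, 21L)
  # all abundance rows sum to one
  for (s in b$snapshots) expect_equal(sum(s$data$q), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(b$ground_truth$diet) - 1) < 1e-9))
  # temperature means per period near the configured targets
  tm <- tapply(b$env$temperature, b$env$period, mean)
  expect_equal(unname(tm["mixing"]), 18.97, tolerance = 0.02)
  expect_equal(unname(tm["stratification"]), 27.11, tolerance = 0.02)
  # both periods present, dates strictly increasing
  expect_setequal(unique(b$env$period), c("mixing", "stratification"))
  expect_true(all(diff(b$env$date) > 0))
})

test_that("generator output passes every reader's schema check", {
  b <- synth_generate(synth_config(), seed = 3)
  dir <- withr::local_tempdir()
  paths <- synth_write(b, dir)
  cons <- read_isotope_table(paths["consumers"])
  expect_equal(nrow(cons), nrow(b$consumers))
  expect_equal(attr(cons, "skipped"), 0L)
  src <- read_source_table(paths["sources"])
  expect_equal(src$mean_d13C, b$sources$mean_d13C)
  snaps <- read_snapshot_table(paths["snapshots"])
  expect_length(snaps, 21L)
  expect_equal(snaps[[1]]$data$q, b$snapshots[[1]]$data$q)
  env <- read_env_table(paths["env"])
  expect_equal(env$temperature, b$env$temperature)
})

test_that("community-weighted mean body size drops from mixing to stratification", {
  b <- synth_generate(synth_config(), seed = 5)
  cwm <- vapply(b$snapshots, community_weighted_mean, numeric(1))
  per <- vapply(b$snapshots, function(s) s$period, character(1))
  expect_lt(mean(cwm[per == "stratification"]), mean(cwm[per == "mixing"]))
})

test_that("noise-free configuration reproduces the ground-truth partitions exactly", {
  cfg <- synth_config(temp_noise_sd = 0, q_noise_sd = 0, dw_noise_sd = 0)
  b <- synth_generate(cfg, seed = 7)
  got <- timeseries_partition(b$snapshots)
  exp <- expected_partitions(b$ground_truth)
  expect_length(got, length(exp))
  for (i in seq_along(got)) {
    expect_equal(got[[i]]$delta_total, exp[[i]]$delta_total, tolerance = 1e-12)
    expect_equal(got[[i]]$TS, exp[[i]]$TS, tolerance = 1e-12)
    expect_equal(got[[i]]$ITV, exp[[i]]$ITV, tolerance = 1e-12)
    expect_equal(got[[i]]$TT, exp[[i]]$TT, tolerance = 1e-12)
  }
})

test_that("flat slopes and abundances give near-zero partition components", {
  cfg <- synth_config(dw_slope = rep(0, 6), ab_slope = rep(0, 6),
                      q_noise_sd = 0.01, dw_noise_sd = 0.01,
                      presence_threshold = 0)
  b <- synth_generate(cfg, seed = 9)
  parts <- timeseries_partition(b$snapshots)
  comps <- unlist(lapply(parts, function(p) c(p$TS, p$ITV, p$TT)))
  expect_lt(max(abs(comps)), 0.1)
})

test_that("noisy partitions track the ground-truth oracle within noise bounds", {
  b <- synth_generate(synth_config(), seed = 21)
  got <- partition_table(timeseries_partition(b$snapshots))
  exp <- partition_table(expected_partitions(b$ground_truth))
  # per-step totals correlate strongly with the noise-free oracle
  expect_gt(cor(got$delta_total, exp$delta_total), 0.6)
})

test_that("a synthetic date's consumers are recovered by the mixing model", {
  # surface POM fractions only: the three are well-separated in isotope
  # space, so the community diet is identifiable from 50 replicates
  surf <- default_sources()[1:3, ]
  cfg <- synth_config(sources = surf,
                      diet_mixing = c(0.40, 0.32, 0.28),
                      diet_strat = c(0.78, 0.13, 0.09))
  b <- synth_generate(cfg, seed = 31)
  gt <- b$ground_truth
  # the warmest date: diet concentrated on surface pico-POM
  d <- which.max(gt$temp_true)
  p_true <- gt$diet[d, ]
  tef <- cfg$tef
  set.seed(101)
  mu <- colSums(p_true * cbind(surf$mean_d13C, surf$mean_d15N)) +
    c(tef$mean_d13C, tef$mean_d15N)
  v <- colSums(p_true^2 * cbind(surf$sd_d13C^2 + tef$sd_d13C^2,
                                surf$sd_d15N^2 + tef$sd_d15N^2))
  consumers <- cbind(rnorm(50, mu[1], sqrt(v[1])), rnorm(50, mu[2], sqrt(v[2])))
  fit <- fit_mixing_model(consumers, surf, tef,
                          iso_config(seed = 4, iterations = 4000, burn = 1000,
                                     thin = 3),
                          screened = TRUE)
  expect_lt(mean(abs(fit$summary$mean - p_true)), 0.10)
  # the dominant source is identified
  expect_equal(fit$summary$source_id[which.max(fit$summary$mean)],
               names(which.max(p_true)))
})

test_that("per-period community niche breadth is larger when mixed", {
  b <- synth_generate(synth_config(), seed = 41)
  mix <- b$consumers[b$consumers$period == "mixing", c("d13C", "d15N")]
  str <- b$consumers[b$consumers$period == "stratification", c("d13C", "d15N")]
  post_m <- sea_b(mix, quick_cfg(seed = 1))
  post_s <- sea_b(str, quick_cfg(seed = 1))
  expect_gt(post_m$mode, post_s$mode)
})

test_that("config validation rejects broken simplexes and tiny series", {
  expect_error(synth_config(diet_mixing = c(0.5, 0.5, 0, 0, 0, 0.1)), "simplex")
  expect_error(synth_config(n_dates = 3), "n_dates")
  expect_error(synth_config(dw_base = 1:3), "per taxon")
})
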