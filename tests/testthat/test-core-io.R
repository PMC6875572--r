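test_that("isotope table round-trips and skips incomplete rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   group_id = c("Bosmina", "Bosmina", "Diaptomidae"),
                   date = c("2016-01-01", "2016-01-01", "2016-01-21"),
                   d13C = c(-28.1, -27.9, -26.5),
                   d15N = c(8.2, 7.9, 9.1),
                   c_percent = c(45, 44, 46), n_percent = c(10, 10, 10.5),
                   cn_ratio = c(4.5, 4.4, 4.38))
  write.csv(df, f, row.names = FALSE)
  got <- read_isotope_table(f)
  expect_equal(nrow(got), 3L)
  expect_equal(attr(got, "skipped"), 0L)
  expect_s3_class(got, "isotope_samples")
  expect_equal(got$d13C, df$d13C)
  expect_s3_class(got$date, "Date")

  # a row with d13C = NA is skipped, not fatal
  df$d13C[2] <- NA
  write.csv(df, f, row.names = FALSE)
  got <- read_isotope_table(f)
  expect_equal(nrow(got), 2L)
  expect_equal(attr(got, "skipped"), 1L)

  # missing required column is a schema error naming the column
  write.csv(df[setdiff(names(df), "d15N")], f, row.names = FALSE)
  expect_error(read_isotope_table(f), "d15N")

  # unparseable date is a row-level error
  df2 <- df; df2$date[3] <- "not-a-date"
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_isotope_table(f), "date")
})

test_that("schema mapping renames file columns to internal names", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ID = "a", taxon = "Bosmina", sampled = "2016-03-01",
                       delC = -27, delN = 8), f, row.names = FALSE)
  got <- read_isotope_table(f, schema = c(sample_id = "ID", group_id = "taxon",
                                          date = "sampled", d13C = "delC",
                                          d15N = "delN"))
  expect_equal(got$d13C, -27)
  expect_error(read_isotope_table(f, schema = c(d13C = "absent_col")),
               "absent_col")
})

test_that("config defaults, validation and seed materialisation", {
  cfg <- load_config(NULL)
  expect_equal(cfg$mcmc$iterations, 20000L)
  expect_equal(cfg$mcmc$burn, 2000L)
  expect_equal(cfg$mcmc$thin, 20L)
  expect_true(is.integer(cfg$seed))
  expect_equal(cfg$thresholds$source_cutoff, 0.12)
  expect_equal(cfg$thresholds$polygon_cutoff, 0.05)

  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("seed: 7\nmcmc:\n  iterations: 5000\n  burn: 500", f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$mcmc$iterations, 5000L)
  expect_equal(cfg2$mcmc$thin, 20L)  # untouched keys keep defaults

  writeLines("mcmc:\n  iterations: 20000\n  burn: 25000", f)
  expect_error(load_config(f), "burn")
  expect_error(iso_config(thin = 0), "thinning")
})

test_that("identical seeds give identical downstream stochastic output", {
  x <- rand_points(30, seed = 5)
  a <- sea_b(x, quick_cfg(seed = 7))
  b <- sea_b(x, quick_cfg(seed = 7))
  expect_identical(a$sea_b_draws, b$sea_b_draws)
  src <- default_sources()
  xin <- sweep(rand_points(30, seed = 5), 2, c(-28, 8), "+")
  p1 <- simulate_mixing_polygon(src, trophic_enrichment(), xin, seed = 7)
  p2 <- simulate_mixing_polygon(src, trophic_enrichment(), xin, seed = 7)
  expect_identical(p1$p, p2$p)
})

test_that("result writers round-trip JSON and CSV", {
  dir <- withr::local_tempdir()
  p <- price_partition(community_snapshot(c("a", "b"), c(.5, .5), c(1, 3)),
                       community_snapshot(c("a", "b"), c(.25, .75), c(2, 4)))
  jf <- file.path(dir, "part.json")
  write_results(p, jf)
  back <- read_results(jf)
  expect_s3_class(back, "price_partition")
  expect_equal(back$delta_total, p$delta_total)
  expect_equal(back$TS, p$TS)
  expect_equal(back$ITV, p$ITV)

  # flat table of metrics for two groups -> CSV with two rows
  m1 <- layman_metrics(rand_points(8, seed = 1))
  m2 <- layman_metrics(rand_points(8, seed = 2))
  tab <- rbind(data.frame(label = "g1", m1[c("CR", "NR", "CD", "MNND", "SDNND", "TA")]),
               data.frame(label = "g2", m2[c("CR", "NR", "CD", "MNND", "SDNND", "TA")]))
  cf <- file.path(dir, "metrics.csv")
  write_results(tab, cf)
  back2 <- read_results(cf)
  expect_equal(nrow(back2), 2L)
  expect_equal(back2$CR, tab$CR)

  # ragged case: group with too few points gets null metrics and a flag
  ragged <- rbind(tab,
                  data.frame(label = "g3", CR = NA, NR = NA, CD = NA,
                             MNND = NA, SDNND = NA, TA = NA))
  ragged$insufficient <- c(FALSE, FALSE, TRUE)
  write_results(ragged, cf)
  back3 <- read_results(cf)
  expect_equal(nrow(back3), 3L)
  expect_true(back3$insufficient[3])
  expect_true(is.na(back3$CR[3]))

  expect_error(write_results(tab, file.path(dir, "nope", "x.csv")), "directory")
})

test_that("snapshot and source constructors enforce invariants", {
  expect_error(community_snapshot(c("a", "b"), c(0.6, 0.6), c(1, 2)), "sum to 1")
  expect_error(community_snapshot(c("a", "b"), c(0.5, 0.5), c(1, NA)), "missing trait")
  expect_error(community_snapshot(c("a", "b"), c(-0.1, 1.1), c(1, 2)), "non-negative")
  expect_error(source_summary("s", -30, -1, 5, 0.5), "non-negative")
  # zero-abundance taxon may carry NA trait
  s <- community_snapshot(c("a", "b"), c(1, 0), c(2, NA))
  expect_equal(community_weighted_mean(s), 2)
})
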