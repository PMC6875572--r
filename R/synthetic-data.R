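# synthetic monomictic-reservoir dataset generator with ground truth

#' Configuration for the synthetic reservoir generator
#'
#' Defaults emulate a year-round zooplankton sampling campaign in a
#' monomictic subtropical reservoir: 21 sampling dates on a 20-day cadence,
#' a cool fully-mixed period and a warm stratified period with mean surface
#' temperatures of 18.97 and 27.11 degC, six taxon groups whose body size
#' responds to temperature with taxon-specific sign (negative for
#' *Bosmina*, *Bosminopsis*, other Cladocera and large Cyclopidae, positive
#' for small Cyclopidae, flat for Diaptomidae), three POM size-fraction
#' food sources in two layers, a diet that concentrates on surface pico-POM
#' when stratified, abundances that shift toward small taxa as temperature
#' rises (so taxa sorting dominates body-size change) and within-group
#' isotopic dispersion that shrinks with temperature (so intrataxonomic
#' variation dominates niche-breadth change and the mixed-period niche is
#' the broader one).
#'
#' @param n_dates number of sampling dates (>= 4).
#' @param start_date first sampling date (ISO-8601).
#' @param cadence_days days between sampling dates.
#' @param temp_mixing,temp_strat period mean surface temperatures, degC.
#' @param temp_within_sd within-period SD of the smooth seasonal component.
#' @param temp_noise_sd measurement noise SD on temperature, degC.
#' @param taxa character vector of taxon group names.
#' @param dw_base per-taxon baseline dry weight, ug/ind.
#' @param dw_slope per-taxon body-size response to temperature, ug/ind per
#'   degC.
#' @param dw_noise_sd body-size noise SD, ug/ind.
#' @param ab_base,ab_slope per-taxon log-abundance baseline and temperature
#'   slope feeding a softmax; positive slopes favour a taxon when warm.
#' @param q_noise_sd log-abundance noise SD.
#' @param presence_threshold relative abundance below which a taxon is
#'   treated as absent on a date (routes rare taxa into turnover).
#' @param sources a `source_summary` of candidate food sources.
#' @param diet_mixing,diet_strat simplex diet-proportion targets for the
#'   two periods (named after the sources, in order).
#' @param tef a [trophic_enrichment()].
#' @param sd13_base,sd15_base within-group isotopic SD at the mean
#'   temperature, permil.
#' @param group_sd_scale per-taxon multiplier on those SDs.
#' @param group_off13,group_off15 per-taxon isotope offsets, permil.
#' @param disp_slope per-degC log-rate at which within-group dispersion
#'   shrinks as temperature rises.
#' @param n_reps consumer replicates per taxon per date.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(
    n_dates = 21L,
    start_date = "2015-11-01",
    cadence_days = 20L,
    temp_mixing = 18.97, temp_strat = 27.11,
    temp_within_sd = 2.0, temp_noise_sd = 0.3,
    taxa = default_taxa(),
    dw_base = c(0.9, 0.6, 1.6, 1.2, 3.4, 2.4),
    dw_slope = c(-0.020, -0.018, -0.045, 0.030, -0.090, 0.0),
    dw_noise_sd = 0.05,
    ab_base = c(0.6, 0.2, 0.2, 0.3, 0.4, 0.2),
    ab_slope = c(0.10, 0.08, -0.06, 0.12, -0.14, -0.05),
    q_noise_sd = 0.15,
    presence_threshold = 0.02,
    sources = default_sources(),
    diet_mixing = c(0.17, 0.17, 0.13, 0.16, 0.16, 0.21),
    diet_strat = c(0.73, 0.08, 0.04, 0.07, 0.05, 0.03),
    tef = trophic_enrichment(),
    sd13_base = 1.0, sd15_base = 0.9,
    group_sd_scale = c(0.85, 0.90, 1.05, 0.90, 1.15, 1.00),
    group_off13 = c(-0.3, -0.2, 0.0, 0.2, 0.4, 0.3),
    group_off15 = c(0.0, 0.1, 0.3, 0.8, 1.3, 1.0),
    disp_slope = 0.08,
    n_reps = 3L) {
  cfg <- as.list(environment())
  if (n_dates < 4L) stop("n_dates must be >= 4", call. = FALSE)
  nt <- length(taxa)
  for (nm in c("dw_base", "dw_slope", "ab_base", "ab_slope",
               "group_sd_scale", "group_off13", "group_off15"))
    if (length(cfg[[nm]]) != nt)
      stop(nm, " must have one entry per taxon", call. = FALSE)
  for (nm in c("diet_mixing", "diet_strat")) {
    p <- cfg[[nm]]
    if (length(p) != nrow(sources) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(nm, " must be a simplex vector over the ", nrow(sources),
           " sources", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Default synthetic food-source signatures
#'
#' Three POM size fractions (pico 0.2-3 um, nano 3-20 um, micro 20-200 um)
#' in surface and bottom layers, with delta13C increasing and delta15N
#' increasing along the size gradient and bottom layers depleted relative
#' to surface. Values are field-typical for subtropical reservoir seston.
#'
#' @return a `source_summary` of six sources.
#' @export
default_sources <- function() {
  source_summary(
    source_id = c("picoPOM_surface", "nanoPOM_surface", "microPOM_surface",
                  "picoPOM_bottom", "nanoPOM_bottom", "microPOM_bottom"),
    mean_d13C = c(-30.5, -28.0, -25.2, -32.2, -29.6, -26.8),
    sd_d13C = c(0.7, 0.8, 0.9, 0.7, 0.8, 0.9),
    mean_d15N = c(3.2, 4.6, 6.2, 2.1, 3.6, 5.1),
    sd_d15N = c(0.6, 0.7, 0.8, 0.6, 0.7, 0.8),
    n = 3L)
}

#' Generate a synthetic reservoir dataset bundle
#'
#' Produces the four tables the analysis pipeline consumes plus the ground
#' truth that generated them. Temperature follows a smooth seasonal
#' trajectory rescaled within each period to hit the configured period
#' means; period labels are calendar-based (May-October = stratification).
#' The date-specific diet interpolates log-linearly between the two period
#' targets as temperature moves from the mixing to the stratified mean.
#' Consumer isotope replicates are drawn around the enrichment-corrected
#' diet mixture with taxon offsets and temperature-shrinking dispersion;
#' body size is `baseline + slope * (T - Tbar) + noise`; relative
#' abundances are a noisy softmax of temperature-dependent affinities with
#' taxa under the presence threshold dropped and renormalised.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed; the same (config, seed) pair regenerates the same
#'   bundle.
#' @return list of class `synth_bundle`: `consumers` (isotope samples),
#'   `sources` (`source_summary`), `snapshots` (list of
#'   [community_snapshot()] carrying dry weight as the trait),
#'   `snapshot_table`, `env` (`env_series`) and `ground_truth` (generating
#'   parameters plus realized noise-free trajectories and per-date truths).
#' @export
synth_generate <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  nd <- config$n_dates
  dates <- as.Date(config$start_date) + config$cadence_days * (0:(nd - 1L))
  month <- as.integer(format(dates, "%m"))
  period <- ifelse(month >= 5L & month <= 10L, "stratification", "mixing")
  if (length(unique(period)) < 2L)
    stop("date range does not span both periods; extend n_dates", call. = FALSE)
  doy <- as.integer(format(dates, "%j"))
  raw <- cos(2 * pi * (doy - 209) / 365.25)        # peaks late July
  t_true <- numeric(nd)
  for (p in unique(period)) {
    i <- period == p
    m <- if (p == "mixing") config$temp_mixing else config$temp_strat
    s <- stats::sd(raw[i])
    t_true[i] <- m + if (is.finite(s) && s > 0)
      config$temp_within_sd * (raw[i] - mean(raw[i])) / s else 0
  }
  temp <- t_true + stats::rnorm(nd, 0, config$temp_noise_sd)
  tbar <- mean(t_true)

  # diet trajectory: log-linear blend between period targets
  w <- pmin(pmax((t_true - config$temp_mixing) /
                   (config$temp_strat - config$temp_mixing), 0), 1)
  lp_mix <- log(pmax(config$diet_mixing, 1e-12))
  lp_str <- log(pmax(config$diet_strat, 1e-12))
  diet <- t(vapply(w, function(wi) {
    p <- exp((1 - wi) * lp_mix + wi * lp_str)
    p / sum(p)
  }, numeric(nrow(config$sources))))
  colnames(diet) <- config$sources$source_id

  nt <- length(config$taxa)
  # noise-free abundances and traits
  softmax_rows <- function(m) t(apply(m, 1L, function(v) {
    e <- exp(v - max(v)); e / sum(e)
  }))
  logits_true <- outer(t_true - tbar, config$ab_slope) +
    matrix(config$ab_base, nd, nt, byrow = TRUE)
  q_true <- apply_presence(softmax_rows(logits_true), config$presence_threshold)
  z_true <- outer(t_true - tbar, config$dw_slope) +
    matrix(config$dw_base, nd, nt, byrow = TRUE)
  z_true <- pmax(z_true, 0.05)
  # realized (noisy) abundances and traits
  logits <- logits_true + matrix(stats::rnorm(nd * nt, 0, config$q_noise_sd),
                                 nd, nt)
  q_real <- apply_presence(softmax_rows(logits), config$presence_threshold)
  z_real <- pmax(z_true + matrix(stats::rnorm(nd * nt, 0, config$dw_noise_sd),
                                 nd, nt), 0.05)
  colnames(q_true) <- colnames(q_real) <- colnames(z_true) <-
    colnames(z_real) <- config$taxa

  # consumer isotope replicates
  disp <- exp(-config$disp_slope * (t_true - tbar))
  mu_mix <- diet %*% cbind(config$sources$mean_d13C, config$sources$mean_d15N)
  rows <- vector("list", nd * nt)
  k <- 0L
  for (d in seq_len(nd)) {
    for (g in seq_len(nt)) {
      k <- k + 1L
      nr <- config$n_reps
      m13 <- mu_mix[d, 1] + config$tef$mean_d13C + config$group_off13[g]
      m15 <- mu_mix[d, 2] + config$tef$mean_d15N + config$group_off15[g]
      s13 <- config$sd13_base * config$group_sd_scale[g] * disp[d]
      s15 <- config$sd15_base * config$group_sd_scale[g] * disp[d]
      cp <- stats::rnorm(nr, 45, 3)
      np <- stats::rnorm(nr, 10, 0.8)
      rows[[k]] <- data.frame(
        sample_id = sprintf("d%02d_%s_r%d", d, config$taxa[g], seq_len(nr)),
        group_id = config$taxa[g],
        date = dates[d], period = period[d],
        d13C = stats::rnorm(nr, m13, s13),
        d15N = stats::rnorm(nr, m15, s15),
        c_percent = cp, n_percent = np, cn_ratio = cp / np,
        stringsAsFactors = FALSE)
    }
  }
  consumers <- do.call(rbind, rows)
  rownames(consumers) <- NULL

  snapshots <- lapply(seq_len(nd), function(d) {
    keep <- q_real[d, ] > 0
    community_snapshot(config$taxa[keep], q_real[d, keep], z_real[d, keep],
                       date = dates[d], period = period[d])
  })
  snapshot_table <- do.call(rbind, lapply(snapshots, function(s)
    data.frame(date = as.character(s$date), period = s$period, s$data,
               stringsAsFactors = FALSE)))

  # only temperature separates the periods strongly and dissolved oxygen
  # weakly; the remaining variables fluctuate mostly independently, the
  # typical monomictic-reservoir pattern
  env <- data.frame(
    date = dates, period = period,
    temperature = temp,
    DO = 9.5 - 0.12 * (t_true - tbar) + stats::rnorm(nd, 0, 0.5),
    pH = 7.3 + 0.02 * (t_true - tbar) + stats::rnorm(nd, 0, 0.15),
    DIC = pmax(10 + 0.05 * (t_true - tbar) + stats::rnorm(nd, 0, 0.8), 1),
    secchi = pmax(2.0 - 0.03 * (t_true - tbar) + stats::rnorm(nd, 0, 0.30), 0.3),
    TN = pmax(0.8 + 0.005 * (t_true - tbar) + stats::rnorm(nd, 0, 0.08), 0.05),
    TP = pmax(0.030 + 0.0005 * (t_true - tbar) + stats::rnorm(nd, 0, 0.005), 0.002),
    chla = pmax(8 + 0.3 * (t_true - tbar) + stats::rnorm(nd, 0, 2.0), 0.5),
    EC = 150 + 1.0 * (t_true - tbar) + stats::rnorm(nd, 0, 8),
    stringsAsFactors = FALSE)
  class(env) <- c("env_series", "data.frame")

  gt <- list(config = config, seed = seed, dates = dates, period = period,
             temp_true = t_true, diet = diet,
             q_true = q_true, z_true = z_true,
             q_real = q_real, z_real = z_real,
             dispersion = disp)
  iso_log("synth_generate", n_dates = nd, n_consumers = nrow(consumers),
          seed = seed)
  structure(list(consumers = consumers, sources = config$sources,
                 snapshots = snapshots, snapshot_table = snapshot_table,
                 env = env, ground_truth = gt),
            class = "synth_bundle")
}

apply_presence <- function(q, threshold) {
  if (threshold <= 0) return(q)
  q[q < threshold] <- 0
  sw <- rowSums(q)
  if (any(sw == 0)) stop("presence threshold removed all taxa", call. = FALSE)
  q / sw
}

#' Expected Price partitions from the generator's ground truth
#'
#' Builds noise-free snapshots from the ground truth's generating abundances
#' and trait values and partitions them, providing an oracle against which
#' pipeline partitions on the noisy realized data can be compared at a
#' tolerance scaled to the configured noise.
#'
#' @param gt the `ground_truth` element of a [synth_generate()] bundle.
#' @param mode passed to [price_partition()].
#' @return list of `price_partition` over consecutive dates.
#' @export
expected_partitions <- function(gt, mode = "telescoping") {
  nd <- length(gt$dates)
  snaps <- lapply(seq_len(nd), function(d) {
    keep <- gt$q_true[d, ] > 0
    community_snapshot(colnames(gt$q_true)[keep], gt$q_true[d, keep],
                       gt$z_true[d, keep],
                       date = gt$dates[d], period = gt$period[d])
  })
  timeseries_partition(snaps, mode = mode)
}

#' Write a synthetic bundle to CSV/JSON files
#'
#' @param bundle a [synth_generate()] bundle.
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
synth_write <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    consumers = file.path(dir, "consumers.csv"),
    sources = file.path(dir, "sources.csv"),
    snapshots = file.path(dir, "snapshots.csv"),
    env = file.path(dir, "env.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(bundle$consumers, paths["consumers"], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$sources), paths["sources"],
                   row.names = FALSE)
  utils::write.csv(bundle$snapshot_table, paths["snapshots"], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$env), paths["env"], row.names = FALSE)
  gt <- bundle$ground_truth
  gt$config$sources <- as.data.frame(gt$config$sources)
  gt$config$tef <- unclass(gt$config$tef)
  gt$dates <- as.character(gt$dates)
  jsonlite::write_json(unclass_deep(gt), paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
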