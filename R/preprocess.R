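# corrections and standardizations applied before niche and mixing analyses

#' Lipid-bias correction of consumer delta13C
#'
#' Lipids are depleted in 13C, so lipid-rich zooplankton read artificially
#' low in delta13C; corrections conventionally use tissue C content and the
#' C:N ratio as lipid proxies. The model form and coefficients differ among
#' calibration studies, so they are supplied explicitly: `mode = "off"`
#' returns delta13C unchanged, `mode = "linear"` applies
#' `d13C + intercept + slope * cn_ratio`. delta15N is never modified.
#'
#' @param samples an `isotope_samples` data.frame (or any data.frame with
#'   `d13C` and, for linear mode, `cn_ratio`).
#' @param mode `"off"` or `"linear"`.
#' @param intercept,slope correction coefficients in permil (per C:N unit
#'   for `slope`); ignored when `mode = "off"`.
#' @return `samples` with corrected `d13C`; in linear mode rows lacking a
#'   C:N ratio are excluded and counted in the `excluded` attribute.
#' @export
lipid_correct <- function(samples, mode = c("off", "linear"),
                          intercept = 0, slope = 0) {
  mode <- match.arg(mode)
  if (mode == "off") {
    attr(samples, "excluded") <- 0L
    return(samples)
  }
  ok <- is.finite(samples$cn_ratio)
  excluded <- sum(!ok)
  if (excluded > 0L)
    warning(excluded, " sample(s) lacking C:N excluded from lipid correction",
            call. = FALSE)
  out <- samples[ok, , drop = FALSE]
  out$d13C <- out$d13C + intercept + slope * out$cn_ratio
  rownames(out) <- NULL
  iso_log("lipid_correct", mode = mode, n = nrow(out), excluded = excluded)
  attr(out, "excluded") <- excluded
  out
}

#' Select baseline food sources by diet contribution
#'
#' A source anchors the isotopic baseline if its estimated mean diet
#' proportion exceeds `cutoff` in at least one period (strict `>`, default
#' 12%).
#'
#' @param contributions data.frame with columns `source_id`, `period`,
#'   `proportion` (mean diet proportions in `[0, 1]`), e.g. from
#'   [fit_mixing_model()] summaries per period.
#' @param cutoff retention threshold, default 0.12.
#' @return character vector of retained source ids.
#' @export
select_baseline_sources <- function(contributions, cutoff = 0.12) {
  need <- c("source_id", "period", "proportion")
  miss <- setdiff(need, names(contributions))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  p <- contributions$proportion
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  keep <- tapply(p, contributions$source_id, function(v) any(v > cutoff))
  retained <- names(keep)[keep]
  # preserve input source order
  retained <- unique(contributions$source_id)[unique(contributions$source_id) %in% retained]
  if (length(retained) == 0L)
    stop("no source exceeds the ", cutoff,
         " contribution cutoff in any period; review the cutoff", call. = FALSE)
  iso_log("select_baseline_sources", retained = length(retained),
          dropped = length(keep) - length(retained))
  retained
}

#' Baseline specification from retained sources
#'
#' Pools the retained sources per axis: baseline mean is the mean of their
#' per-source means and baseline range the spread of those means
#' (`pooling = "pooled"`, the default); `pooling = "minmax_sd"` instead
#' widens the range by the source SDs (mean +/- SD envelope). Both express
#' the same idea -- centre and scale of the resource field feeding the
#' consumers.
#'
#' @param sources a `source_summary` data.frame.
#' @param retained character vector of source ids to use.
#' @param pooling `"pooled"` or `"minmax_sd"`.
#' @return list of class `baseline_spec` with per-axis `mean` and `range`.
#' @export
baseline_spec <- function(sources, retained = sources$source_id,
                          pooling = c("pooled", "minmax_sd")) {
  pooling <- match.arg(pooling)
  s <- sources[sources$source_id %in% retained, , drop = FALSE]
  if (nrow(s) == 0L) stop("no retained sources found", call. = FALSE)
  rng <- function(mu, sd) {
    if (pooling == "pooled") diff(range(mu)) else diff(range(mu - sd, mu + sd))
  }
  out <- structure(list(
    retained = s$source_id,
    mean = c(x = mean(s$mean_d13C), y = mean(s$mean_d15N)),
    range = c(x = rng(s$mean_d13C, s$sd_d13C), y = rng(s$mean_d15N, s$sd_d15N))
  ), class = "baseline_spec")
  if (any(out$range <= 0))
    stop("degenerate baseline: zero range on an axis (single source or ",
         "coincident source means)", call. = FALSE)
  out
}

#' Standardize consumer isotope values against a resource baseline
#'
#' Removes among-date/among-system differences in resource signatures before
#' Euclidean niche metrics: per axis, `(x - baseline mean) / baseline range`.
#'
#' @param x numeric matrix or data.frame with two columns (delta13C,
#'   delta15N) or a numeric vector of length 2.
#' @param spec a `baseline_spec`.
#' @return same shape as `x`, dimensionless.
#' @export
baseline_standardize <- function(x, spec) {
  if (any(spec$range <= 0)) stop("degenerate baseline: zero range", call. = FALSE)
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop("x must have two isotope axes", call. = FALSE)
    return((x - spec$mean) / spec$range)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("x must have two isotope axes", call. = FALSE)
  sweep(sweep(x, 2, spec$mean, "-"), 2, spec$range, "/")
}

#' Dissolved CO2 from DIC, temperature and pH
#'
#' Carbonate-equilibrium speciation for fresh water: the CO2(aq) fraction of
#' dissolved inorganic carbon is `1 / (1 + K1/[H+] + K1*K2/[H+]^2)` with the
#' temperature-dependent first and second dissociation constants of carbonic
#' acid from the freshwater parameterization of Plummer & Busenberg (1982)
#' (pK1 = 6.352, pK2 = 10.329 at 25 degC). DIC is taken as mg C/L and
#' converted to umol/L via the molar mass of carbon (12.011 g/mol).
#'
#' @param dic dissolved inorganic carbon, mg C/L (>= 0).
#' @param temperature water temperature, degC, in (0, 40).
#' @param ph pH, in (0, 14).
#' @return dissolved CO2 in umol/L. Vectorised over all arguments.
#' @export
co2aq <- function(dic, temperature, ph) {
  if (any(ph <= 0 | ph >= 14)) stop("pH out of range (0, 14)", call. = FALSE)
  if (any(temperature <= 0 | temperature >= 40))
    stop("temperature out of range (0, 40) degC", call. = FALSE)
  if (any(dic < 0)) stop("DIC must be non-negative", call. = FALSE)
  tk <- temperature + 273.15
  # Plummer & Busenberg (1982) freshwater carbonic acid constants (log10 K)
  log_k1 <- -356.3094 - 0.06091964 * tk + 21834.37 / tk +
    126.8339 * log10(tk) - 1684915 / tk^2
  log_k2 <- -107.8871 - 0.03252849 * tk + 5151.79 / tk +
    38.92561 * log10(tk) - 563713.9 / tk^2
  k1 <- 10^log_k1; k2 <- 10^log_k2
  h <- 10^(-ph)
  frac_co2 <- 1 / (1 + k1 / h + k1 * k2 / h^2)
  dic_umol <- dic / 12.011 * 1000
  dic_umol * frac_co2
}

#' Euphotic depth from Secchi depth
#'
#' The depth of the photic zone approximated as 2.7 times the Secchi-disk
#' transparency.
#'
#' @param secchi Secchi depth, m (>= 0).
#' @return euphotic depth, m.
#' @export
euphotic_depth <- function(secchi) {
  if (any(secchi < 0)) stop("Secchi depth must be non-negative", call. = FALSE)
  2.7 * secchi
}

#' Community-weighted mean trait value
#'
#' `sum(q_i * z_i)` over the taxa of one snapshot.
#'
#' @param snapshot a `community_snapshot`.
#' @return the community-weighted mean, in trait units.
#' @export
community_weighted_mean <- function(snapshot) {
  d <- snapshot$data
  if (is.null(d) || nrow(d) == 0L) stop("empty snapshot", call. = FALSE)
  d <- d[d$q > 0, , drop = FALSE]   # absent taxa may carry NA traits
  sum(d$q * d$z)
}
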