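# Price-equation partitioning of community trait change into taxa sorting,
# intrataxonomic variation and taxa turnover

#' Price-equation partition of community trait change
#'
#' Decomposes the change in a community-aggregated trait,
#' `delta = sum(q2 * z2) - sum(q1 * z1)`, between two snapshots into:
#' taxa sorting `TS = sum_shared z1_i * (q2_i - q1_i)` (shifts in relative
#' abundance among taxa present at both times), intrataxonomic variation
#' `ITV = sum_shared q2_i * (z2_i - z1_i)` (within-taxon trait change), and
#' taxa turnover `TT = sum_gained q2*z2 - sum_lost q1*z1` (taxa present at
#' only one time). This telescoping pairing makes the three terms sum to
#' `delta` exactly. `mode = "three_term"` instead reports
#' `TS = sum z1 dq`, `ITV = sum q1 dz` and the abundance-trait covariation
#' `COV = sum dq dz` separately (also exactly additive).
#'
#' Taxa with relative abundance below `rarity_threshold` in a snapshot are
#' treated as absent there (and renormalised), routing rare taxa into the
#' turnover term; the default 0 disables this.
#'
#' @param c1,c2 `community_snapshot` objects (or lists with a `data`
#'   data.frame of `group_id`, `q`, `z`).
#' @param mode `"telescoping"` (default) or `"three_term"`.
#' @param rarity_threshold relative-abundance cutoff below which a taxon is
#'   routed to turnover (e.g. 0.03).
#' @return list of class `price_partition` with `delta_total`, `TS`, `ITV`,
#'   `TT` (and `COV` in three-term mode), relative contributions `rel_TS`,
#'   `rel_ITV`, `rel_TT` (percent), and the snapshot dates.
#' @export
price_partition <- function(c1, c2, mode = c("telescoping", "three_term"),
                            rarity_threshold = 0) {
  mode <- match.arg(mode)
  d1 <- snapshot_frame(c1, rarity_threshold)
  d2 <- snapshot_frame(c2, rarity_threshold)
  shared <- intersect(d1$group_id, d2$group_id)
  lost <- setdiff(d1$group_id, shared)
  gained <- setdiff(d2$group_id, shared)
  i1 <- match(shared, d1$group_id); i2 <- match(shared, d2$group_id)
  q1 <- d1$q[i1]; z1 <- d1$z[i1]
  q2 <- d2$q[i2]; z2 <- d2$z[i2]
  delta_total <- sum(d2$q * d2$z) - sum(d1$q * d1$z)
  tt <- sum(d2$q[match(gained, d2$group_id)] * d2$z[match(gained, d2$group_id)]) -
    sum(d1$q[match(lost, d1$group_id)] * d1$z[match(lost, d1$group_id)])
  if (mode == "telescoping") {
    ts <- sum(z1 * (q2 - q1))
    itv <- sum(q2 * (z2 - z1))
    comp <- list(TS = ts, ITV = itv, TT = tt)
  } else {
    ts <- sum(z1 * (q2 - q1))
    itv <- sum(q1 * (z2 - z1))
    cov_term <- sum((q2 - q1) * (z2 - z1))
    comp <- list(TS = ts, ITV = itv, COV = cov_term, TT = tt)
  }
  out <- c(list(delta_total = delta_total), comp,
           relative_contributions_raw(comp),
           list(mode = mode,
                date1 = date_or_na(c1), date2 = date_or_na(c2),
                shared = shared, gained = gained, lost = lost))
  class(out) <- "price_partition"
  out
}

snapshot_frame <- function(s, rarity_threshold = 0) {
  d <- if (is.list(s) && !is.null(s$data)) s$data else as.data.frame(s)
  d <- d[d$q > 0, , drop = FALSE]
  if (rarity_threshold > 0) {
    d <- d[d$q >= rarity_threshold, , drop = FALSE]
    if (nrow(d) == 0L) stop("all taxa below the rarity threshold", call. = FALSE)
    d$q <- d$q / sum(d$q)
  }
  bad <- !is.finite(d$z)
  if (any(bad))
    stop("missing trait value for taxa: ",
         paste(d$group_id[bad], collapse = ", "), call. = FALSE)
  d
}

date_or_na <- function(s) {
  if (is.list(s) && !is.null(s$date)) as.character(s$date) else NA_character_
}

relative_contributions_raw <- function(comp) {
  tot <- sum(abs(unlist(comp)))
  if (tot == 0)
    return(list(rel_TS = NA_real_, rel_ITV = NA_real_, rel_TT = NA_real_,
                rel_undefined = TRUE))
  rel <- lapply(comp, function(v) abs(v) / tot * 100)
  names(rel) <- paste0("rel_", names(comp))
  c(rel, list(rel_undefined = FALSE))
}

#' Relative contributions of partition components
#'
#' Percent share of each component in the total absolute change:
#' `rel_X = |X| / sum(|components|) * 100`. Components of opposite sign
#' therefore both register positive contributions. All-zero components
#' yield `NA` shares with `rel_undefined = TRUE`.
#'
#' @param p a `price_partition`.
#' @return named list of percentages plus `rel_undefined`.
#' @export
relative_contributions <- function(p) {
  comp <- p[intersect(c("TS", "ITV", "COV", "TT"), names(p))]
  relative_contributions_raw(comp)
}

#' Price partitions along a snapshot time series
#'
#' One partition per consecutive snapshot pair. The trait carried in `z`
#' can be anything computed upstream: per-taxon dry weight, group-mean
#' delta13C or delta15N, group MNND or group SEA_B.
#'
#' @param series list of `community_snapshot` with strictly increasing
#'   dates.
#' @inheritParams price_partition
#' @return list of `price_partition`, length `length(series) - 1`.
#' @export
timeseries_partition <- function(series, mode = "telescoping",
                                 rarity_threshold = 0) {
  if (length(series) < 2L) stop("need at least 2 snapshots", call. = FALSE)
  dates <- as.Date(vapply(series, date_or_na, ""))
  if (anyNA(dates) || any(diff(dates) <= 0))
    stop("snapshot dates must be present and strictly increasing", call. = FALSE)
  lapply(seq_len(length(series) - 1L), function(i)
    price_partition(series[[i]], series[[i + 1L]], mode = mode,
                    rarity_threshold = rarity_threshold))
}

#' Tidy table of a partition series
#'
#' @param partitions list of `price_partition` (from
#'   [timeseries_partition()]).
#' @return data.frame with one row per consecutive pair.
#' @export
partition_table <- function(partitions) {
  do.call(rbind, lapply(partitions, function(p) {
    data.frame(date1 = p$date1, date2 = p$date2,
               delta_total = p$delta_total, TS = p$TS, ITV = p$ITV,
               COV = if (!is.null(p$COV)) p$COV else NA_real_, TT = p$TT,
               rel_TS = p$rel_TS, rel_ITV = p$rel_ITV, rel_TT = p$rel_TT,
               stringsAsFactors = FALSE)
  }))
}

#' Aggregate a set of snapshots into one period-level snapshot
#'
#' Per-taxon mean relative abundance (renormalised; dates where a taxon is
#' absent count as zero) and mean trait value over the dates where the
#' taxon is present. Used to partition change between whole periods, e.g.
#' mixing vs stratification.
#'
#' @param snapshots list of `community_snapshot`.
#' @param label period label attached to the aggregate.
#' @return a `community_snapshot`.
#' @export
aggregate_snapshots <- function(snapshots, label = NA) {
  if (length(snapshots) == 0L) stop("no snapshots to aggregate", call. = FALSE)
  all_groups <- unique(unlist(lapply(snapshots, function(s) s$data$group_id)))
  qm <- sapply(all_groups, function(g) {
    mean(vapply(snapshots, function(s) {
      i <- match(g, s$data$group_id)
      if (is.na(i)) 0 else s$data$q[i]
    }, numeric(1)))
  })
  zm <- sapply(all_groups, function(g) {
    zz <- vapply(snapshots, function(s) {
      i <- match(g, s$data$group_id)
      if (is.na(i)) NA_real_ else s$data$z[i]
    }, numeric(1))
    mean(zz, na.rm = TRUE)
  })
  keep <- qm > 0
  community_snapshot(all_groups[keep], qm[keep] / sum(qm[keep]), zm[keep],
                     date = snapshots[[1]]$date, period = label)
}

#' Link partition-component contributions to environmental change
#'
#' Spearman correlation between the relative contribution of each partition
#' component and the change in each environmental variable over the same
#' consecutive date pairs.
#'
#' @param partitions list of `price_partition` over consecutive dates.
#' @param env an `env_series` data.frame covering the same dates; deltas
#'   are computed between consecutive rows after date-sorting.
#' @param variables environmental columns to use; default all numeric
#'   columns except `date`.
#' @return data.frame with `component`, `variable`, `rho`, `p`, `n` and a
#'   `flag` column (`"ok"`, `"insufficient_data"` or `"constant"`). Pairs
#'   with missing values are dropped listwise per cell; fewer than 4 usable
#'   pairs or a constant vector yield `NA` with the corresponding flag.
#' @export
link_contributions_env <- function(partitions, env, variables = NULL) {
  pt <- partition_table(partitions)
  env <- env[order(as.Date(env$date)), , drop = FALSE]
  if (is.null(variables))
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
  n_pairs <- nrow(env) - 1L
  if (n_pairs != nrow(pt))
    stop("env series must cover the same consecutive pairs as the partitions (",
         n_pairs, " vs ", nrow(pt), ")", call. = FALSE)
  comps <- c("rel_TS", "rel_ITV", "rel_TT")
  rows <- list()
  for (comp in comps) {
    for (v in variables) {
      dv <- diff(env[[v]])
      cc <- pt[[comp]]
      ok <- is.finite(dv) & is.finite(cc)
      flag <- "ok"; rho <- NA_real_; pval <- NA_real_
      if (sum(ok) < 4L) {
        flag <- "insufficient_data"
      } else if (stats::sd(cc[ok]) == 0 || stats::sd(dv[ok]) == 0) {
        flag <- "constant"
      } else {
        ct <- suppressWarnings(
          stats::cor.test(cc[ok], dv[ok], method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); pval <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = sub("rel_", "", comp), variable = v,
        rho = rho, p = pval, n = sum(ok), flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
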