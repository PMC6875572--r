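# a-priori mixing-polygon consumer screening and Bayesian diet-source mixing

#' Monte Carlo mixing-polygon screening of consumers
#'
#' Before fitting a mixing model, consumers falling outside the region the
#' sources can actually explain are flagged. Per iteration each
#' enrichment-corrected source vertex is drawn from
#' `Normal(source mean + TEF mean, sqrt(source SD^2 + TEF SD^2))` per axis,
#' the convex hull of the drawn vertices is built, and every consumer is
#' point-in-hull tested (boundary counts as inside). A consumer's inclusion
#' probability is the fraction of iterations whose polygon contains it;
#' consumers with probability below `cutoff` (default 0.05, i.e. outside the
#' 95% simulated mixing region) are flagged for exclusion.
#'
#' @param sources a `source_summary` with at least three sources.
#' @param tef a [trophic_enrichment()].
#' @param consumers two-column matrix/data.frame of consumer
#'   (delta13C, delta15N) points; row names (or a `sample_id` column of a
#'   data.frame) are carried through.
#' @param n_iter Monte Carlo iterations (>= 1000).
#' @param cutoff exclusion threshold on the inclusion probability.
#' @param seed RNG seed.
#' @return data.frame of class `polygon_test` with `sample_id`, `p`
#'   (inclusion probability) and `excluded`; attribute `n_iter`.
#' @export
simulate_mixing_polygon <- function(sources, tef, consumers,
                                    n_iter = 2000L, cutoff = 0.05,
                                    seed = 1L) {
  if (nrow(sources) < 3L)
    stop("mixing polygon needs >= 3 sources (got ", nrow(sources),
         "); the hull is degenerate", call. = FALSE)
  if (n_iter < 1000L) stop("n_iter must be >= 1000", call. = FALSE)
  ids <- if (is.data.frame(consumers) && "sample_id" %in% names(consumers)) {
    out <- as.character(consumers$sample_id)
    consumers <- consumers[, setdiff(names(consumers), "sample_id")]
    out
  } else if (!is.null(rownames(consumers))) rownames(consumers) else NULL
  x <- as_point_matrix(consumers)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  s <- nrow(sources)
  mx <- sources$mean_d13C + tef$mean_d13C
  my <- sources$mean_d15N + tef$mean_d15N
  sx <- sqrt(sources$sd_d13C^2 + tef$sd_d13C^2)
  sy <- sqrt(sources$sd_d15N^2 + tef$sd_d15N^2)
  set.seed(seed)
  hits <- integer(nrow(x))
  for (it in seq_len(n_iter)) {
    vx <- stats::rnorm(s, mx, sx)
    vy <- stats::rnorm(s, my, sy)
    hits <- hits + in_convex_hull(x, vx, vy)
  }
  p <- hits / n_iter
  res <- data.frame(sample_id = ids, p = p, excluded = p < cutoff,
                    stringsAsFactors = FALSE)
  if (all(hits == 0L))
    warning("no consumer fell inside any simulated polygon; all excluded",
            call. = FALSE)
  iso_log("simulate_mixing_polygon", n = nrow(x), excluded = sum(res$excluded),
          n_iter = n_iter, seed = seed)
  attr(res, "n_iter") <- n_iter
  attr(res, "cutoff") <- cutoff
  class(res) <- c("polygon_test", "data.frame")
  res
}

# vectorised inclusive point-in-convex-hull test for all rows of pts against
# the hull of (vx, vy); boundary points count as inside
in_convex_hull <- function(pts, vx, vy) {
  h <- grDevices::chull(vx, vy)
  if (length(h) < 3L) return(rep(0L, nrow(pts)))
  hx <- vx[h]; hy <- vy[h]
  n <- length(h)
  tol <- 1e-12 * max(abs(c(hx, hy, 1)))^2
  inside <- rep(TRUE, nrow(pts))
  # chull returns vertices clockwise: interior lies at non-positive cross
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    cr <- ex * (pts[, 2] - hy[i]) - ey * (pts[, 1] - hx[i])
    inside <- inside & (cr <= tol)
  }
  as.integer(inside)
}

#' Bayesian diet-source mixing model
#'
#' Estimates community-level diet proportions `p` over the sources from
#' consumer delta13C/delta15N values. Likelihood per consumer `j` and
#' isotope `k`:
#' `x_jk ~ Normal(sum_s p_s (mu_sk + f_k), sum_s p_s^2 (sigma_sk^2 + tau_k^2) + eps_k^2)`
#' with trophic-enrichment mean `f` and SD `tau`, and an optional residual
#' SD `eps_k` with a weakly-informative half-normal prior. The prior on `p`
#' is `Dirichlet(1, ..., 1)`; sampling is random-walk Metropolis on
#' centered-log-ratio coordinates (the Dirichlet prior enters through the
#' softmax Jacobian) plus `log eps`, with step sizes adapted during burn-in
#' only. Multiple chains are run and split-R-hat and a crude effective
#' sample size are reported per source.
#'
#' @param consumers two-column matrix/data.frame of consumer points
#'   (ideally already screened by [simulate_mixing_polygon()]).
#' @param sources a `source_summary` with >= 2 sources.
#' @param tef a [trophic_enrichment()].
#' @param cfg an [iso_config()] supplying MCMC settings and seed.
#' @param resid_err include the residual error term? (`FALSE` gives the
#'   exact process model, useful for oracle tests.)
#' @param screened set `TRUE` to silence the reminder that polygon screening
#'   should precede fitting.
#' @return list of class `mixing_posterior`: `draws` (retained draws x
#'   sources, all chains pooled), `summary` data.frame (mean, median, 2.5%
#'   and 97.5% quantiles per source), `eps_draws`, `rhat`, `ess`,
#'   `converged`, and the settings used.
#' @export
fit_mixing_model <- function(consumers, sources, tef = trophic_enrichment(),
                             cfg = iso_config(), resid_err = TRUE,
                             screened = FALSE) {
  x <- as_point_matrix(consumers)
  s <- nrow(sources)
  if (nrow(x) < 1L) stop("no consumers", call. = FALSE)
  if (s == 1L) {
    # 0-dimensional simplex: the posterior is a point mass at p = 1
    n_keep <- length(seq.int(cfg$mcmc$burn + 1L, cfg$mcmc$iterations,
                             by = cfg$mcmc$thin))
    draws <- matrix(1, n_keep, 1L, dimnames = list(NULL, sources$source_id))
    summary_df <- data.frame(source_id = sources$source_id, mean = 1,
                             median = 1, q025 = 1, q975 = 1, rhat = 1,
                             ess = n_keep, stringsAsFactors = FALSE)
    return(structure(list(draws = draws, eps_draws = NULL,
                          summary = summary_df,
                          rhat = c(1), ess = c(n_keep), converged = TRUE,
                          accept_rate = NA_real_, settings = cfg$mcmc,
                          resid_err = resid_err),
                     class = "mixing_posterior"))
  }
  if (!screened)
    message("note: consumers have not been flagged as polygon-screened")
  m <- cfg$mcmc
  mu <- cbind(sources$mean_d13C + tef$mean_d13C,
              sources$mean_d15N + tef$mean_d15N)
  v <- cbind(sources$sd_d13C^2 + tef$sd_d13C^2,
             sources$sd_d15N^2 + tef$sd_d15N^2)
  nx <- nrow(x)
  sum_x <- colSums(x)
  sum_x2 <- colSums(x^2)

  # log posterior as a function of clr coords z and log-residual-sd le
  log_post <- function(z, le) {
    p <- exp(z - max(z)); p <- p / sum(p)
    if (any(p < 1e-300)) return(-Inf)
    eps2 <- if (resid_err) exp(2 * le) else c(0, 0)
    lp <- sum(log(p))                           # Dirichlet(1) + Jacobian
    if (resid_err) lp <- lp - sum(exp(le)^2) / (2 * 25) + sum(le)
    for (k in 1:2) {
      mk <- sum(p * mu[, k])
      vk <- sum(p^2 * v[, k]) + eps2[k]
      # sum of dnorm over consumers in closed form
      lp <- lp - nx * 0.5 * log(2 * pi * vk) -
        (sum_x2[k] - 2 * mk * sum_x[k] + nx * mk^2) / (2 * vk)
    }
    lp
  }

  n_keep <- length(seq.int(m$burn + 1L, m$iterations, by = m$thin))
  chains_p <- vector("list", m$chains)
  chains_e <- vector("list", m$chains)
  accepts <- numeric(m$chains)
  for (ch in seq_len(m$chains)) {
    set.seed(cfg$seed + 1000L * (ch - 1L))
    z <- stats::rnorm(s, 0, 0.5); z <- z - mean(z)
    le <- if (resid_err) stats::rnorm(2, 0, 0.5) else c(0, 0)
    step <- 0.4
    lp <- log_post(z, le)
    kept <- matrix(NA_real_, n_keep, s)
    kept_e <- matrix(NA_real_, n_keep, 2)
    ki <- 0L
    acc <- 0L; acc_win <- 0L
    for (it in seq_len(m$iterations)) {
      z_new <- z + stats::rnorm(s, 0, step)
      z_new <- z_new - mean(z_new)
      le_new <- if (resid_err) le + stats::rnorm(2, 0, step) else le
      lp_new <- log_post(z_new, le_new)
      if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
        z <- z_new; le <- le_new; lp <- lp_new
        acc <- acc + 1L; acc_win <- acc_win + 1L
      }
      if (it <= m$burn && it %% 50L == 0L) {   # adapt during burn-in only
        rate <- acc_win / 50
        step <- step * exp(rate - 0.3)
        acc_win <- 0L
      }
      if (it > m$burn && (it - m$burn - 1L) %% m$thin == 0L) {
        ki <- ki + 1L
        pk <- exp(z - max(z)); pk <- pk / sum(pk)
        kept[ki, ] <- pk
        kept_e[ki, ] <- exp(le)
      }
    }
    chains_p[[ch]] <- kept[seq_len(ki), , drop = FALSE]
    chains_e[[ch]] <- kept_e[seq_len(ki), , drop = FALSE]
    accepts[ch] <- acc / m$iterations
  }
  draws <- do.call(rbind, chains_p)
  colnames(draws) <- sources$source_id
  eps_draws <- do.call(rbind, chains_e)
  colnames(eps_draws) <- c("eps_d13C", "eps_d15N")
  rhat <- vapply(seq_len(s), function(j)
    split_rhat(lapply(chains_p, function(cc) cc[, j])), numeric(1))
  ess <- vapply(seq_len(s), function(j)
    sum(vapply(chains_p, function(cc) ess_chain(cc[, j]), numeric(1))),
    numeric(1))
  names(rhat) <- names(ess) <- sources$source_id
  converged <- all(is.finite(rhat) & rhat < 1.1)
  if (!converged)
    warning("non-convergence: split-R-hat > 1.1 for ",
            paste(sources$source_id[rhat >= 1.1], collapse = ", "),
            call. = FALSE)
  summary_df <- data.frame(
    source_id = sources$source_id,
    mean = colMeans(draws),
    median = apply(draws, 2, stats::median),
    q025 = apply(draws, 2, stats::quantile, 0.025),
    q975 = apply(draws, 2, stats::quantile, 0.975),
    rhat = rhat, ess = ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  iso_log("fit_mixing_model", n_consumers = nx, n_sources = s,
          chains = m$chains, accept = round(mean(accepts), 2),
          converged = converged)
  structure(list(draws = draws, eps_draws = eps_draws, summary = summary_df,
                 rhat = rhat, ess = ess, converged = converged,
                 accept_rate = accepts, settings = m, resid_err = resid_err),
            class = "mixing_posterior")
}

# split-R-hat over a list of per-chain draw vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  m <- length(halves); n <- length(halves[[1]])
  w <- mean(vrs)
  b <- n * stats::var(mns)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# crude initial-positive-sequence effective sample size for one chain
ess_chain <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1L else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}
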