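# partial least squares path modeling with reflective (mode-A) blocks

#' Specify a PLS path model
#'
#' @param blocks named list; each element is a character vector of indicator
#'   column names forming one latent block (e.g. `temperature`,
#'   `physicochemical`, `nutrients`, `chlorophyll`).
#' @param paths square 0/1 matrix over the blocks (rows = response,
#'   columns = predictor): `paths[i, j] = 1` means latent `j` points at
#'   latent `i`. Must be lower-triangular in the given block order
#'   (acyclic).
#' @param scheme inner weighting scheme: `"centroid"` (default),
#'   `"factorial"` or `"path"`.
#' @param max_iter,tol outer-estimation iteration cap and convergence
#'   tolerance on the weight change.
#' @return list of class `path_model_spec`.
#' @export
path_model_spec <- function(blocks, paths, scheme = c("centroid", "factorial", "path"),
                            max_iter = 200L, tol = 1e-7) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a named list", call. = FALSE)
  if (any(lengths(blocks) == 0L)) stop("empty block", call. = FALSE)
  paths <- as.matrix(paths)
  nb <- length(blocks)
  if (!all(dim(paths) == nb)) stop("paths must be ", nb, "x", nb, call. = FALSE)
  if (is.null(rownames(paths))) rownames(paths) <- colnames(paths) <- names(blocks)
  if (any(paths[upper.tri(paths, diag = TRUE)] != 0))
    stop("paths must be lower-triangular (acyclic) in block order", call. = FALSE)
  structure(list(blocks = blocks, paths = (paths != 0) * 1L, scheme = scheme,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "path_model_spec")
}

#' Fit a PLS path model
#'
#' Lohmoeller-style alternating estimation with reflective (mode-A) outer
#' weights: latent scores are standardized weighted sums of their block's
#' indicators; inner proxies combine adjacent latents per the chosen
#' scheme (centroid: sign of the score correlation; factorial: the
#' correlation; path: regression on predecessors, correlation with
#' successors); outer weights are refreshed as indicator-proxy covariances
#' until the maximum weight change falls below `tol`. Path coefficients are
#' then OLS fits of each endogenous latent on its predecessors, and
#' `GoF = sqrt(mean communality x mean R2)` with communality the squared
#' loading (averaged over all indicators) and R2 averaged over endogenous
#' latents. Each latent is oriented so the sum of its loadings is positive,
#' making results deterministic. Indicators are standardized internally, so
#' results are scale-invariant.
#'
#' @param data data.frame containing every indicator column; rows with
#'   missing values among the used indicators are dropped listwise.
#' @param spec a [path_model_spec()].
#' @return list of class `path_model_fit`: `weights`, `loadings` (named by
#'   indicator), `scores` (n x blocks), `paths` data.frame (`from`, `to`,
#'   `coefficient`), `r2` (per endogenous latent), `communality`, `gof`,
#'   `iterations`, `spec`, `n`.
#' @export
fit_plspm <- function(data, spec) {
  vars <- unlist(spec$blocks, use.names = FALSE)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("missing indicator column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(data[, vars, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 complete samples", call. = FALSE)
  if (n < max(lengths(spec$blocks)) + 3L)
    warning("few samples relative to the largest block", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant indicator(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  x <- scale(x)
  nb <- length(spec$blocks)
  bn <- names(spec$blocks)
  adj <- spec$paths | t(spec$paths)          # undirected neighbourhood
  idx <- lapply(spec$blocks, function(b) match(b, colnames(x)))
  # init: equal weights
  w <- lapply(idx, function(ii) rep(1, length(ii)))
  scores <- function(w) {
    y <- vapply(seq_len(nb), function(b) {
      s <- x[, idx[[b]], drop = FALSE] %*% w[[b]]
      as.numeric(scale(s))
    }, numeric(n))
    colnames(y) <- bn
    y
  }
  y <- scores(w)
  it <- 0L
  repeat {
    it <- it + 1L
    r_yy <- stats::cor(y)
    z <- matrix(0, n, nb)
    for (b in seq_len(nb)) {
      nbrs <- which(adj[b, ] > 0)
      if (length(nbrs) == 0L) { z[, b] <- y[, b]; next }
      e <- numeric(length(nbrs))
      for (k in seq_along(nbrs)) {
        j <- nbrs[k]
        e[k] <- switch(spec$scheme,
          centroid = sign(r_yy[b, j]),
          factorial = r_yy[b, j],
          path = NA_real_)   # filled below
      }
      if (spec$scheme == "path") {
        preds <- which(spec$paths[b, ] > 0)          # predecessors of b
        succs <- which(spec$paths[, b] > 0)          # successors of b
        e <- numeric(length(nbrs))
        if (length(preds)) {
          beta <- stats::coef(stats::lm.fit(cbind(1, y[, preds, drop = FALSE]),
                                            y[, b]))[-1]
          e[match(preds, nbrs)] <- beta
        }
        if (length(succs)) e[match(succs, nbrs)] <- r_yy[b, succs]
      }
      z[, b] <- y[, nbrs, drop = FALSE] %*% e
    }
    # mode-A outer weights, normalised so the score has unit variance
    w_new <- lapply(seq_len(nb), function(b) {
      wb <- as.numeric(stats::cor(x[, idx[[b]], drop = FALSE], z[, b]))
      s <- x[, idx[[b]], drop = FALSE] %*% wb
      wb / stats::sd(s)
    })
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    y <- scores(w)
    if (delta < spec$tol) break
    if (it >= spec$max_iter)
      stop("PLS-PM did not converge in ", spec$max_iter,
           " iterations (last delta = ", format(delta), ")", call. = FALSE)
  }
  # orient latents: sum of loadings positive
  for (b in seq_len(nb)) {
    ld <- as.numeric(stats::cor(x[, idx[[b]], drop = FALSE], y[, b]))
    if (sum(ld) < 0) { y[, b] <- -y[, b]; w[[b]] <- -w[[b]] }
  }
  loadings <- stats::setNames(unlist(lapply(seq_len(nb), function(b)
    as.numeric(stats::cor(x[, idx[[b]], drop = FALSE], y[, b])))), vars)
  # inner model: OLS per endogenous latent
  paths_df <- NULL
  r2 <- numeric(0)
  for (b in seq_len(nb)) {
    preds <- which(spec$paths[b, ] > 0)
    if (length(preds) == 0L) next
    fit <- stats::lm(y[, b] ~ y[, preds, drop = FALSE])
    beta <- stats::coef(fit)[-1]
    paths_df <- rbind(paths_df, data.frame(
      from = bn[preds], to = bn[b], coefficient = as.numeric(beta),
      stringsAsFactors = FALSE))
    r2[bn[b]] <- summary(fit)$r.squared
  }
  communality <- loadings^2
  gof <- sqrt(mean(communality) * mean(r2))
  structure(list(weights = w, loadings = loadings, scores = y,
                 paths = paths_df, r2 = r2, communality = communality,
                 gof = gof, iterations = it, spec = spec, n = n),
            class = "path_model_fit")
}

#' Prune low-loading indicators and refit
#'
#' Drops every indicator whose absolute loading in the initial fit is below
#' `loading_cutoff`, then refits. Blocks emptied by the pruning are removed
#' from the inner model with a warning; a terminal endogenous block losing
#' all its indicators is an error.
#'
#' @param data as in [fit_plspm()].
#' @param spec a [path_model_spec()].
#' @param loading_cutoff minimum absolute loading kept, default 0.7.
#' @return list: `fit` (the refit `path_model_fit`), `dropped`
#'   (indicator names), `initial_fit`.
#' @export
prune_and_refit <- function(data, spec, loading_cutoff = 0.7) {
  fit0 <- fit_plspm(data, spec)
  drop <- names(fit0$loadings)[abs(fit0$loadings) < loading_cutoff]
  if (length(drop) == 0L)
    return(list(fit = fit0, dropped = character(0), initial_fit = fit0))
  blocks <- lapply(spec$blocks, setdiff, y = drop)
  empty <- names(blocks)[lengths(blocks) == 0L]
  if (length(empty)) {
    terminal <- names(blocks)[rowSums(spec$paths) > 0 & colSums(spec$paths) == 0]
    dead <- intersect(empty, terminal)
    if (length(dead))
      stop("pruning emptied terminal endogenous block(s): ",
           paste(dead, collapse = ", "), call. = FALSE)
    warning("block(s) emptied by pruning removed from the inner model: ",
            paste(empty, collapse = ", "), call. = FALSE)
    keep <- setdiff(names(blocks), empty)
    blocks <- blocks[keep]
    paths <- spec$paths[keep, keep, drop = FALSE]
  } else paths <- spec$paths
  spec2 <- path_model_spec(blocks, paths, scheme = spec$scheme,
                           max_iter = spec$max_iter, tol = spec$tol)
  list(fit = fit_plspm(data, spec2), dropped = drop, initial_fit = fit0)
}

#' Bootstrap confidence intervals and p-values for path coefficients
#'
#' Nonparametric bootstrap over rows: the model is refit on each resample,
#' percentile confidence intervals are formed per path, and a two-sided
#' p-value is computed from the bootstrap distribution's tail mass at zero
#' (with a `1/(B+1)` continuity floor). Paths are flagged significant at
#' `alpha` (default 0.10).
#'
#' @param data,spec as in [fit_plspm()].
#' @param B number of resamples.
#' @param seed RNG seed.
#' @param alpha significance level for the flag and the `1 - alpha` CI.
#' @return data.frame: `from`, `to`, `coefficient` (full-data), `ci_lo`,
#'   `ci_hi`, `p`, `significant`; attribute `failures` counts resamples
#'   whose fit failed (error if above 5% of `B`).
#' @export
bootstrap_paths <- function(data, spec, B = 200L, seed = 1L, alpha = 0.10) {
  fit0 <- fit_plspm(data, spec)
  key <- paste(fit0$paths$from, fit0$paths$to, sep = "->")
  set.seed(seed)
  vars <- unlist(spec$blocks, use.names = FALSE)
  cc <- stats::complete.cases(as.matrix(data[, vars, drop = FALSE]))
  df <- data[cc, , drop = FALSE]
  n <- nrow(df)
  boots <- matrix(NA_real_, B, length(key), dimnames = list(NULL, key))
  failures <- 0L
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_plspm(df[rows, , drop = FALSE], spec),
                   error = function(e) NULL)
    if (is.null(fb)) { failures <- failures + 1L; next }
    boots[b, paste(fb$paths$from, fb$paths$to, sep = "->")] <-
      fb$paths$coefficient
  }
  if (failures > 0.05 * B)
    stop("bootstrap failure rate ", round(failures / B, 3),
         " exceeds 5%", call. = FALSE)
  out <- fit0$paths
  out$ci_lo <- apply(boots, 2, stats::quantile, alpha / 2, na.rm = TRUE)
  out$ci_hi <- apply(boots, 2, stats::quantile, 1 - alpha / 2, na.rm = TRUE)
  out$p <- vapply(seq_along(key), function(j) {
    v <- boots[, j]; v <- v[is.finite(v)]
    lo <- mean(v <= 0); hi <- mean(v >= 0)
    max(2 * min(lo, hi), 1 / (length(v) + 1))
  }, numeric(1))
  out$significant <- out$p < alpha
  attr(out, "failures") <- failures
  out
}
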