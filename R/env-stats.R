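# environment-side statistics: PERMANOVA, collinearity pruning, VIF filtering

#' One-factor PERMANOVA on a multivariate environmental table
#'
#' Permutational multivariate ANOVA on the Euclidean distance matrix of the
#' (optionally z-score standardized) sample-by-variable matrix, testing a
#' single grouping factor (e.g. mixing vs stratification period). The
#' partitioning and permutation test are delegated to
#' [vegan::adonis2()]. With `per_variable = TRUE` each variable is tested in
#' its own marginal one-variable run, mirroring tables that report per
#' variable R-squared against the same grouping.
#'
#' @param data numeric samples-by-variables matrix or data.frame.
#' @param grouping factor/character of group labels, length `nrow(data)`;
#'   at least 2 groups.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param standardize z-score each column first? (default TRUE)
#' @param per_variable report marginal one-variable runs instead of one
#'   grouped run.
#' @return For the grouped run, a list of class `permanova_result` with
#'   `r2`, `r2_residual`, `f`, `p`, `df`, `n_perm`; for `per_variable`, a
#'   data.frame with one row per variable (`variable`, `r2`, `f`, `p`).
#' @export
permanova_one_factor <- function(data, grouping, n_perm = 999L, seed = 1L,
                                 standardize = TRUE, per_variable = FALSE) {
  x <- as.matrix(data)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  grouping <- as.factor(grouping)
  if (nlevels(grouping) < 2L)
    stop("grouping must have at least 2 levels", call. = FALSE)
  if (length(grouping) != nrow(x))
    stop("grouping length must match rows of data", call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0   # constant columns carry no signal
  }
  run_one <- function(mat) {
    set.seed(seed)
    d <- stats::dist(mat)
    a <- vegan::adonis2(d ~ g, data = data.frame(g = grouping),
                        permutations = n_perm)
    list(r2 = a$R2[1], r2_residual = a$R2[nrow(a) - 1L],
         f = a$F[1], p = a$`Pr(>F)`[1],
         df = a$Df[1], n_perm = n_perm)
  }
  if (per_variable) {
    out <- do.call(rbind, lapply(colnames(x), function(v) {
      r <- run_one(x[, v, drop = FALSE])
      data.frame(variable = v, r2 = r$r2, f = r$f, p = r$p,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  res <- run_one(x)
  class(res) <- "permanova_result"
  res
}

#' Greedy Spearman collinearity pruning
#'
#' Variables are scanned in column order; a variable is dropped when its
#' absolute Spearman correlation with an already-retained variable exceeds
#' `rho_cutoff` with `p < p_cutoff`. Records which retained partner caused
#' each drop.
#'
#' @param data numeric samples-by-variables matrix or data.frame.
#' @param rho_cutoff absolute Spearman rho above which a pair is collinear
#'   (default 0.7, strict `>`).
#' @param p_cutoff significance cutoff for the correlation (default 0.05).
#' @return list with `retained` (character), `dropped` (named character:
#'   dropped variable -> retained partner) and the pairwise `rho` matrix.
#' @export
collinearity_prune <- function(data, rho_cutoff = 0.7, p_cutoff = 0.05) {
  x <- as.data.frame(data)
  vars <- names(x)
  if (length(vars) < 2L) stop("need at least 2 variables", call. = FALSE)
  retained <- character(0)
  dropped <- character(0)
  for (v in vars) {
    clash <- NA_character_
    for (r in retained) {
      ct <- suppressWarnings(
        stats::cor.test(x[[v]], x[[r]], method = "spearman", exact = FALSE))
      if (is.finite(ct$estimate) && abs(ct$estimate) > rho_cutoff &&
          ct$p.value < p_cutoff) {
        clash <- r
        break
      }
    }
    if (is.na(clash)) retained <- c(retained, v)
    else dropped[v] <- clash
  }
  if (length(retained) == 1L)
    warning("all variables mutually collinear; single survivor '",
            retained, "'", call. = FALSE)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  iso_log("collinearity_prune", retained = length(retained),
          dropped = length(dropped))
  list(retained = retained, dropped = dropped, rho = rho)
}

#' Variance-inflation-factor filtering
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing variable `j` on all others;
#' the largest VIF at or above `cutoff` is dropped and VIFs recomputed,
#' until all remaining VIFs are below the cutoff. Perfectly collinear
#' variables (infinite VIF) are dropped first.
#'
#' @param data numeric samples-by-variables matrix or data.frame; for exact
#'   VIFs there must be more samples than variables.
#' @param cutoff VIF threshold, default 10.
#' @return list with `retained`, `dropped` (in drop order), and `vif`
#'   (named vector for the retained set).
#' @export
vif_filter <- function(data, cutoff = 10) {
  x <- as.data.frame(data)
  dropped <- character(0)
  vifs <- compute_vifs(x)
  while (length(vifs) > 1L && max(vifs) >= cutoff) {
    worst <- names(vifs)[which.max(vifs)]
    dropped <- c(dropped, worst)
    x[[worst]] <- NULL
    vifs <- compute_vifs(x)
  }
  iso_log("vif_filter", retained = length(vifs), dropped = length(dropped))
  list(retained = names(vifs), dropped = dropped, vif = vifs)
}

compute_vifs <- function(x) {
  vars <- names(x)
  if (length(vars) == 1L) return(stats::setNames(1, vars))
  vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = x)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}
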