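# ---- shared machinery ------------------------------------------------------

# precomputed unpenalized fixed-basis engine for one design matrix.
# The mean-curve tests compare working Gaussian likelihoods of UNPENALIZED
# fixed-basis fits: with smoothing = 0 the null model's column space is
# nested in the alternative's, so RSS_alt <= RSS_null and the statistic is
# non-negative by construction (a penalized RSS would not be monotone).
lrt_engine <- function(X, basis_dim = 15L) {
  basis <- fosr_basis(basis_dim, 2L)
  A <- kronecker(crossprod(X), crossprod(basis$B))
  R <- tryCatch(chol(A), error = function(e) {
    stop("rank-deficient design in likelihood-ratio fit: ",
         conditionMessage(e))
  })
  list(X = X, B = basis$B, R = R, P = ncol(X), d = basis$dim)
}

# residual sum of squares of the engine's least-squares fit to Y
engine_rss <- function(eng, Y, sumY2 = sum(Y^2)) {
  Cm <- crossprod(eng$X, Y %*% eng$B)
  b <- as.vector(t(Cm))
  theta <- backsolve(eng$R, backsolve(eng$R, b, transpose = TRUE))
  max(sumY2 - sum(theta * b), 0)
}

# fitted curves of the engine's fit (needed once, for the null model)
engine_fitted <- function(eng, Y) {
  Cm <- crossprod(eng$X, Y %*% eng$B)
  b <- as.vector(t(Cm))
  theta <- backsolve(eng$R, backsolve(eng$R, b, transpose = TRUE))
  coefm <- matrix(theta, nrow = eng$P, ncol = eng$d, byrow = TRUE)
  eng$X %*% coefm %*% t(eng$B)
}

# working-Gaussian LRT statistic: 2(l_alt - l_null) = N log(RSS0 / RSS1)
lrt_statistic <- function(rss0, rss1, N) {
  if (rss0 <= 0) return(0)
  max(N * log(rss0 / max(rss1, 1e-300)), 0)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# ---- mean-curve equality ----------------------------------------------------

#' Simulation-based likelihood-ratio test for equality of two mean curves
#'
#' Tests whether two groups share a mean curve, optionally controlling for
#' covariates. The null model regresses the curves on the covariates only;
#' the alternative adds a time-varying group-indicator coefficient. Both are
#' unpenalized fixed-basis function-on-scalar fits (cubic B-splines,
#' `basis_dim` functions), so the models are exactly nested and the working
#' Gaussian likelihood-ratio statistic `Lambda = N log(RSS0/RSS1)` is always
#' non-negative. The null distribution is built by residual-curve
#' resampling: simulated responses are the null fitted values plus whole
#' residual curves resampled with replacement across subjects, which
#' preserves within-curve dependence.
#'
#' @param curves `n x 288` response matrix.
#' @param group length-`n` vector with exactly two distinct labels.
#' @param covariates optional `n x q` matrix of (standardized) covariate
#'   columns for the null model; `NULL` for the no-covariate setting.
#' @param n_sim number of null simulations (>= 99; 10000 for
#'   publication-scale runs).
#' @param seed integer seed (the test is deterministic given it).
#' @param basis_dim fixed spline basis dimension (default 15).
#' @param comparison,covariate_setting labels recorded in the result.
#' @return object of class `fda_lrt`: `statistic`, `null_draws`, `p_value`
#'   `= (1 + #\{null >= Lambda\})/(n_sim + 1)`, `n_sim`, labels.
#' @export
lrt_mean_equality <- function(curves, group, covariates = NULL,
                              n_sim = 10000L, seed = 1L, basis_dim = 15L,
                              comparison = "", covariate_setting = "") {
  if (!is.matrix(curves)) curves <- as.matrix(curves)
  if (n_sim < 99L) stop("n_sim below 99 gives too coarse a p-value resolution")
  glab <- unique(group)
  if (length(glab) != 2L) stop("group must have exactly two levels")
  if (length(group) != nrow(curves)) stop("group/curves length mismatch")
  g <- as.numeric(group == glab[2])
  n <- nrow(curves)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  X1 <- cbind(X0, group = g)
  eng0 <- lrt_engine(X0, basis_dim)
  eng1 <- lrt_engine(X1, basis_dim)

  F0 <- engine_fitted(eng0, curves)
  E <- curves - F0
  sumY2 <- sum(curves^2)
  rss0 <- engine_rss(eng0, curves, sumY2)
  rss1 <- engine_rss(eng1, curves, sumY2)
  N <- length(curves)
  stat <- lrt_statistic(rss0, rss1, N)

  draws <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      Ystar <- F0 + E[sample.int(n, n, replace = TRUE), , drop = FALSE]
      s2 <- sum(Ystar^2)
      lrt_statistic(engine_rss(eng0, Ystar, s2),
                    engine_rss(eng1, Ystar, s2), N)
    }, numeric(1))
  })
  structure(list(statistic = stat, null_draws = draws,
                 p_value = (1 + sum(draws >= stat)) / (n_sim + 1),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 comparison = comparison,
                 covariate_setting = covariate_setting,
                 groups = as.character(glab), method = "residual-resampling"),
            class = "fda_lrt")
}

#' Paired weekend-vs-weekday mean-curve test
#'
#' Forms per-subject difference curves `D_i(t) = weekend_i(t) - weekday_i(t)`
#' and tests whether their mean is identically zero: the null model fits
#' nothing (mean zero), the alternative a free fixed-basis spline mean. The
#' null distribution sign-flips whole difference curves (exchangeable under
#' the null of no day-type effect within subject).
#'
#' @param weekday,weekend `n x 288` matrices, rows paired by subject (equal
#'   rownames when present).
#' @param n_sim number of sign-flip simulations (>= 99).
#' @param seed integer seed.
#' @param basis_dim fixed spline basis dimension.
#' @param comparison label recorded in the result.
#' @return object of class `fda_lrt`.
#' @export
lrt_paired_daytype <- function(weekday, weekend, n_sim = 10000L, seed = 1L,
                               basis_dim = 15L, comparison = "") {
  if (!is.matrix(weekday)) weekday <- as.matrix(weekday)
  if (!is.matrix(weekend)) weekend <- as.matrix(weekend)
  if (n_sim < 99L) stop("n_sim below 99 gives too coarse a p-value resolution")
  if (nrow(weekday) != nrow(weekend)) {
    stop("unpaired subjects: weekday and weekend matrices differ in rows")
  }
  if (!is.null(rownames(weekday)) && !is.null(rownames(weekend)) &&
      !identical(rownames(weekday), rownames(weekend))) {
    stop("unpaired subjects: row names disagree")
  }
  D <- weekend - weekday
  n <- nrow(D)
  N <- length(D)
  eng <- lrt_engine(cbind(`(Intercept)` = rep(1, n)), basis_dim)
  sumD2 <- sum(D^2)
  stat <- lrt_statistic(sumD2, engine_rss(eng, D, sumD2), N)
  # sign flips leave sum(D^2) unchanged; only the alternative RSS moves
  draws <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      Ds <- D * sample(c(-1, 1), n, replace = TRUE)
      lrt_statistic(sumD2, engine_rss(eng, Ds, sumD2), N)
    }, numeric(1))
  })
  structure(list(statistic = stat, null_draws = draws,
                 p_value = (1 + sum(draws >= stat)) / (n_sim + 1),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 comparison = comparison,
                 covariate_setting = "none (paired)",
                 groups = c("weekday", "weekend"), method = "sign-flip"),
            class = "fda_lrt")
}

#' @export
print.fda_lrt <- function(x, ...) {
  cat("Functional mean-equality likelihood-ratio test (", x$method, " null)\n",
      sep = "")
  if (nzchar(x$comparison)) cat("  comparison:", x$comparison, "\n")
  cat(sprintf("  covariates: %s\n",
              if (nzchar(x$covariate_setting)) x$covariate_setting else "none"))
  cat(sprintf("  Lambda = %.3f, p = %.4g (%d simulations)\n",
              x$statistic, x$p_value, x$n_sim))
  invisible(x)
}

# ---- Anderson-Darling distribution tests -----------------------------------

# rank-form two-sample AD statistic given the sorted pooled membership vector
# of sample 1. Uses the identity that sample 2's summand equals sample 1's,
# giving A^2 = (1/N)(1/n1 + 1/n2) * sum_j (N M_1j - j n1)^2 / (j (N - j)).
ad_statistic_sorted <- function(lab1_sorted, n1, n2) {
  N <- n1 + n2
  j <- seq_len(N - 1L)
  M1 <- cumsum(lab1_sorted)[j]
  sum((N * M1 - j * n1)^2 / (j * (N - j))) * (1 / n1 + 1 / n2) / N
}

#' Two-sample Anderson-Darling test with a permutation null
#'
#' Rank-based test of whether two real samples come from one distribution,
#' weighted toward the tails. The statistic is
#' `A^2 = (1/N) sum_i (1/n_i) sum_{j=1}^{N-1} (N M_ij - j n_i)^2 / (j(N-j))`
#' with `M_ij` the count of sample `i` among the `j` smallest pooled values.
#' The p-value is by random permutation of the pooled labels, or exact
#' enumeration of all label assignments when `exact = TRUE` (small samples).
#' Ties are broken by adding seeded uniform jitter of `1e-9` times the data
#' range (scores from continuous curves are tie-free in practice).
#'
#' @param x,y numeric samples (non-empty).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param exact enumerate all `choose(n1+n2, n1)` assignments instead of
#'   sampling (error if more than 500000).
#' @return object of class `fda_adtest` with `statistic` (A^2) and `p_value`.
#' @export
ad_two_sample <- function(x, y, n_perm = 999L, seed = 1L, exact = FALSE) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  if (anyDuplicated(pooled)) {
    rng <- diff(range(pooled))
    if (rng == 0) rng <- 1
    pooled <- with_seed(seed, pooled + stats::runif(n1 + n2, -1, 1) * 1e-9 * rng)
  }
  lab <- c(rep(TRUE, n1), rep(FALSE, n2))[order(pooled)]
  obs <- ad_statistic_sorted(lab, n1, n2)
  N <- n1 + n2
  if (exact) {
    if (choose(N, n1) > 5e5) stop("too many assignments for exact enumeration")
    sets <- utils::combn(N, n1)
    stats_all <- apply(sets, 2, function(pos) {
      l <- rep(FALSE, N)
      l[pos] <- TRUE
      ad_statistic_sorted(l, n1, n2)
    })
    p <- mean(stats_all >= obs - 1e-12)
    method <- "exact enumeration"
    n_perm <- ncol(sets)
  } else {
    stats_all <- with_seed(seed, {
      vapply(seq_len(n_perm), function(s) {
        ad_statistic_sorted(sample(lab), n1, n2)
      }, numeric(1))
    })
    p <- (1 + sum(stats_all >= obs - 1e-12)) / (n_perm + 1)
    method <- "random permutation"
  }
  structure(list(statistic = obs, p_value = p, n_perm = as.integer(n_perm),
                 n1 = n1, n2 = n2, method = method, seed = as.integer(seed)),
            class = "fda_adtest")
}

#' @export
print.fda_adtest <- function(x, ...) {
  cat(sprintf("Two-sample Anderson-Darling test (%s, %d vs %d)\n",
              x$method, x$n1, x$n2))
  cat(sprintf("  A^2 = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Projection-based two-sample test for equality of curve distributions
#'
#' Tests whether two samples of curves share one population distribution:
#' FPCA is run on the pooled sample (removing the common mean), the smallest
#' number of components explaining at least `var_threshold` of the variance
#' is kept, and the two groups' score distributions are compared per
#' component with the permutation Anderson-Darling test. Per-component
#' p-values are Bonferroni-corrected (`alpha / K`); the overall p-value is
#' the Bonferroni min-p combination `min(K * min_k p_k, 1)`.
#'
#' @param curves_a,curves_b matrices of curves (>= 3 rows each).
#' @param var_threshold cumulative variance fraction selecting K.
#' @param k_max upper cap on K (default 10): with near-white residual
#'   variation the variance threshold alone can demand dozens of noise
#'   components, which dilutes power without adding information about the
#'   distributional difference.
#' @param n_perm permutations per component.
#' @param seed integer seed (per-component seeds are derived from it).
#' @param alpha family significance level (default 0.05).
#' @return object of class `fda_disttest`: per-component table, `K`,
#'   `bonferroni_alpha`, `overall_p`, `decision`.
#' @export
distribution_test <- function(curves_a, curves_b, var_threshold = 0.95,
                              k_max = 10L, n_perm = 999L, seed = 1L,
                              alpha = 0.05) {
  if (!is.matrix(curves_a)) curves_a <- as.matrix(curves_a)
  if (!is.matrix(curves_b)) curves_b <- as.matrix(curves_b)
  if (nrow(curves_a) < 3L || nrow(curves_b) < 3L) {
    stop("both samples need at least 3 curves")
  }
  pooled <- rbind(curves_a, curves_b)
  fit <- fpca(pooled, k = var_threshold)
  K <- min(length(fit$lambda), k_max)
  if (K < 1L || fit$total_var <= 0) stop("degenerate pooled covariance (K = 0)")
  na <- nrow(curves_a)
  per <- lapply(seq_len(K), function(k) {
    ad <- ad_two_sample(fit$scores[seq_len(na), k],
                        fit$scores[-seq_len(na), k],
                        n_perm = n_perm, seed = seed + k)
    data.frame(component = k, A2 = ad$statistic, p_value = ad$p_value)
  })
  tab <- do.call(rbind, per)
  overall <- min(K * min(tab$p_value), 1)
  structure(list(n_components = K, table = tab, k_max = as.integer(k_max),
                 bonferroni_alpha = alpha / K, alpha = alpha,
                 overall_p = overall,
                 decision = if (overall <= alpha) "reject" else "retain",
                 var_threshold = var_threshold, fpca = fit,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "fda_disttest")
}

#' @export
print.fda_disttest <- function(x, ...) {
  cat(sprintf("Projection Anderson-Darling distribution test (%d components, %.0f%% variance)\n",
              x$n_components, 100 * x$var_threshold))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("  Bonferroni alpha = %.4g; overall p = %.4g -> %s\n",
              x$bonferroni_alpha, x$overall_p, x$decision))
  invisible(x)
}
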