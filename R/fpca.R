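#' Functional principal components analysis of daily curves
#'
#' Decomposes a sample of complete daily curves `Y_i(t)` on the common
#' 288-point grid as `Y_i(t) = mu(t) + sum_k phi_k(t) xi_ik + eps`, where the
#' eigenfunctions `phi_k` are orthonormal under the quadrature inner product
#' (weight `grid_weight()` per point) and the eigenvalues `lambda_k` are
#' non-increasing. The covariance is the empirical (unsmoothed) sample
#' covariance: curves here are dense and complete, so no pre-smoothing is
#' applied (see the methods vignette). Scores are quadrature inner products
#' of the centered curves with the eigenfunctions.
#'
#' Eigenfunction sign is fixed reproducibly: the integral of `phi_k` over the
#' morning window 5-9 h is made non-negative, with the sign of the first grid
#' point as tie-break.
#'
#' @param curves numeric `n x 288` matrix, one curve per row (`n >= 3`).
#' @param k number of components to keep: a positive integer, or a fraction
#'   in (0, 1) interpreted as the minimum cumulative variance fraction
#'   (default 0.95).
#' @param weight quadrature weight per grid point; default `24/ncol(curves)`
#'   ([grid_weight()] on the standard 288-point grid).
#' @param grid grid point locations in hours; defaults to [time_grid()] for
#'   288-column input, equally spaced midpoints on `[0, 24)` otherwise.
#' @return an object of class `fpca`: list with `mu` (288), `phi`
#'   (`288 x K`), `lambda` (K, units curve-variance x hours), `scores`
#'   (`n x K`), `var_explained` (K fractions of the total covariance trace),
#'   `resid_var` (total integrated variance not captured by the K
#'   components), `total_var`, `grid`, `weight`, `n`.
#' @examples
#' set.seed(1)
#' t <- time_grid()
#' mu <- sin(2 * pi * t / 24)
#' curves <- t(replicate(20, mu + rnorm(1) * cos(2 * pi * t / 24)))
#' fit <- fpca(curves, k = 1)
#' fit$var_explained[1]  # ~1: rank-1 structure
#' @export
fpca <- function(curves, k = 0.95, weight = NULL, grid = NULL) {
  if (!is.matrix(curves)) curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 3L) stop("fpca needs at least 3 curves")
  if (any(!is.finite(curves))) stop("curves must be finite and complete")
  p <- ncol(curves)
  if (is.null(weight)) weight <- 24 / p
  if (is.null(grid)) {
    grid <- if (p == N_BINS) time_grid() else (seq_len(p) - 0.5) * 24 / p
  }
  if (length(grid) != p) stop("grid length must match ncol(curves)")
  if (weight <= 0) stop("quadrature weight must be positive")

  mu <- colMeans(curves)
  Xc <- sweep(curves, 2L, mu)
  covm <- crossprod(Xc) / (n - 1)
  eg <- eigen(covm, symmetric = TRUE)
  lambda_all <- eg$values * weight
  total_var <- sum(diag(covm)) * weight

  # numerical negatives: clip if tiny relative to lambda_1, else refuse
  lam1 <- max(lambda_all[1], 0)
  neg <- lambda_all < 0
  if (any(neg)) {
    if (any(-lambda_all[neg] >= 1e-10 * max(lam1, 1e-300))) {
      stop("covariance eigen-decomposition returned a non-negligible negative eigenvalue")
    }
    lambda_all[neg] <- 0
  }

  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a positive integer or a fraction in (0, 1)")
  }
  kmax <- min(n - 1L, p)
  if (k < 1) {
    cum <- cumsum(lambda_all) / max(total_var, 1e-300)
    K <- which(cum >= k)[1]
    if (is.na(K)) K <- kmax
    K <- min(K, kmax)
  } else {
    K <- min(as.integer(k), kmax)
  }
  K <- max(K, 1L)

  phi <- eg$vectors[, seq_len(K), drop = FALSE] / sqrt(weight)
  # reproducible orientation: morning-window integral >= 0
  morning <- grid >= 5 & grid < 9
  for (j in seq_len(K)) {
    s <- sum(phi[morning, j])
    if (s < 0 || (s == 0 && phi[1, j] < 0)) phi[, j] <- -phi[, j]
  }
  scores <- Xc %*% phi * weight
  lambda <- lambda_all[seq_len(K)]
  structure(list(mu = mu, phi = phi, lambda = lambda, scores = scores,
                 var_explained = lambda / max(total_var, 1e-300),
                 resid_var = total_var - sum(lambda),
                 total_var = total_var,
                 grid = grid, weight = weight, n = n),
            class = "fpca")
}

#' @export
print.fpca <- function(x, ...) {
  cat(sprintf("Functional PCA: %d curves, %d components\n", x$n,
              length(x$lambda)))
  cat(sprintf("  variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.2f%%", 100 * x$var_explained), collapse = ", "),
              100 * sum(x$var_explained)))
  invisible(x)
}

#' @export
summary.fpca <- function(object, ...) {
  tab <- data.frame(component = seq_along(object$lambda),
                    eigenvalue = object$lambda,
                    var_explained = object$var_explained,
                    cum_var_explained = cumsum(object$var_explained))
  structure(list(table = tab, n = object$n, resid_var = object$resid_var),
            class = "summary.fpca")
}

#' @export
print.summary.fpca <- function(x, ...) {
  cat(sprintf("Functional PCA of %d curves\n", x$n))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("residual (uncaptured) integrated variance: %.4g\n",
              x$resid_var))
  invisible(x)
}

#' Reconstructed curves from an FPCA fit
#'
#' `mu + sum_k xi_ik phi_k`, the rank-K reconstruction of each curve.
#'
#' @param object an `fpca` fit.
#' @param ... unused.
#' @return `n x 288` matrix.
#' @export
fitted.fpca <- function(object, ...) {
  sweep(object$scores %*% t(object$phi), 2L, object$mu, `+`)
}

#' Modes of variation of an FPCA component
#'
#' The curve pair `mu(t) +/- 2 sqrt(lambda_k) phi_k(t)` used to visualise the
#' effect of component `k` around the mean.
#'
#' @param object an `fpca` fit.
#' @param k component index.
#' @return list with `plus` and `minus` curves (length 288).
#' @export
modes_of_variation <- function(object, k) {
  stopifnot(inherits(object, "fpca"))
  if (k < 1 || k > length(object$lambda)) {
    stop("component index out of range 1..", length(object$lambda))
  }
  off <- 2 * sqrt(object$lambda[k]) * object$phi[, k]
  list(plus = object$mu + off, minus = object$mu - off)
}

#' Plot an FPCA fit
#'
#' One panel per component showing the mean and its modes of variation.
#'
#' @param x an `fpca` fit.
#' @param components which components to draw (default all).
#' @param ... passed to `matplot`.
#' @export
plot.fpca <- function(x, components = seq_along(x$lambda), ...) {
  old <- graphics::par(mfrow = c(1, length(components)))
  on.exit(graphics::par(old))
  for (k in components) {
    m <- modes_of_variation(x, k)
    graphics::matplot(x$grid, cbind(x$mu, m$plus, m$minus), type = "l",
                      lty = c(1, 2, 3), col = c("black", "red", "blue"),
                      xlab = "hour of day", ylab = "curve",
                      main = sprintf("FPC%d (%.1f%%)", k,
                                     100 * x$var_explained[k]), ...)
  }
  invisible(x)
}

#' Correlation of subject scores across two FPCA fits
#'
#' Pearson correlation between the component-`k` scores of the same subjects
#' under two fits (e.g. weekend vs weekday curves). Subjects must be in the
#' same order in both fits.
#'
#' @param scores_a,scores_b `n x K` score matrices or `fpca` objects.
#' @param k component index.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
score_correlation <- function(scores_a, scores_b, k = 1L) {
  if (inherits(scores_a, "fpca")) scores_a <- scores_a$scores
  if (inherits(scores_b, "fpca")) scores_b <- scores_b$scores
  if (nrow(scores_a) != nrow(scores_b)) {
    stop("score matrices must describe the same subjects in the same order")
  }
  if (nrow(scores_a) < 3L) stop("need at least 3 subjects")
  if (k > ncol(scores_a) || k > ncol(scores_b)) stop("component out of range")
  a <- scores_a[, k]
  b <- scores_b[, k]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance score column: correlation undefined")
  }
  stats::cor(a, b)
}
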