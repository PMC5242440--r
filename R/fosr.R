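# ---- penalized-spline machinery ------------------------------------------

# cubic B-spline basis on [0, 24] with `dim` functions, evaluated on the grid,
# plus the difference penalty matrix of the requested order
fosr_basis <- function(basis_dim = 15L, penalty_order = 2L,
                       at = time_grid()) {
  if (basis_dim < penalty_order + 2L) {
    stop("basis_dim must be at least penalty_order + 2")
  }
  ord <- 4L  # cubic
  n_interior <- basis_dim - ord
  interior <- seq(0, 24, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  knots <- c(rep(0, ord), interior, rep(24, ord))
  B <- splines::splineDesign(knots, x = at, ord = ord)
  D <- diff(diag(basis_dim), differences = penalty_order)
  list(B = B, Pen = crossprod(D), dim = basis_dim,
       penalty_order = penalty_order)
}

# block-diagonal penalty: lambda_p * Pen per coefficient function
penalty_block <- function(Pen, lambda) {
  P <- length(lambda)
  d <- ncol(Pen)
  out <- matrix(0, P * d, P * d)
  for (p in seq_len(P)) {
    idx <- (p - 1L) * d + seq_len(d)
    out[idx, idx] <- lambda[p] * Pen
  }
  out
}

# penalized least squares for Y (n x T) = X (n x P) %*% A (P x d) %*% t(B) + E
# returns coefficient matrix A, RSS, effective df, and the pieces needed to
# re-solve cheaply
fosr_solve <- function(Y, X, basis, lambda) {
  P <- ncol(X)
  d <- basis$dim
  MG <- kronecker(crossprod(X), crossprod(basis$B))
  C <- crossprod(X, Y %*% basis$B)          # P x d
  b <- as.vector(t(C))                      # stacked theta_1..theta_P order
  A <- MG + penalty_block(basis$Pen, rep_len(lambda, P))
  theta <- tryCatch(solve(A, b), error = function(e) {
    stop("rank-deficient design or singular penalized system: ",
         conditionMessage(e))
  })
  rss <- sum(Y^2) - 2 * sum(theta * b) + drop(crossprod(theta, MG %*% theta))
  rss <- max(rss, 0)
  edf <- sum(diag(solve(A, MG)))
  coefm <- matrix(theta, nrow = P, ncol = d, byrow = TRUE)
  list(coef = coefm, rss = rss, edf = edf)
}

# per-term GCV smoothing selection by coordinate descent over a log grid
select_lambda_gcv <- function(Y, X, basis, grid = 10^seq(-3, 9, by = 1),
                              passes = 2L) {
  P <- ncol(X)
  N <- length(Y)
  lambda <- rep(1, P)
  gcv <- function(lam) {
    f <- fosr_solve(Y, X, basis, lam)
    N * f$rss / (N - f$edf)^2
  }
  for (pass in seq_len(passes)) {
    for (p in seq_len(P)) {
      scores <- vapply(grid, function(l) {
        lam <- lambda
        lam[p] <- l
        gcv(lam)
      }, numeric(1))
      lambda[p] <- grid[which.min(scores)]
    }
  }
  lambda
}

# ---- covariate standardization -------------------------------------------

#' Standardized design matrix for function-on-scalar regression
#'
#' Each main-effect covariate is centered and scaled to unit sample SD;
#' interaction columns (named `"a:b"`) are elementwise products of the two
#' standardized main effects, so coefficient functions are on the
#' "standard deviations away from the mean" scale throughout.
#'
#' @param data data.frame of raw covariates.
#' @param terms character vector of term labels, e.g.
#'   `c("age", "bcs", "age:bcs")`. An intercept column is always prepended.
#' @return list with `design` (n x (1 + length(terms)) matrix, first column
#'   `(Intercept)`) and `scaling` (data.frame of means/SDs per main effect).
#' @export
standardize_covariates <- function(data, terms) {
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(mains, names(data))
  if (length(miss)) stop("covariates not found: ", paste(miss, collapse = ", "))
  scaling <- data.frame(term = mains,
                        mean = vapply(mains, function(m) mean(data[[m]]), 0),
                        sd = vapply(mains, function(m) stats::sd(data[[m]]), 0))
  if (any(!is.finite(scaling$sd) | scaling$sd == 0)) {
    stop("zero-variance covariate: ",
         paste(scaling$term[scaling$sd == 0], collapse = ", "))
  }
  std <- lapply(mains, function(m) (data[[m]] - mean(data[[m]])) / stats::sd(data[[m]]))
  names(std) <- mains
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, std[parts])
  })
  design <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(design) <- c("(Intercept)", terms)
  list(design = design, scaling = scaling)
}

# ---- the fitting function -------------------------------------------------

#' Function-on-scalar regression with penalized-spline coefficients
#'
#' Fits `Y_i(t) = beta_0(t) + sum_p x_ip beta_p(t) + eps_i(t)` for curve
#' responses on the daily grid, with each time-varying coefficient expanded
#' in a cubic B-spline basis (`basis_dim` functions on `[0, 24]`) under a
#' difference penalty of order `penalty_order`. Estimation is penalized least
#' squares over all `n x 288` observations under a working-independence
#' Gaussian model (residuals iid with variance `sigma2`); smoothing
#' parameters are selected per term by generalized cross-validation unless
#' `lambda` is supplied. Within-curve residual dependence is handled by the
#' subject-level bootstrap of [bootstrap_ci()], not by the working likelihood.
#'
#' @param curves `n x 288` response matrix (activity or intensity profiles).
#' @param formula one-sided formula naming covariate terms, e.g.
#'   `~ age + bcs + age:bcs`; terms are standardized via
#'   [standardize_covariates()]. Supply either `formula`+`data` or `design`.
#' @param data data.frame of raw covariates (with `formula`).
#' @param design alternatively, a ready design matrix whose first column is
#'   the intercept.
#' @param basis_dim B-spline basis dimension per coefficient (default 15).
#' @param penalty_order difference-penalty order (default 2).
#' @param lambda optional fixed smoothing parameters (scalar or per term);
#'   when `NULL` (default) GCV selects them.
#' @param response,daytype optional labels recorded in the fit.
#' @return an object of class `fosr`: coefficient curves `beta`
#'   (`288 x P`, columns named by term), spline coefficients `coef`
#'   (`P x basis_dim`), `lambda`, `sigma2`, `edf`, `loglik`, the basis, the
#'   data (`X`, `Y`) for bootstrapping, and `scaling` when standardization
#'   was applied. Confidence bands are added by [bootstrap_ci()].
#' @seealso [bootstrap_ci()], [significance_regions()]
#' @export
fosr <- function(curves, formula = NULL, data = NULL, design = NULL,
                 basis_dim = 15L, penalty_order = 2L, lambda = NULL,
                 response = "activity", daytype = "") {
  if (!is.matrix(curves)) curves <- as.matrix(curves)
  if (ncol(curves) != N_BINS) stop("curves must have 288 columns")
  if (any(!is.finite(curves))) stop("curves must be finite")
  scaling <- NULL
  if (!is.null(formula)) {
    if (is.null(data)) stop("'data' is required with 'formula'")
    terms <- attr(stats::terms(formula), "term.labels")
    sc <- standardize_covariates(data, terms)
    design <- sc$design
    scaling <- sc$scaling
  }
  if (is.null(design)) {
    design <- matrix(1, nrow(curves), 1L,
                     dimnames = list(NULL, "(Intercept)"))
  }
  design <- as.matrix(design)
  if (nrow(design) != nrow(curves)) stop("design/curves row mismatch")
  if (nrow(curves) <= ncol(design)) stop("need n > number of terms")
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design")

  basis <- fosr_basis(basis_dim, penalty_order)
  Yvec_n <- length(curves)
  if (is.null(lambda)) {
    lambda <- select_lambda_gcv(curves, design, basis)
    lambda_method <- "GCV"
  } else {
    lambda <- rep_len(lambda, ncol(design))
    lambda_method <- "fixed"
  }
  fitres <- fosr_solve(curves, design, basis, lambda)
  beta <- basis$B %*% t(fitres$coef)   # 288 x P
  colnames(beta) <- colnames(design)
  sigma2 <- fitres$rss / (Yvec_n - fitres$edf)
  s2ml <- fitres$rss / Yvec_n
  loglik <- -Yvec_n / 2 * (log(2 * pi * max(s2ml, 1e-300)) + 1)
  structure(list(beta = beta, coef = fitres$coef, lambda = lambda,
                 lambda_method = lambda_method, sigma2 = sigma2,
                 edf = fitres$edf, rss = fitres$rss, loglik = loglik,
                 basis = basis, X = design, Y = curves, scaling = scaling,
                 terms = colnames(design), response = response,
                 daytype = daytype, grid = time_grid(),
                 ci_lower = NULL, ci_upper = NULL, n_boot = 0L),
            class = "fosr")
}

#' @export
print.fosr <- function(x, ...) {
  cat(sprintf("Function-on-scalar regression (%s%s): %d curves, terms: %s\n",
              x$response, if (nzchar(x$daytype)) paste0(", ", x$daytype) else "",
              nrow(x$Y), paste(x$terms, collapse = ", ")))
  cat(sprintf("  basis dim %d, penalty order %d, smoothing (%s): %s\n",
              x$basis$dim, x$basis$penalty_order, x$lambda_method,
              paste(signif(x$lambda, 2), collapse = ", ")))
  cat(sprintf("  sigma^2 = %.4g, edf = %.1f, working loglik = %.1f\n",
              x$sigma2, x$edf, x$loglik))
  if (x$n_boot > 0L) {
    cat(sprintf("  95%% pointwise bootstrap CIs from %d resamples\n", x$n_boot))
  }
  invisible(x)
}

#' @export
coef.fosr <- function(object, ...) object$beta

#' @export
fitted.fosr <- function(object, ...) {
  object$X %*% object$coef %*% t(object$basis$B)
}

#' @export
residuals.fosr <- function(object, ...) object$Y - fitted(object)

#' Predict mean curves for new covariate values
#'
#' @param object a fitted `fosr` (fit with `formula` + `data`, so the
#'   standardization record is available, or with a raw `design`).
#' @param newdata data.frame of raw covariates (formula fits) or a design
#'   matrix (design fits).
#' @param ... unused.
#' @return matrix of predicted curves, one row per new subject.
#' @export
predict.fosr <- function(object, newdata, ...) {
  if (!is.null(object$scaling)) {
    std <- list()
    for (i in seq_len(nrow(object$scaling))) {
      m <- object$scaling$term[i]
      std[[m]] <- (newdata[[m]] - object$scaling$mean[i]) / object$scaling$sd[i]
    }
    cols <- lapply(object$terms[-1], function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      Reduce(`*`, std[parts])
    })
    X <- cbind(1, do.call(cbind, cols))
  } else {
    X <- as.matrix(newdata)
  }
  X %*% object$coef %*% t(object$basis$B)
}

#' Subject-level bootstrap confidence bands
#'
#' Resamples whole subjects (curve + covariates) with replacement and refits
#' the model with the smoothing parameters held at their values from the
#' original fit; pointwise 2.5% and 97.5% percentiles of the resampled
#' coefficient curves form 95% bands. Deterministic given `seed`.
#'
#' @param fit a `fosr` object.
#' @param n_boot number of bootstrap resamples (>= 50; 2000 for
#'   publication-scale bands).
#' @param seed integer seed.
#' @return the fit, with `ci_lower`/`ci_upper` (288 x P) and `n_boot` filled.
#' @export
bootstrap_ci <- function(fit, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(fit, "fosr"))
  if (n_boot < 50L) stop("n_boot must be at least 50")
  n <- nrow(fit$Y)
  P <- length(fit$terms)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- array(NA_real_, c(N_BINS, P, n_boot))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      fosr_solve(fit$Y[idx, , drop = FALSE], fit$X[idx, , drop = FALSE],
                 fit$basis, fit$lambda),
      error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    draws[, , b] <- fit$basis$B %*% t(res$coef)
  }
  if (failures > 0.05 * n_boot) {
    stop(sprintf("bootstrap refit failure rate %.1f%% exceeds 5%%",
                 100 * failures / n_boot))
  }
  qs <- apply(draws, c(1, 2), stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  fit$ci_lower <- matrix(qs[1, , ], N_BINS, P,
                         dimnames = list(NULL, fit$terms))
  fit$ci_upper <- matrix(qs[2, , ], N_BINS, P,
                         dimnames = list(NULL, fit$terms))
  fit$n_boot <- as.integer(n_boot - failures)
  fit$boot_seed <- as.integer(seed)
  fit
}

#' Time intervals where a coefficient function is significant
#'
#' Maximal runs of consecutive grid points where the 95% pointwise band lies
#' entirely above or entirely below zero.
#'
#' @param fit a `fosr` with bootstrap bands (see [bootstrap_ci()]).
#' @param term term name (one of `fit$terms`).
#' @return data.frame `term, start_hour, end_hour, sign` (possibly 0 rows);
#'   hours are bin midpoints of the first and last significant bin.
#' @export
significance_regions <- function(fit, term) {
  stopifnot(inherits(fit, "fosr"))
  if (is.null(fit$ci_lower)) stop("fit has no bootstrap bands; run bootstrap_ci()")
  if (!term %in% fit$terms) stop("unknown term: ", term)
  lo <- fit$ci_lower[, term]
  hi <- fit$ci_upper[, term]
  sig <- ifelse(lo > 0, 1L, ifelse(hi < 0, -1L, 0L))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  t <- fit$grid
  out <- data.frame(term = character(0), start_hour = numeric(0),
                    end_hour = numeric(0), sign = integer(0))
  if (any(keep)) {
    out <- data.frame(term = term, start_hour = t[starts[keep]],
                      end_hour = t[ends[keep]], sign = r$values[keep])
  }
  out
}

#' Plot estimated coefficient functions
#'
#' One panel per term: the coefficient curve, zero line, and (when present)
#' the 95% pointwise bootstrap band.
#'
#' @param x a `fosr` fit.
#' @param terms which terms to draw (default all).
#' @param ... passed to `plot`.
#' @export
plot.fosr <- function(x, terms = x$terms, ...) {
  old <- graphics::par(mfrow = c(1, length(terms)))
  on.exit(graphics::par(old))
  for (tm in terms) {
    b <- x$beta[, tm]
    ylim <- range(b, x$ci_lower[, tm], x$ci_upper[, tm], 0, na.rm = TRUE)
    plot(x$grid, b, type = "l", ylim = ylim, xlab = "hour of day",
         ylab = "coefficient", main = tm, ...)
    graphics::abline(h = 0, col = "red")
    if (!is.null(x$ci_lower)) {
      graphics::lines(x$grid, x$ci_lower[, tm], col = "blue", lty = 2)
      graphics::lines(x$grid, x$ci_upper[, tm], col = "blue", lty = 2)
    }
  }
  invisible(x)
}
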