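test_that("covariate standardization has the closed-form fixed points", {
  d <- data.frame(age = c(4, 6, 8), bcs = c(5, 5, 5), tpain = c(1, 2, 6))
  sc <- standardize_covariates(d, c("age", "tpain"))
  expect_equal(unname(sc$design[, "age"]), c(-1, 0, 1))
  expect_equal(unname(sc$design[, "(Intercept)"]), rep(1, 3))
  expect_error(standardize_covariates(d, c("age", "bcs")), "zero-variance")
  # interaction column is the product of the standardized mains
  d2 <- data.frame(age = c(2, 5, 9, 11), bcs = c(3, 7, 4, 6))
  sc2 <- standardize_covariates(d2, c("age", "bcs", "age:bcs"))
  expect_equal(sc2$design[, "age:bcs"], sc2$design[, "age"] * sc2$design[, "bcs"])
  expect_error(standardize_covariates(d2, "weight"), "not found")
})

test_that("exactly-representable coefficients are recovered at zero smoothing", {
  set.seed(20)
  basis <- actifda:::fosr_basis(15, 2)
  theta <- matrix(rnorm(2 * 15), 2)
  X <- cbind(1, rnorm(40))
  Y <- X %*% theta %*% t(basis$B)           # zero noise, spline-representable
  fit <- fosr(Y, design = X, lambda = 0)
  expect_lt(max(abs(fit$beta - basis$B %*% t(theta))), 1e-6)
})

test_that("a planted sinusoidal age effect is recovered under noise", {
  set.seed(21)
  n <- 150
  t <- time_grid()
  beta_age <- sin(2 * pi * t / 24)
  age <- rnorm(n)
  Y <- outer(rep(1, n), 3 + 0.5 * cos(2 * pi * t / 24)) +
    outer(age, beta_age) + matrix(rnorm(n * 288, 0, 0.5), n)
  fit <- fosr(Y, design = cbind(`(Intercept)` = 1, age = age))
  expect_gt(cor(fit$beta[, "age"], beta_age), 0.9)
})

test_that("null coefficients stay near zero and scale linearly", {
  set.seed(22)
  n <- 150
  x <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n))
  Y <- outer(rep(1, n), 3 + sin(2 * pi * time_grid() / 24)) +
    matrix(rnorm(n * 288, 0, 0.5), n)
  fit <- fosr(Y, design = x)
  expect_lt(max(abs(fit$beta[, "a"])), 0.2)
  expect_lt(max(abs(fit$beta[, "b"])), 0.2)
  # linearity at fixed smoothing: scaling the curves scales every beta
  f1 <- fosr(Y, design = x, lambda = fit$lambda)
  f2 <- fosr(3 * Y, design = x, lambda = fit$lambda)
  expect_equal(f2$beta, 3 * f1$beta, tolerance = 1e-10)
})

test_that("adding a term never decreases the working log-likelihood", {
  set.seed(23)
  n <- 40
  x <- cbind(1, rnorm(n), rnorm(n))
  Y <- outer(x[, 2], sin(2 * pi * time_grid() / 24)) +
    matrix(rnorm(n * 288, 0, 0.3), n)
  small <- fosr(Y, design = x[, 1:2], lambda = 0)
  big <- fosr(Y, design = x, lambda = 0)
  expect_gte(big$loglik, small$loglik)
})

test_that("fosr validates its inputs", {
  Y <- matrix(rnorm(10 * 288), 10)
  expect_error(fosr(Y[, 1:100]), "288")
  x <- cbind(1, rep(2, 10))  # collinear with intercept after join
  expect_error(fosr(Y, design = cbind(x, x)), "rank-deficient")
  expect_error(fosr(Y, formula = ~ age), "'data' is required")
  expect_error(fosr(matrix(rnorm(3 * 288), 3),
                    design = cbind(1, rnorm(3), rnorm(3), rnorm(3))),
               "n > number of terms")
})

test_that("bootstrap bands are deterministic, centered and scale with n", {
  set.seed(24)
  n <- 60
  age <- rnorm(n)
  Y <- outer(rep(1, n), 2 + cos(2 * pi * time_grid() / 24)) +
    matrix(rnorm(n * 288, 0, 0.4), n)
  fit <- fosr(Y, design = cbind(`(Intercept)` = 1, age = age))
  b1 <- bootstrap_ci(fit, n_boot = 50, seed = 9)
  b2 <- bootstrap_ci(fit, n_boot = 50, seed = 9)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_true(all(b1$ci_lower <= fit$beta + 1e-10))
  expect_true(all(b1$ci_upper >= fit$beta - 1e-10))

  # the null age term is covered by its band at >= 80% of grid points
  covered <- mean(b1$ci_lower[, "age"] <= 0 & b1$ci_upper[, "age"] >= 0)
  expect_gte(covered, 0.8)

  # duplicating every subject shrinks the half-width by about 1/sqrt(2)
  fit2 <- fosr(rbind(Y, Y),
               design = rbind(cbind(1, age), cbind(1, age)),
               lambda = fit$lambda)
  b3 <- bootstrap_ci(fit2, n_boot = 400, seed = 10)
  b1b <- bootstrap_ci(fit, n_boot = 400, seed = 10)
  ratio <- mean(b3$ci_upper[, 2] - b3$ci_lower[, 2]) /
    mean(b1b$ci_upper[, 2] - b1b$ci_lower[, 2])
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.2 / sqrt(2))
  expect_error(bootstrap_ci(fit, n_boot = 10), "at least 50")
})

test_that("significance regions are the maximal sign-consistent runs", {
  set.seed(25)
  n <- 50
  Y <- matrix(rnorm(n * 288, 0, 0.1), n)
  fit <- fosr(Y, design = cbind(`(Intercept)` = 1, x = rnorm(n)), lambda = 1)
  fit$ci_lower <- matrix(0.1, 288, 2, dimnames = list(NULL, fit$terms))
  fit$ci_upper <- matrix(0.5, 288, 2, dimnames = list(NULL, fit$terms))
  r <- significance_regions(fit, "x")
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_hour, time_grid()[1])
  expect_equal(r$end_hour, time_grid()[288])

  fit$ci_lower[] <- -0.1
  expect_equal(nrow(significance_regions(fit, "x")), 0L)
  expect_error(significance_regions(fit, "z"), "unknown term")

  # a strong effect confined to the 6-9 h window is localized there
  t <- time_grid()
  beta <- ifelse(t >= 6 & t <= 9, 1.5 * sin(pi * (t - 6) / 3), 0)
  x <- rnorm(n)
  Y2 <- outer(x, beta) + matrix(rnorm(n * 288, 0, 0.3), n)
  f2 <- fosr(Y2, design = cbind(`(Intercept)` = 1, x = x))
  f2 <- bootstrap_ci(f2, n_boot = 100, seed = 3)
  r2 <- significance_regions(f2, "x")
  expect_gt(nrow(r2), 0)
  expect_true(any(r2$start_hour < 9 & r2$end_hour > 6 & r2$sign == 1))
})

test_that("formula interface, prediction and residuals are coherent", {
  co <- small_cohort(n_normal = 0, n_djd = 25, seed = 31)
  prep <- preprocess_cohort(co$epochs)
  Y <- actifda:::profile_matrix(prep$profiles, "activity", "weekday")
  cv <- co$covariates[match(rownames(Y), co$covariates$cat_id), ]
  fit <- fosr(Y, ~ age + bcs + age:bcs, cv, response = "activity",
              daytype = "weekday")
  expect_identical(fit$terms, c("(Intercept)", "age", "bcs", "age:bcs"))
  expect_equal(dim(coef(fit)), c(288L, 4L))
  expect_equal(fitted(fit) + residuals(fit), unname(Y), ignore_attr = TRUE)
  pr <- predict(fit, cv[1:2, ])
  expect_equal(unname(pr), unname(fitted(fit)[1:2, ]))
  expect_output(print(fit), "Function-on-scalar")
})
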