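test_that("the mean-equality statistic is non-negative on arbitrary data", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 16
    Y <- matrix(rnorm(n * 288), n) +
      outer(rnorm(n), sin(2 * pi * time_grid() / 24))
    g <- rep(c("a", "b"), each = n / 2)
    covs <- cbind(x = rnorm(n))
    lr <- lrt_mean_equality(Y, g, covs, n_sim = 99, seed = seed)
    expect_gte(lr$statistic, 0)
    expect_true(all(lr$null_draws >= 0))
    expect_gt(lr$p_value, 0)
    expect_lte(lr$p_value, 1)
    # p-values live on the permutation grid (1+m)/(n_sim+1)
    expect_equal((lr$p_value * 100) %% 1, 0)
  }
})

test_that("mean tests are deterministic given a seed and validate inputs", {
  set.seed(30)
  Y <- matrix(rnorm(20 * 288), 20)
  g <- rep(c("a", "b"), 10)
  l1 <- lrt_mean_equality(Y, g, n_sim = 99, seed = 5)
  l2 <- lrt_mean_equality(Y, g, n_sim = 99, seed = 5)
  expect_identical(l1$null_draws, l2$null_draws)
  expect_identical(l1$p_value, l2$p_value)
  expect_error(lrt_mean_equality(Y, g, n_sim = 50), "n_sim")
  expect_error(lrt_mean_equality(Y, rep("a", 20), n_sim = 99), "two levels")
})

test_that("a strong planted mean difference is detected", {
  set.seed(31)
  t <- time_grid()
  mu <- 3 + sin(2 * pi * t / 24)
  bump <- 0.6 * exp(-(t - 7)^2 / 2)
  A <- outer(rep(1, 15), mu) + matrix(rnorm(15 * 288, 0, 0.3), 15)
  B <- outer(rep(1, 15), mu + bump) + matrix(rnorm(15 * 288, 0, 0.3), 15)
  lr <- lrt_mean_equality(rbind(A, B), rep(c("a", "b"), each = 15),
                          n_sim = 199, seed = 6)
  expect_lte(lr$p_value, 0.05)
})

test_that("paired day-type test handles identity, pairing and signal", {
  set.seed(32)
  W <- matrix(rnorm(12 * 288), 12,
              dimnames = list(paste0("c", 1:12), NULL))
  # identical pairs: Lambda = 0, p = 1
  t0 <- lrt_paired_daytype(W, W, n_sim = 99, seed = 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # mismatched subjects refuse to pair
  expect_error(lrt_paired_daytype(W[1:10, ], W[1:8, ], n_sim = 99), "unpaired")
  W2 <- W
  rownames(W2) <- paste0("d", 1:12)
  expect_error(lrt_paired_daytype(W, W2, n_sim = 99), "unpaired")
  # a common shift on every subject is detected
  shift <- outer(rep(1, 12), 0.5 * sin(2 * pi * time_grid() / 24))
  t1 <- lrt_paired_daytype(W, W + shift + matrix(rnorm(12 * 288, 0, 0.2), 12),
                           n_sim = 199, seed = 2)
  expect_lte(t1$p_value, 0.05)
})

test_that("the AD statistic matches hand evaluation and the naive oracle", {
  expect_equal(ad_two_sample(0, 1, n_perm = 99)$statistic, 1)
  set.seed(33)
  for (rep in 1:5) {
    x <- rnorm(6)
    y <- rnorm(9)
    expect_equal(ad_two_sample(x, y, n_perm = 99)$statistic, ad_oracle(x, y))
  }
})

test_that("exact AD p-values equal full enumeration by an independent oracle", {
  set.seed(34)
  x <- rnorm(5)
  y <- rnorm(5) + 1
  res <- ad_two_sample(x, y, exact = TRUE)
  expect_equal(res$n_perm, 252L)
  # brute-force enumeration with the naive statistic
  pooled <- c(x, y)
  sets <- combn(10, 5)
  stats_all <- apply(sets, 2, function(idx) {
    ad_oracle(pooled[idx], pooled[-idx])
  })
  expect_equal(res$p_value, mean(stats_all >= res$statistic - 1e-12))
})

test_that("the AD test is invariant under strictly monotone transforms", {
  set.seed(35)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  a <- ad_two_sample(x, y, n_perm = 199, seed = 7)
  b <- ad_two_sample(exp(x), exp(y), n_perm = 199, seed = 7)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("distribution test retains on identical samples and validates", {
  set.seed(36)
  sim <- sim_rank_curves(20, lambda = c(2, 1), noise_sd = 0.05)
  d <- distribution_test(sim$curves, sim$curves, n_perm = 199, seed = 4)
  expect_identical(d$decision, "retain")
  expect_equal(d$bonferroni_alpha, 0.05 / d$n_components)
  expect_equal(d$overall_p, min(d$n_components * min(d$table$p_value), 1))
  expect_error(distribution_test(sim$curves[1:2, ], sim$curves), "at least 3")
  expect_error(ad_two_sample(numeric(0), 1), "non-empty")
})
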