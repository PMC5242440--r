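test_that("templates are bimodal with the configured peak geometry", {
  cfg <- generator_config()
  t <- time_grid()
  wd <- bimodal_template("Normal", "weekday", cfg)
  we <- bimodal_template("Normal", "weekend", cfg)

  # morning argmax of the first half-day in the 5:30-9:00 window
  half <- t < 12
  expect_gte(t[half][which.max(wd[half])], 5.5)
  expect_lte(t[half][which.max(wd[half])], 9.0)
  # overnight trough between 02:00 and 05:00
  trough_t <- t[which.min(wd)]
  expect_gte(trough_t, 2)
  expect_lte(trough_t, 5)
  # evening local maximum in the configured window
  evening <- t >= 17 & t <= 23
  expect_gt(max(wd[evening]), max(wd[t >= 12 & t < 17]))

  # weekend morning peak strictly later than weekday
  expect_gt(t[half][which.max(we[half])], t[half][which.max(wd[half])])

  # DJD muting: smaller excursion when attenuation < 1, identity when = 1
  djd <- bimodal_template("DJD", "weekday", cfg)
  expect_lt(diff(range(djd)), diff(range(wd)))
  cfg1 <- generator_config(djd_attenuation = 1)
  expect_equal(bimodal_template("DJD", "weekday", cfg1),
               bimodal_template("Normal", "weekday", cfg1))

  expect_error(bimodal_template("Feral", "weekday", cfg), "unknown group")
  expect_error(bimodal_template("Normal", "holiday", cfg), "unknown daytype")
})

test_that("count conversion inverts the log scale exactly and in median", {
  set.seed(1)
  expect_identical(curve_to_counts(rep(0, 1440), 0), rep(0L, 1440))
  expect_identical(curve_to_counts(rep(log1p(100), 1440), 0),
                   rep(100L, 1440))
  # lognormal noise preserves the median through the monotone inverse
  set.seed(2)
  draws <- curve_to_counts(rep(log1p(50), 1440), 0.3)
  for (i in 1:69) draws <- c(draws, curve_to_counts(rep(log1p(50), 1440), 0.3))
  expect_lt(abs(median(draws) - 50), 2)
  expect_error(curve_to_counts(c(Inf, rep(0, 1439))), "finite")
})

test_that("generation is deterministic and structurally complete", {
  cfg <- generator_config(seed = 21, n_per_group = c(Normal = 3, DJD = 3),
                          noise_sd = 0.6)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_epoch_csv(co1$epochs, f1)
  write_epoch_csv(co2$epochs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(co1$covariates, co2$covariates)

  # every subject has n_days complete days of non-negative integer counts
  ids <- vapply(co1$epochs, function(s) s$cat_id, "")
  expect_true(all(table(ids) == cfg$n_days))
  expect_true(all(vapply(co1$epochs, function(s) {
    length(s$counts) == 1440 && all(s$counts >= 0)
  }, logical(1))))

  # covariates within plausible published ranges, group-dependent ages
  cv <- co1$covariates
  expect_true(all(cv$age > 1))
  expect_true(all(cv$bcs %in% 1:9))
  expect_true(all(cv$tpain >= 0 & cv$tpain <= 80))
  expect_true(all(cv$tdjd >= 0 & cv$tdjd <= 200))

  # planted eigenfunctions orthonormal under the quadrature inner product
  phi <- co1$truth$eigenfunctions
  gram <- crossprod(phi) * grid_weight()
  expect_lt(max(abs(gram - diag(ncol(phi)))), 1e-10)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_per_group = c(Feline = 5)), "n_per_group")
  expect_error(generator_config(eigen_spec = list(values = c(1, -2))),
               "non-negative")
  expect_error(generator_config(eigen_spec = list(values = c(1, 2))),
               "non-increasing")
  expect_error(generator_config(djd_attenuation = 0), "djd_attenuation")
  expect_error(generator_config(n_days = 8), "n_days")
  expect_error(generator_config(beta_spec = list(weight = function(t) t)),
               "beta_spec")
})

test_that("planted weekend-weekday score correlation is recovered", {
  cfg <- generator_config(seed = 33, n_per_group = c(Normal = 200, DJD = 0),
                          score_xcorr = 0.6)
  co <- generate_cohort(cfg)
  r <- cor(co$truth$scores$weekend[, 1], co$truth$scores$weekday[, 1])
  expect_lt(abs(r - 0.6), 0.1)
})

test_that("noise-free, effect-free subjects reproduce their template counts", {
  cfg <- generator_config(seed = 8, n_per_group = c(Normal = 1, DJD = 0),
                          noise_sd = 0, eigen_spec = list(values = c(0, 0, 0)))
  co <- generate_cohort(cfg)
  tpl <- co$truth$templates[["Normal.weekday"]]
  monday <- co$epochs[[1]]
  expect_identical(split_daytype(monday$date), "weekday")
  expect_identical(monday$counts,
                   as.integer(pmax(0, round(expm1(rep(tpl, each = 5))))))
})

test_that("the Normal-minus-DJD weekday contrast is muting, not a shift", {
  # group-mean difference must cross zero: positive at the peaks (Normal
  # higher) and negative in the trough (Normal lower)
  for (seed in 1:100) {
    cfg <- generator_config(seed = seed,
                            n_per_group = c(Normal = 12, DJD = 12),
                            noise_sd = 0.4)
    co <- generate_cohort(cfg)
    prep <- preprocess_cohort(co$epochs)
    groups <- co$covariates$group[match(names(prep$profiles),
                                        co$covariates$cat_id)]
    wd <- actifda:::profile_matrix(prep$profiles, "activity", "weekday")
    diffc <- colMeans(wd[groups == "Normal", ]) - colMeans(wd[groups == "DJD", ])
    expect_gt(max(diffc), 0)
    expect_lt(min(diffc), 0)
  }
})
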