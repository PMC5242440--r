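test_that("log transform is ln(1+x) with the exact fixed points", {
  expect_identical(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  expect_equal(log_transform(c(0, 99)), c(0, log(100)))
  expect_true(all(diff(log_transform(0:50)) > 0))  # order-preserving
  expect_error(log_transform(-1), "non-negative")
  expect_error(log_transform(c(1, NA)), "finite")
})

test_that("5-minute binning averages left-closed minute blocks", {
  expect_equal(bin_five_minutes(rep(3.7, 1440)), rep(3.7, 288))
  # minutes labelled by index: mean of {5j..5j+4} = 5j + 2
  expect_equal(bin_five_minutes(0:1439), 5 * (0:287) + 2)
  set.seed(42)
  v <- rexp(1440)
  oracle <- vapply(0:287, function(j) mean(v[(5 * j + 1):(5 * j + 5)]),
                   numeric(1))
  expect_equal(bin_five_minutes(v), oracle)
  expect_error(bin_five_minutes(1:100), "1440")
})

test_that("the pipeline transforms before binning (the two do not commute)", {
  set.seed(7)
  counts <- rpois(1440, 30)
  expect_false(isTRUE(all.equal(bin_five_minutes(log_transform(counts)),
                                log_transform(bin_five_minutes(counts)))))
  # and the daily-curve path uses the transform-then-bin order
  s <- epoch_series("a", "2015-06-01", counts)
  expect_equal(actifda:::daily_curve(s), bin_five_minutes(log_transform(counts)))
})

test_that("day-type labels follow the Saturday/Sunday rule", {
  expect_identical(split_daytype(as.Date("2015-06-06")), "weekend")  # Sat
  expect_identical(split_daytype(as.Date("2015-06-07")), "weekend")  # Sun
  expect_identical(split_daytype(as.Date("2015-06-03")), "weekday")  # Wed
  week <- split_daytype(as.Date("2015-06-01") + 0:6)
  expect_identical(sum(week == "weekend"), 2L)
})

test_that("baseline selection drops first/last days then keeps the last 7", {
  mk <- function(dates) lapply(dates, function(d) {
    epoch_series("cat", d, rep(1L, 1440))
  })
  d0 <- as.Date("2015-06-01")
  sel <- select_baseline_days(mk(d0 + 0:14))      # 15 recorded days
  expect_equal(vapply(sel, function(s) format(s$date), ""),
               format(d0 + 7:13))
  sel9 <- select_baseline_days(mk(d0 + 0:8))      # exactly 9: the middle 7
  expect_equal(vapply(sel9, function(s) format(s$date), ""),
               format(d0 + 1:7))
  expect_error(select_baseline_days(mk(d0 + 0:7)), "cat")  # 8 days: too few
})

test_that("profiles obey the weighted intensity-mean-zero identity", {
  # constant curves: Y = c, ave = c, I = 0
  const <- matrix(2.5, 7, 288)
  dts <- c(rep("weekday", 5), rep("weekend", 2))
  p <- build_profile(const, dts, "c1")
  expect_equal(p$Y_weekday, rep(2.5, 288))
  expect_equal(p$ave, 2.5)
  expect_equal(p$I_weekend, rep(0, 288))

  # two-level closed form: weekday a, weekend b
  ab <- rbind(matrix(1, 5, 288), matrix(8, 2, 288))
  p2 <- build_profile(ab, dts, "c2")
  expect_equal(p2$ave, (5 * 1 + 2 * 8) / 7)
  expect_equal(p2$I_weekday, rep(1 - (5 + 16) / 7, 288))

  # random curves: (5 mean I_wd + 2 mean I_we)/7 = 0 to 1e-12
  set.seed(3)
  for (rep in 1:20) {
    r <- matrix(rexp(7 * 288), 7, 288)
    pr <- build_profile(r, dts)
    expect_lt(abs((5 * mean(pr$I_weekday) + 2 * mean(pr$I_weekend)) / 7),
              1e-12)
  }
  expect_error(build_profile(const, rep("weekday", 7)), "5 weekday")
})

test_that("noise-free synthetic subjects are recovered up to count rounding", {
  cfg <- generator_config(seed = 5, n_per_group = c(Normal = 2, DJD = 2),
                          noise_sd = 0,
                          eigen_spec = list(values = c(0, 0, 0)))
  co <- generate_cohort(cfg)
  prep <- preprocess_cohort(co$epochs)
  for (id in names(prep$profiles)) {
    g <- co$covariates$group[co$covariates$cat_id == id]
    for (dt in c("weekday", "weekend")) {
      planted <- co$truth$templates[[paste(g, dt, sep = ".")]]
      got <- prep$profiles[[id]][[paste0("Y_", dt)]]
      counts <- expm1(planted)
      # ln-scale rounding error is ~0.5/(1+count): 0.02 needs counts >= 25
      expect_lt(max(abs(got - planted)[counts >= 25]), 0.02)
      expect_lt(max(abs(got - planted)[counts >= 5]), 0.1)
    }
  }
})

test_that("group means and descriptive summaries match direct computation", {
  co <- small_cohort(n_normal = 4, n_djd = 5)
  prep <- preprocess_cohort(co$epochs)
  groups <- co$covariates$group[match(names(prep$profiles),
                                      co$covariates$cat_id)]
  gm <- group_mean_profiles(prep$profiles, groups)
  # single-subject group equals its own profile
  one <- group_mean_profiles(prep$profiles[1], groups[1])
  expect_equal(one$activity[one$daytype == "weekday"],
               prep$profiles[[1]]$Y_weekday)
  # pointwise linearity for a two-subject group
  two <- group_mean_profiles(prep$profiles[1:2], c("g", "g"))
  expect_equal(two$intensity[two$daytype == "weekend"],
               (prep$profiles[[1]]$I_weekend + prep$profiles[[2]]$I_weekend) / 2)
  expect_error(group_mean_profiles(list(), character(0)), "no profiles")

  cs <- cohort_summary(prep$mean_counts, groups)
  for (g in unique(groups)) {
    x <- prep$mean_counts[groups == g]
    row <- cs[cs$group == g, ]
    expect_equal(row$median, unname(quantile(x, 0.5, type = 7)))
    expect_equal(row$q1, unname(quantile(x, 0.25, type = 7)))
    expect_equal(row$mean, mean(x))
    expect_equal(c(row$minimum, row$maximum), range(x))
  }
  expect_equal(cohort_summary(setNames(1:5, letters[1:5]),
                              rep("g", 5))$median, 3)
})
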