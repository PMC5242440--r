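#' Log transform of activity counts
#'
#' Per-minute accelerometer counts are highly right-skewed; all analyses work
#' on the `ln(1 + x)` scale. The transform is applied BEFORE 5-minute binning.
#'
#' @param counts numeric vector of non-negative counts.
#' @return `ln(1 + counts)`, elementwise.
#' @examples
#' log_transform(c(0, exp(1) - 1, 99))
#' @export
log_transform <- function(counts) {
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts must be finite and non-missing")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  log1p(counts)
}

#' Average a per-minute day into 5-minute bins
#'
#' Bin `j` (0-based) is the arithmetic mean of minutes `[5j, 5j+5)`, giving
#' the 288-point daily grid of [time_grid()].
#'
#' @param values numeric vector of length 1440.
#' @return numeric vector of length 288.
#' @export
bin_five_minutes <- function(values) {
  if (length(values) != N_MINUTES) {
    stop(sprintf("expected 1440 per-minute values, got %d", length(values)))
  }
  colMeans(matrix(values, nrow = 5L))
}

#' Weekday/weekend label of a calendar date
#'
#' Saturday and Sunday are `weekend`; Monday through Friday `weekday`.
#'
#' @param date a `Date` vector.
#' @return character vector of `"weekday"`/`"weekend"` labels.
#' @export
split_daytype <- function(date) {
  date <- as.Date(date)
  ifelse(format(date, "%u") %in% c("6", "7"), "weekend", "weekday")
}

#' Select the baseline week from a longer recording
#'
#' Monitors are worn longer than the analysis window: the first and last
#' recorded days are discarded (partial wear), and the chronologically last 7
#' of the remaining complete days form the baseline week.
#'
#' @param series list of [epoch_series] for ONE subject (any order).
#' @return list of 7 [epoch_series], chronologically ordered.
#' @export
select_baseline_days <- function(series) {
  if (length(series) == 0L) stop("no days supplied")
  id <- series[[1]]$cat_id
  if (!all(vapply(series, function(s) s$cat_id, character(1)) == id)) {
    stop("select_baseline_days expects days of a single subject")
  }
  dates <- as.Date(vapply(series, function(s) format(s$date), character(1)))
  if (anyDuplicated(dates)) stop("duplicated dates for subject ", id)
  series <- series[order(dates)]
  n <- length(series)
  if (n < 9L) {
    stop(sprintf("subject %s: %d recorded days; need >= 9 (first and last are dropped, then 7 kept)",
                 id, n))
  }
  usable <- series[2:(n - 1L)]
  usable[(length(usable) - 6L):length(usable)]
}

# one epoch_series -> 288-point log-scale daily curve
daily_curve <- function(series) {
  bin_five_minutes(log_transform(series$counts))
}

#' Per-subject activity and intensity profiles
#'
#' Builds a subject's day-type profiles from exactly 7 daily curves (5 weekday
#' + 2 weekend, the composition of any run of 7 consecutive calendar days).
#' The activity profiles `Y_weekday`, `Y_weekend` are pointwise means of the
#' daily log-scale curves within day type; `ave` is the grand mean of all
#' 7 x 288 values; the intensity profiles are `I(t) = Y(t) - ave`, the
#' subject's activity relative to its own typical level. The construction
#' guarantees `(5 * mean(I_weekday) + 2 * mean(I_weekend)) / 7 == 0`.
#'
#' @param curves 7 x 288 matrix of daily log-scale curves (rows are days), or
#'   a list of 7 such vectors.
#' @param daytypes character vector of 7 `"weekday"`/`"weekend"` labels.
#' @param cat_id subject identifier.
#' @return an object of class `cat_profile` with elements `cat_id`,
#'   `Y_weekday`, `Y_weekend`, `ave`, `I_weekday`, `I_weekend`.
#' @export
build_profile <- function(curves, daytypes, cat_id = "") {
  if (is.list(curves)) curves <- do.call(rbind, curves)
  if (!is.matrix(curves) || ncol(curves) != N_BINS || nrow(curves) != 7L) {
    stop("curves must be a 7 x 288 matrix")
  }
  if (length(daytypes) != 7L) stop("need 7 day-type labels")
  nwd <- sum(daytypes == "weekday")
  nwe <- sum(daytypes == "weekend")
  if (nwd != 5L || nwe != 2L) {
    stop(sprintf("subject %s: need 5 weekday + 2 weekend days, got %d + %d",
                 cat_id, nwd, nwe))
  }
  Y_wd <- colMeans(curves[daytypes == "weekday", , drop = FALSE])
  Y_we <- colMeans(curves[daytypes == "weekend", , drop = FALSE])
  ave <- mean(curves)
  structure(list(cat_id = cat_id,
                 Y_weekday = Y_wd, Y_weekend = Y_we, ave = ave,
                 I_weekday = Y_wd - ave, I_weekend = Y_we - ave),
            class = "cat_profile")
}

#' @export
print.cat_profile <- function(x, ...) {
  cat(sprintf("<cat_profile> %s  ave log-activity %.3f\n", x$cat_id, x$ave))
  cat(sprintf("  weekday peak at %.2f h, weekend peak at %.2f h\n",
              time_grid()[which.max(x$Y_weekday)],
              time_grid()[which.max(x$Y_weekend)]))
  invisible(x)
}

#' Preprocess a cohort of epoch series into profiles
#'
#' Runs the full per-subject preprocessing chain: log transform, 5-minute
#' binning, baseline-week selection when more than 7 days were recorded
#' (see [select_baseline_days()]; subjects with exactly 7 days are used
#' as-is), day-type stratification, and profile construction.
#'
#' @param epochs list of [epoch_series] (all subjects mixed).
#' @return a list with `profiles` (list of `cat_profile`, one per subject,
#'   ordered by id) and `mean_counts` (named vector: each subject's average
#'   per-minute raw count across its 7 baseline days, computed before the
#'   log transform — the descriptive summary scale).
#' @export
preprocess_cohort <- function(epochs) {
  ids <- vapply(epochs, function(s) s$cat_id, character(1))
  profiles <- list()
  mean_counts <- numeric(0)
  for (id in sort(unique(ids))) {
    days <- epochs[ids == id]
    if (length(days) > 7L) {
      days <- select_baseline_days(days)
    } else if (length(days) < 7L) {
      stop(sprintf("subject %s has only %d complete days; 7 required",
                   id, length(days)))
    } else {
      dates <- as.Date(vapply(days, function(s) format(s$date), character(1)))
      days <- days[order(dates)]
    }
    daytypes <- split_daytype(as.Date(vapply(days, function(s) format(s$date),
                                             character(1))))
    curves <- t(vapply(days, daily_curve, numeric(N_BINS)))
    profiles[[id]] <- build_profile(curves, daytypes, id)
    mean_counts[id] <- mean(vapply(days, function(s) mean(s$counts),
                                   numeric(1)))
  }
  list(profiles = profiles, mean_counts = mean_counts)
}

#' Stack per-subject profiles into a curve matrix
#'
#' Extracts one `n x 288` matrix of curves (rows named by `cat_id`) from a
#' list of profiles — the input shape that [fpca()], [fosr()] and the test
#' functions expect.
#'
#' @param profiles list of `cat_profile` (see [preprocess_cohort()]).
#' @param response `"activity"` or `"intensity"`.
#' @param daytype `"weekday"` or `"weekend"`.
#' @return numeric matrix, one row per subject.
#' @export
profile_matrix <- function(profiles, response = c("activity", "intensity"),
                           daytype = c("weekday", "weekend")) {
  response <- match.arg(response)
  daytype <- match.arg(daytype)
  field <- paste0(if (response == "activity") "Y_" else "I_", daytype)
  m <- t(vapply(profiles, function(p) p[[field]], numeric(N_BINS)))
  rownames(m) <- vapply(profiles, function(p) p$cat_id, character(1))
  m
}

#' Group-mean activity and intensity profiles
#'
#' Pointwise means across subjects, per group and day type.
#'
#' @param profiles list of `cat_profile`.
#' @param groups character vector of group labels, parallel to `profiles`.
#' @return a data.frame in long format with columns
#'   `group,daytype,bin_index,t_hours,activity,intensity`.
#' @export
group_mean_profiles <- function(profiles, groups) {
  stopifnot(length(groups) == length(profiles))
  if (length(profiles) == 0L) stop("no profiles supplied")
  out <- list()
  for (g in sort(unique(groups))) {
    sel <- profiles[groups == g]
    if (length(sel) == 0L) stop("empty group: ", g)
    for (dt in c("weekday", "weekend")) {
      act <- colMeans(profile_matrix(sel, "activity", dt))
      int <- colMeans(profile_matrix(sel, "intensity", dt))
      out[[paste(g, dt)]] <- data.frame(
        group = g, daytype = dt, bin_index = 0:(N_BINS - 1L),
        t_hours = time_grid(), activity = act, intensity = int)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Descriptive summary of per-subject mean per-minute counts
#'
#' Five-number summary plus mean, per group, of each subject's average raw
#' per-minute count over the baseline week (pre-transform scale). Quartiles
#' use linear interpolation (`quantile` type 7); the convention is recorded
#' in the output.
#'
#' @param mean_counts named numeric vector of subject-level average counts
#'   (as produced by [preprocess_cohort()]).
#' @param groups character vector of group labels parallel to `mean_counts`.
#' @return data.frame with columns `group, n, minimum, q1, median, mean, q3,
#'   maximum, quantile_type`.
#' @export
cohort_summary <- function(mean_counts, groups) {
  stopifnot(length(groups) == length(mean_counts))
  if (length(mean_counts) == 0L) stop("no subjects supplied")
  rows <- lapply(sort(unique(groups)), function(g) {
    x <- mean_counts[groups == g]
    if (length(x) == 0L) stop("empty group: ", g)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), minimum = min(x), q1 = q[1],
               median = q[2], mean = mean(x), q3 = q[3], maximum = max(x),
               quantile_type = 7L)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Export profiles as a tidy curves table
#'
#' @param profiles list of `cat_profile`.
#' @return data.frame `cat_id,daytype,bin_index,t_hours,activity,intensity`.
#' @export
profiles_to_df <- function(profiles) {
  out <- lapply(profiles, function(p) {
    do.call(rbind, lapply(c("weekday", "weekend"), function(dt) {
      data.frame(cat_id = p$cat_id, daytype = dt,
                 bin_index = 0:(N_BINS - 1L), t_hours = time_grid(),
                 activity = p[[paste0("Y_", dt)]],
                 intensity = p[[paste0("I_", dt)]])
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
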