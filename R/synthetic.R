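#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions a generated cohort emulates: a bimodal feline
#' circadian profile (overnight trough ~02:00-05:00, sharp morning peak, broad
#' evening peak) on the `ln(1 + count)` scale; a weekend morning peak that is
#' flattened and delayed; joint-disease (DJD) profiles whose peak/trough
#' excursions are multiplicatively attenuated; low-rank inter-subject
#' variation through planted orthonormal eigenfunctions; optional planted
#' time-varying covariate effects; and right-skewed integer counts obtained by
#' inverting the log scale under lognormal per-minute noise.
#'
#' @param seed integer RNG seed; recorded in all outputs.
#' @param n_per_group named integer vector, subjects per group
#'   (names `Normal`, `DJD`).
#' @param n_days days per subject starting at `anchor_date`; 7 (one calendar
#'   week used as-is) or at least 9 (so baseline-week selection can drop the
#'   first and last days and keep 7).
#' @param anchor_date first recorded calendar date (default a Monday).
#' @param peak_params named list of template parameters on the log-count
#'   scale: `baseline`, `morning_center`/`morning_width`/`morning_amp`,
#'   `evening_center`/`evening_width`/`evening_amp`,
#'   `trough_center`/`trough_width`/`trough_depth` (hours / hours / log-count
#'   units), and `weekend_morning_flatten`, the factor applied to the weekend
#'   morning amplitude.
#' @param eigen_spec list with `ids` (subset of `"sin1"`, `"cos1"`, `"sin2"`,
#'   `"cos2"`, or a 288 x K matrix in `functions`) and `values`, the
#'   eigenvalues, non-negative and non-increasing.
#' @param beta_spec named list of planted time-varying covariate effects;
#'   names among `age`, `bcs`, `age_bcs`, `tpain`, `tdjd`; each a function of
#'   time in hours or a 288-vector. Effects multiply the cohort-standardized
#'   covariate.
#' @param weekend_shift hours by which the weekend morning peak is delayed.
#' @param djd_attenuation factor in (0, 1] multiplying all peak/trough
#'   excursions of the DJD templates (1 = no disease effect).
#' @param noise_sd per-minute lognormal noise SD on the latent log scale.
#' @param score_xcorr planted correlation between a subject's weekend and
#'   weekday scores on each eigenfunction.
#' @return a validated object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_per_group = c(Normal = 15L, DJD = 83L),
                             n_days = 7L,
                             anchor_date = "2015-06-01",
                             peak_params = list(),
                             eigen_spec = list(),
                             beta_spec = list(),
                             weekend_shift = 1.5,
                             djd_attenuation = 0.75,
                             noise_sd = 0.8,
                             score_xcorr = 0.6) {
  pp <- utils::modifyList(list(
    baseline = 3.2,
    morning_center = 7.0, morning_width = 1.0, morning_amp = 1.2,
    evening_center = 20.0, evening_width = 2.0, evening_amp = 0.9,
    trough_center = 3.5, trough_width = 1.2, trough_depth = 1.2,
    weekend_morning_flatten = 0.7), peak_params)
  es <- utils::modifyList(list(ids = c("sin1", "cos1", "sin2"),
                               values = c(0.5, 0.25, 0.12)),
                          eigen_spec)
  if (!all(names(n_per_group) %in% c("Normal", "DJD"))) {
    stop("n_per_group names must be among 'Normal', 'DJD'")
  }
  if (any(n_per_group < 0)) stop("n_per_group must be non-negative")
  if (!(n_days == 7L || n_days >= 9L)) {
    stop("n_days must be 7 or at least 9")
  }
  vals <- es$values
  if (any(vals < 0)) stop("eigenvalues must be non-negative")
  if (is.unsorted(rev(vals), strictly = FALSE)) {
    stop("eigenvalues must be listed in non-increasing order")
  }
  if (!all(vapply(pp, is.finite, logical(1)))) {
    stop("all peak parameters must be finite")
  }
  if (djd_attenuation <= 0 || djd_attenuation > 1) {
    stop("djd_attenuation must lie in (0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (abs(score_xcorr) > 1) stop("score_xcorr must lie in [-1, 1]")
  bad <- setdiff(names(beta_spec), c("age", "bcs", "age_bcs", "tpain", "tdjd"))
  if (length(bad)) stop("unknown beta_spec terms: ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 n_days = as.integer(n_days),
                 anchor_date = as.Date(anchor_date),
                 peak_params = pp, eigen_spec = es, beta_spec = beta_spec,
                 weekend_shift = weekend_shift,
                 djd_attenuation = djd_attenuation,
                 noise_sd = noise_sd, score_xcorr = score_xcorr),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  seed %d; %s; %d days from %s\n", x$seed,
              paste(names(x$n_per_group), x$n_per_group, collapse = " + "),
              x$n_days, format(x$anchor_date)))
  cat(sprintf("  weekend shift %.2g h, DJD attenuation %.2g, noise sd %.2g, score xcorr %.2g\n",
              x$weekend_shift, x$djd_attenuation, x$noise_sd, x$score_xcorr))
  cat(sprintf("  eigenvalues: %s\n", paste(x$eigen_spec$values, collapse = ", ")))
  invisible(x)
}

# orthonormal (quadrature inner product) planted eigenfunctions
planted_eigenfunctions <- function(eigen_spec) {
  t <- time_grid()
  if (!is.null(eigen_spec$functions)) {
    raw <- eigen_spec$functions
    if (!is.matrix(raw) || nrow(raw) != N_BINS) {
      stop("eigen_spec$functions must be a 288 x K matrix")
    }
  } else {
    base <- list(
      sin1 = sin(2 * pi * t / 24), cos1 = cos(2 * pi * t / 24),
      sin2 = sin(4 * pi * t / 24), cos2 = cos(4 * pi * t / 24))
    unknown <- setdiff(eigen_spec$ids, names(base))
    if (length(unknown)) stop("unknown eigenfunction ids: ",
                              paste(unknown, collapse = ", "))
    raw <- do.call(cbind, base[eigen_spec$ids])
  }
  K <- min(ncol(raw), length(eigen_spec$values))
  raw <- raw[, seq_len(K), drop = FALSE]
  # Gram-Schmidt under the quadrature inner product
  for (k in seq_len(K)) {
    v <- raw[, k]
    if (k > 1L) {
      for (j in seq_len(k - 1L)) v <- v - quad_inner(v, raw[, j]) * raw[, j]
    }
    nrm <- sqrt(quad_inner(v, v))
    if (nrm < 1e-12) stop("planted eigenfunctions are linearly dependent")
    raw[, k] <- v / nrm
  }
  raw
}

#' Group/day-type mean template on the daily grid
#'
#' The latent (log-scale) population mean curve: a constant baseline plus
#' Gaussian morning and evening bumps and a negative Gaussian overnight
#' trough. Weekend templates delay the morning bump by `weekend_shift` hours
#' and flatten it by `weekend_morning_flatten`; DJD templates multiply all
#' excursions by `djd_attenuation` ("muted" peaks and shallower troughs).
#'
#' @param group `"Normal"` or `"DJD"`.
#' @param daytype `"weekday"` or `"weekend"`.
#' @param config a [generator_config()].
#' @return numeric vector of 288 latent log-scale values.
#' @export
bimodal_template <- function(group, daytype, config = generator_config()) {
  if (!group %in% c("Normal", "DJD")) stop("unknown group label: ", group)
  if (!daytype %in% c("weekday", "weekend")) {
    stop("unknown daytype label: ", daytype)
  }
  p <- config$peak_params
  t <- time_grid()
  m_center <- p$morning_center
  m_amp <- p$morning_amp
  if (daytype == "weekend") {
    m_center <- m_center + config$weekend_shift
    m_amp <- m_amp * p$weekend_morning_flatten
  }
  bump <- function(center, width, amp) amp * exp(-(t - center)^2 / (2 * width^2))
  excursion <- bump(m_center, p$morning_width, m_amp) +
    bump(p$evening_center, p$evening_width, p$evening_amp) -
    bump(p$trough_center, p$trough_width, p$trough_depth)
  if (group == "DJD") excursion <- excursion * config$djd_attenuation
  p$baseline + excursion
}

#' Turn a latent per-minute log curve into integer counts
#'
#' Inverts the `ln(1 + x)` analysis scale: adds Gaussian noise on the latent
#' scale, exponentiates, subtracts 1, rounds, and clips at 0. Draws from the
#' CURRENT RNG state (callers seed it).
#'
#' @param latent numeric vector of 1440 finite latent log-scale values.
#' @param noise_sd per-minute noise SD on the latent scale.
#' @return integer vector of 1440 non-negative counts.
#' @export
curve_to_counts <- function(latent, noise_sd = 0) {
  if (any(!is.finite(latent))) stop("latent values must be finite")
  noisy <- latent + stats::rnorm(length(latent), 0, noise_sd)
  as.integer(pmax(0, round(expm1(noisy))))
}

# group-dependent covariate draws (ranges per the published scales)
draw_covariates <- function(group, n) {
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  if (group == "Normal") {
    age <- round(clamp(stats::rnorm(n, 6, 2), 1.5, 20), 1)
    bcs <- as.integer(clamp(round(stats::rnorm(n, 5, 1)), 1, 9))
    tpain <- as.integer(clamp(stats::rpois(n, 1.3), 0, 80))
    tdjd <- as.integer(clamp(stats::rpois(n, 3), 0, 200))
    msjp <- as.integer(pmin(tpain, stats::rbinom(n, 1, 0.2)))
    study <- rep("Normal", n)
  } else {
    age <- round(clamp(stats::rnorm(n, 12, 2.5), 2, 22), 1)
    bcs <- as.integer(clamp(round(stats::rnorm(n, 6, 1.2)), 1, 9))
    tpain <- as.integer(clamp(round(stats::rnorm(n, 15, 6)), 1, 80))
    tdjd <- as.integer(clamp(round(stats::rnorm(n, 22, 8)), 4, 200))
    msjp <- as.integer(clamp(round(tpain / 8), 1, 4))
    # two enrolment sub-studies pooled downstream, in ~25:58 proportion
    n_fmpi <- round(n * 25 / 83)
    study <- sample(rep(c("FMPI", "LowDose"), c(n_fmpi, n - n_fmpi)))
  }
  data.frame(group = group, study = study, age = age, bcs = bcs,
             sex = sample(c("MC", "FS"), n, replace = TRUE),
             tpain = tpain, tdjd = tdjd, max_single_joint_pain = msjp,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Draws covariates, per-subject eigenfunction scores (weekend scores
#' correlated with weekday scores at `score_xcorr` per component), builds each
#' subject's latent day-type curves
#' `template + sum_k xi_ik phi_k(t) + sum_p x_ip beta_p(t)` (covariates
#' standardized over the cohort), and converts them to per-minute integer
#' counts day by day. Fully deterministic given the config (including seed).
#'
#' @param config a [generator_config()].
#' @return a list with `epochs` (list of [epoch_series]), `covariates`
#'   (data.frame as in [read_covariate_csv()]), and `truth` (planted
#'   templates, eigenfunctions/eigenvalues, beta curves, scores, seed).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  groups <- names(config$n_per_group)[config$n_per_group > 0]
  covs <- list()
  for (g in groups) {
    n <- config$n_per_group[[g]]
    prefix <- if (g == "Normal") "N" else "D"
    cc <- draw_covariates(g, n)
    cc <- cbind(cat_id = sprintf("%s%03d", prefix, seq_len(n)), cc)
    covs[[g]] <- cc
  }
  covariates <- do.call(rbind, covs)
  rownames(covariates) <- NULL
  n_tot <- nrow(covariates)
  if (n_tot == 0L) stop("empty cohort")

  phi <- planted_eigenfunctions(config$eigen_spec)
  K <- ncol(phi)
  lambda <- config$eigen_spec$values[seq_len(K)]

  # weekday/weekend scores, bivariate Gaussian per component
  rho <- config$score_xcorr
  xi_wd <- matrix(0, n_tot, K)
  xi_we <- matrix(0, n_tot, K)
  for (k in seq_len(K)) {
    z1 <- stats::rnorm(n_tot)
    z2 <- stats::rnorm(n_tot)
    xi_wd[, k] <- sqrt(lambda[k]) * z1
    xi_we[, k] <- sqrt(lambda[k]) * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  rownames(xi_wd) <- rownames(xi_we) <- covariates$cat_id

  # planted covariate effects act on cohort-standardized covariates
  beta <- lapply(config$beta_spec, function(b) {
    if (is.function(b)) b(time_grid()) else {
      stopifnot(length(b) == N_BINS)
      as.numeric(b)
    }
  })
  xstd <- matrix(0, n_tot, length(beta),
                 dimnames = list(covariates$cat_id, names(beta)))
  if (length(beta)) {
    for (nm in names(beta)) {
      raw <- switch(nm,
                    age_bcs = scale01(covariates$age) * scale01(covariates$bcs),
                    scale01(covariates[[nm]]))
      xstd[, nm] <- raw
    }
  }

  templates <- list()
  for (g in groups) for (dt in c("weekday", "weekend")) {
    templates[[paste(g, dt, sep = ".")]] <- bimodal_template(g, dt, config)
  }

  dates <- config$anchor_date + 0:(config$n_days - 1L)
  daytypes <- split_daytype(dates)
  epochs <- vector("list", n_tot * config$n_days)
  pos <- 0L
  for (i in seq_len(n_tot)) {
    g <- covariates$group[i]
    cov_part <- if (length(beta)) {
      Reduce(`+`, Map(function(b, x) b * x, beta, as.list(xstd[i, ])))
    } else numeric(N_BINS)
    lat <- list(
      weekday = templates[[paste(g, "weekday", sep = ".")]] +
        as.numeric(phi %*% xi_wd[i, ]) + cov_part,
      weekend = templates[[paste(g, "weekend", sep = ".")]] +
        as.numeric(phi %*% xi_we[i, ]) + cov_part)
    for (d in seq_along(dates)) {
      minute_latent <- rep(lat[[daytypes[d]]], each = 5L)
      pos <- pos + 1L
      epochs[[pos]] <- epoch_series(covariates$cat_id[i], dates[d],
                                    curve_to_counts(minute_latent,
                                                    config$noise_sd))
    }
  }

  truth <- list(templates = templates, eigenfunctions = phi,
                eigenvalues = lambda, beta = beta,
                scores = list(weekday = xi_wd, weekend = xi_we),
                covariates_std = xstd, seed = config$seed)
  list(epochs = epochs, covariates = covariates, truth = truth)
}

# center/scale to unit sample SD (errors on zero variance)
scale01 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance covariate")
  (x - mean(x)) / s
}

#' Write a generated cohort to disk
#'
#' Emits the per-minute epoch CSV, the covariate CSV and a small metadata
#' sidecar recording the seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_epoch_csv(cohort$epochs, file.path(dir, "epochs.csv"))
  write_covariate_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  meta <- file(file.path(dir, "cohort_meta.json"), open = "wb")
  writeLines(jsonlite::toJSON(list(seed = cohort$truth$seed,
                                   n_subjects = nrow(cohort$covariates)),
                              auto_unbox = TRUE), meta, sep = "\n")
  close(meta)
  invisible(dir)
}
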