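# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Assemble (or read from a YAML file) the configuration for a full analysis
#' run: either input CSV paths (`epoch_csv`, `covariate_csv`) or a generator
#' config, plus output directory, master seed, and simulation sizes.
#'
#' @param file optional YAML file; its keys override the defaults and are in
#'   turn overridden by arguments supplied here.
#' @param epoch_csv,covariate_csv input paths (omit to simulate).
#' @param generator a [generator_config()] or a list of its arguments.
#' @param outdir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_sim LRT null simulations per test.
#' @param n_boot bootstrap resamples for regression bands.
#' @param n_perm permutations per Anderson-Darling component.
#' @param var_threshold FPCA variance threshold for the distribution test.
#' @param fpca_k components kept in the descriptive FPCA (default 3).
#' @param write_cohort write the simulated cohort CSVs into `outdir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(file = NULL, epoch_csv = NULL,
                            covariate_csv = NULL, generator = NULL,
                            outdir = "actifda-run", seed = 1L,
                            n_sim = 200L, n_boot = 200L, n_perm = 499L,
                            var_threshold = 0.95, fpca_k = 3L,
                            write_cohort = TRUE) {
  cfg <- list(epoch_csv = epoch_csv, covariate_csv = covariate_csv,
              generator = generator, outdir = outdir, seed = as.integer(seed),
              n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
              n_perm = as.integer(n_perm), var_threshold = var_threshold,
              fpca_k = as.integer(fpca_k), write_cohort = write_cohort)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    known <- intersect(names(y), names(cfg))
    supplied <- names(as.list(match.call()))[-1]
    for (k in setdiff(known, supplied)) cfg[[k]] <- y[[k]]
    cfg$seed <- as.integer(cfg$seed)
  }
  if (is.null(cfg$generator) && is.null(cfg$epoch_csv)) {
    cfg$generator <- list()
  }
  if (!is.null(cfg$generator) && !inherits(cfg$generator, "generator_config")) {
    gen_args <- cfg$generator
    if (!"seed" %in% names(gen_args)) gen_args$seed <- cfg$seed
    if (!is.null(gen_args$n_per_group)) {
      gen_args$n_per_group <- unlist(gen_args$n_per_group)
    }
    cfg$generator <- do.call(generator_config, gen_args)
  }
  if (is.null(cfg$seed)) stop("a seed is required")
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic stage seeds derived from the master seed (kept < 2^31)
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647)
}

write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# the four standard covariate settings of the mean-equality test battery
covariate_settings <- function(covs) {
  base <- standardize_covariates(covs, c("age", "bcs", "age:bcs"))$design[, -1, drop = FALSE]
  tdjd <- standardize_covariates(covs, "tdjd")$design[, -1, drop = FALSE]
  tpain <- standardize_covariates(covs, "tpain")$design[, -1, drop = FALSE]
  list("none" = NULL,
       "age+bcs+ixn" = base,
       "age+bcs+ixn+tdjd" = cbind(base, tdjd),
       "age+bcs+ixn+tpain" = cbind(base, tpain))
}

# ---- the pipeline -----------------------------------------------------------

#' Run the full activity-profile analysis
#'
#' Executes, in order: cohort ingest (or synthesis), preprocessing to
#' activity/intensity profiles, the pooling check between the two DJD
#' enrolment sub-studies (distribution tests plus mean-curve LRTs under the
#' four covariate settings; pooling proceeds regardless, with a warning if a
#' check rejects), group mean profiles, per-group/day-type FPCA of intensity
#' with modes of variation and weekend-weekday score correlations,
#' function-on-scalar regression Models 1 (Normal: age, BCS, age:BCS) and 2
#' (DJD: + TDJD, TPain) with bootstrap bands and significance regions, the
#' Normal-vs-DJD mean-curve LRT battery (weekend/weekday x
#' activity/intensity x four covariate settings, Bonferroni-adjusted per
#' row), and Normal-vs-DJD distribution tests. Every artifact is written as
#' CSV beneath `config$outdir` together with a JSON run manifest; a run is
#' byte-identical under a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results
#'   (`profiles`, `fpca`, `fosr`, `mean_tests`, `dist_tests`, ...).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                            format(Sys.time(), "%H:%M:%S"), ...))

  # 1. ingest or generate ----------------------------------------------------
  if (!is.null(config$epoch_csv)) {
    log("reading cohort from %s", config$epoch_csv)
    epochs <- read_epoch_csv(config$epoch_csv)
    covs <- read_covariate_csv(config$covariate_csv)
    truth <- NULL
  } else {
    log("generating synthetic cohort (seed %d)", config$generator$seed)
    cohort <- generate_cohort(config$generator)
    epochs <- cohort$epochs
    covs <- cohort$covariates
    truth <- cohort$truth
    if (isTRUE(config$write_cohort)) {
      write_cohort(cohort, file.path(config$outdir, "cohort"))
    }
  }

  # 2. preprocessing ----------------------------------------------------------
  log("preprocessing %d subject-days", length(epochs))
  prep <- preprocess_cohort(epochs)
  profiles <- prep$profiles
  covs <- covs[match(names(profiles), covs$cat_id), ]
  if (anyNA(covs$cat_id)) stop("covariate table is missing subjects")
  groups <- covs$group
  write_csv_lf(profiles_to_df(profiles),
               file.path(config$outdir, "profiles.csv"))
  write_csv_lf(cohort_summary(prep$mean_counts,
                              ifelse(groups == "Normal", "Normal", covs$study)),
               file.path(config$outdir, "cohort_summary.csv"))
  write_csv_lf(group_mean_profiles(profiles, groups),
               file.path(config$outdir, "group_mean_profiles.csv"))

  curves <- list()
  for (resp in c("activity", "intensity")) for (dt in c("weekday", "weekend")) {
    curves[[paste(resp, dt, sep = ".")]] <- profile_matrix(profiles, resp, dt)
  }

  # 3. pooling check between the DJD sub-studies ------------------------------
  pooling <- NULL
  djd_idx <- which(groups == "DJD")
  studies <- covs$study[djd_idx]
  if (length(unique(studies)) == 2L && min(table(studies)) >= 3L) {
    log("pooling check: %s", paste(names(table(studies)), table(studies),
                                   collapse = " vs "))
    settings <- covariate_settings(covs[djd_idx, ])
    rows <- list()
    for (key in names(curves)) {
      cm <- curves[[key]][djd_idx, , drop = FALSE]
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      dt <- distribution_test(cm[studies == "FMPI", , drop = FALSE],
                              cm[studies != "FMPI", , drop = FALSE],
                              var_threshold = config$var_threshold,
                              n_perm = config$n_perm,
                              seed = stage_seed(config$seed, 11))
      rows[[paste(key, "dist")]] <- data.frame(
        comparison = "FMPI-vs-LowDose", response = parts[1],
        daytype = parts[2], covariate_setting = "distribution",
        statistic = min(dt$table$A2), p_value = dt$overall_p,
        n_sim = config$n_perm, adjusted_alpha = dt$bonferroni_alpha,
        decision = dt$decision)
      for (cs in names(settings)) {
        lr <- lrt_mean_equality(cm, studies, settings[[cs]],
                                n_sim = config$n_sim,
                                seed = stage_seed(config$seed, 13),
                                comparison = "FMPI-vs-LowDose",
                                covariate_setting = cs)
        adj <- 0.05 / length(settings)
        rows[[paste(key, cs)]] <- data.frame(
          comparison = "FMPI-vs-LowDose", response = parts[1],
          daytype = parts[2], covariate_setting = cs,
          statistic = lr$statistic, p_value = lr$p_value,
          n_sim = lr$n_sim, adjusted_alpha = adj,
          decision = if (lr$p_value <= adj) "reject" else "retain")
      }
    }
    pooling <- do.call(rbind, rows)
    rownames(pooling) <- NULL
    write_csv_lf(pooling, file.path(config$outdir, "pooling_check.csv"))
    if (any(pooling$decision == "reject")) {
      warning("pooling check rejected for at least one comparison; ",
              "the DJD sub-studies are pooled regardless", call. = FALSE)
    }
  }

  # 4. FPCA per group x day type (intensity), score correlations --------------
  log("FPCA per group and day type")
  fpca_fits <- list()
  eig_rows <- list()
  var_rows <- list()
  cor_rows <- list()
  score_rows <- list()
  for (g in unique(groups)) {
    for (dt in c("weekday", "weekend")) {
      cm <- curves[[paste("intensity", dt, sep = ".")]][groups == g, ,
                                                        drop = FALSE]
      f <- fpca(cm, k = config$fpca_k)
      fpca_fits[[paste(g, dt, sep = ".")]] <- f
      for (k in seq_along(f$lambda)) {
        eig_rows[[paste(g, dt, k)]] <- data.frame(
          group = g, daytype = dt, component = k,
          bin_index = 0:(N_BINS - 1L), t_hours = f$grid, phi = f$phi[, k])
      }
      var_rows[[paste(g, dt)]] <- data.frame(
        group = g, daytype = dt, component = seq_along(f$lambda),
        eigenvalue = f$lambda, var_explained = f$var_explained)
      score_rows[[paste(g, dt)]] <- data.frame(
        cat_id = rownames(cm), group = g, daytype = dt,
        component = rep(seq_along(f$lambda), each = nrow(cm)),
        score = as.vector(f$scores))
    }
    fwd <- fpca_fits[[paste(g, "weekday", sep = ".")]]
    fwe <- fpca_fits[[paste(g, "weekend", sep = ".")]]
    kk <- min(length(fwd$lambda), length(fwe$lambda))
    cor_rows[[g]] <- data.frame(
      group = g, component = seq_len(kk),
      score_correlation = vapply(seq_len(kk), function(k) {
        score_correlation(fwe, fwd, k)
      }, numeric(1)))
  }
  write_csv_lf(do.call(rbind, eig_rows),
               file.path(config$outdir, "fpca_eigenfunctions.csv"))
  write_csv_lf(do.call(rbind, var_rows),
               file.path(config$outdir, "fpca_variance.csv"))
  write_csv_lf(do.call(rbind, score_rows),
               file.path(config$outdir, "fpca_scores.csv"))
  score_cors <- do.call(rbind, cor_rows)
  rownames(score_cors) <- NULL
  write_csv_lf(score_cors, file.path(config$outdir, "score_correlations.csv"))

  # 5. function-on-scalar regression Models 1 and 2 ---------------------------
  log("function-on-scalar regressions (n_boot = %d)", config$n_boot)
  fosr_fits <- list()
  coef_rows <- list()
  sig_rows <- list()
  models <- list(Normal = ~ age + bcs + age:bcs,
                 DJD = ~ age + bcs + age:bcs + tdjd + tpain)
  for (g in names(models)) {
    idx <- which(groups == g)
    if (length(idx) <= 6L) next
    for (resp in c("activity", "intensity")) for (dt in c("weekday", "weekend")) {
      cm <- curves[[paste(resp, dt, sep = ".")]][idx, , drop = FALSE]
      fit <- fosr(cm, models[[g]], covs[idx, ], response = resp, daytype = dt)
      fit <- bootstrap_ci(fit, n_boot = config$n_boot,
                          seed = stage_seed(config$seed, 29))
      key <- paste(g, resp, dt, sep = ".")
      fosr_fits[[key]] <- fit
      for (tm in fit$terms) {
        coef_rows[[paste(key, tm)]] <- data.frame(
          group = g, response = resp, daytype = dt, term = tm,
          bin_index = 0:(N_BINS - 1L), t_hours = fit$grid,
          beta = fit$beta[, tm], ci_lower = fit$ci_lower[, tm],
          ci_upper = fit$ci_upper[, tm])
        sr <- significance_regions(fit, tm)
        if (nrow(sr)) {
          sig_rows[[paste(key, tm)]] <- cbind(
            data.frame(group = g, response = resp, daytype = dt), sr)
        }
      }
    }
  }
  write_csv_lf(do.call(rbind, coef_rows),
               file.path(config$outdir, "fosr_coefficients.csv"))
  sig_df <- if (length(sig_rows)) do.call(rbind, sig_rows) else
    data.frame(group = character(0), response = character(0),
               daytype = character(0), term = character(0),
               start_hour = numeric(0), end_hour = numeric(0),
               sign = integer(0))
  rownames(sig_df) <- NULL
  write_csv_lf(sig_df, file.path(config$outdir, "fosr_significance.csv"))

  # 6. paired weekend-vs-weekday tests per group ------------------------------
  log("paired day-type tests")
  paired_rows <- list()
  paired_tests <- list()
  for (g in unique(groups)) {
    for (resp in c("activity", "intensity")) {
      wd <- curves[[paste(resp, "weekday", sep = ".")]][groups == g, ,
                                                        drop = FALSE]
      we <- curves[[paste(resp, "weekend", sep = ".")]][groups == g, ,
                                                        drop = FALSE]
      tt <- lrt_paired_daytype(wd, we, n_sim = config$n_sim,
                               seed = stage_seed(config$seed, 31),
                               comparison = sprintf("%s weekend-vs-weekday", g))
      paired_tests[[paste(g, resp, sep = ".")]] <- tt
      paired_rows[[paste(g, resp)]] <- data.frame(
        comparison = tt$comparison, response = resp, daytype = "both",
        covariate_setting = "none (paired)", statistic = tt$statistic,
        p_value = tt$p_value, n_sim = tt$n_sim, adjusted_alpha = 0.05,
        decision = if (tt$p_value <= 0.05) "reject" else "retain")
    }
  }
  paired_df <- do.call(rbind, paired_rows)
  rownames(paired_df) <- NULL
  write_csv_lf(paired_df, file.path(config$outdir, "paired_daytype_tests.csv"))

  # 7. Normal-vs-DJD mean-equality battery ------------------------------------
  mean_table <- NULL
  mean_tests <- list()
  if (all(c("Normal", "DJD") %in% groups)) {
    log("Normal-vs-DJD mean-curve tests (n_sim = %d)", config$n_sim)
    settings <- covariate_settings(covs)
    rows <- list()
    for (resp in c("activity", "intensity")) for (dt in c("weekday", "weekend")) {
      cm <- curves[[paste(resp, dt, sep = ".")]]
      for (cs in names(settings)) {
        lr <- lrt_mean_equality(cm, groups, settings[[cs]],
                                n_sim = config$n_sim,
                                seed = stage_seed(config$seed, 37),
                                comparison = "Normal-vs-DJD",
                                covariate_setting = cs)
        mean_tests[[paste(resp, dt, cs, sep = ".")]] <- lr
        adj <- 0.05 / length(settings)   # Bonferroni within each profile row
        rows[[paste(resp, dt, cs)]] <- data.frame(
          comparison = "Normal-vs-DJD", response = resp, daytype = dt,
          covariate_setting = cs, statistic = lr$statistic,
          p_value = lr$p_value, n_sim = lr$n_sim, adjusted_alpha = adj,
          decision = if (lr$p_value <= adj) "reject" else "retain")
      }
    }
    mean_table <- do.call(rbind, rows)
    rownames(mean_table) <- NULL
    write_csv_lf(mean_table, file.path(config$outdir, "mean_tests.csv"))
    # wide layout: one row per daytype x response, one column per setting
    wide <- stats::reshape(
      mean_table[, c("response", "daytype", "covariate_setting", "p_value")],
      idvar = c("daytype", "response"), timevar = "covariate_setting",
      direction = "wide")
    write_csv_lf(wide, file.path(config$outdir, "mean_tests_wide.csv"))
  }

  # 8. Normal-vs-DJD distribution tests ---------------------------------------
  dist_tests <- list()
  dist_rows <- list()
  if (all(c("Normal", "DJD") %in% groups)) {
    log("Normal-vs-DJD distribution tests (n_perm = %d)", config$n_perm)
    for (resp in c("activity", "intensity")) for (dt in c("weekday", "weekend")) {
      cm <- curves[[paste(resp, dt, sep = ".")]]
      dtst <- distribution_test(cm[groups == "Normal", , drop = FALSE],
                                cm[groups == "DJD", , drop = FALSE],
                                var_threshold = config$var_threshold,
                                n_perm = config$n_perm,
                                seed = stage_seed(config$seed, 41))
      dist_tests[[paste(resp, dt, sep = ".")]] <- dtst
      dist_rows[[paste(resp, dt)]] <- data.frame(
        comparison = "Normal-vs-DJD", response = resp, daytype = dt,
        covariate_setting = "distribution", statistic = min(dtst$table$A2),
        p_value = dtst$overall_p, n_sim = config$n_perm,
        adjusted_alpha = dtst$bonferroni_alpha, decision = dtst$decision)
    }
    dist_df <- do.call(rbind, dist_rows)
    rownames(dist_df) <- NULL
    write_csv_lf(dist_df, file.path(config$outdir, "distribution_tests.csv"))
  }

  # 9. manifest ---------------------------------------------------------------
  manifest <- list(
    package = "actifda",
    version = as.character(utils::packageVersion("actifda")),
    seed = config$seed, n_sim = config$n_sim, n_boot = config$n_boot,
    n_perm = config$n_perm, var_threshold = config$var_threshold,
    fpca_k = config$fpca_k,
    n_subjects = length(profiles),
    groups = as.list(table(groups)),
    decisions = list(
      transform = "ln(1+x) before 5-minute binning",
      quantile_type = 7,
      fpca_covariance = "empirical, unsmoothed",
      eigen_sign = "morning-window integral non-negative",
      fosr_smoothing = "per-term GCV; fixed during bootstrap",
      lrt = "working-Gaussian, unpenalized fixed basis (dim 15), resampling null",
      ad_ties = "seeded jitter 1e-9 x range",
      pooling = "unconditional with warning"))
  mcon <- file(file.path(config$outdir, "manifest.json"), open = "wb")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), mcon, sep = "\n")
  close(mcon)
  log("pipeline complete in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  invisible(list(config = config, profiles = profiles, covariates = covs,
                 curves = curves, truth = truth, pooling = pooling,
                 fpca = fpca_fits, score_correlations = score_cors,
                 fosr = fosr_fits, paired_tests = paired_tests,
                 mean_tests = mean_tests, mean_table = mean_table,
                 dist_tests = dist_tests))
}

#' Summarise a pipeline run as tables and figures
#'
#' Reads the CSV artifacts of a [run_pipeline()] output directory and writes
#' a compact summary table plus (optionally) PNG figures: group
#' activity/intensity profiles, FPCA modes of variation, and coefficient
#' panels with bootstrap bands.
#'
#' @param outdir a pipeline output directory.
#' @param plots also render PNG figures (default TRUE).
#' @return invisibly, the summary table (data.frame).
#' @export
make_report <- function(outdir, plots = TRUE) {
  need <- c("group_mean_profiles.csv", "fpca_variance.csv",
            "score_correlations.csv")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing)) {
    stop("incomplete result bundle; missing: ", paste(missing, collapse = ", "))
  }
  gm <- utils::read.csv(file.path(outdir, "group_mean_profiles.csv"))
  fv <- utils::read.csv(file.path(outdir, "fpca_variance.csv"))
  sc <- utils::read.csv(file.path(outdir, "score_correlations.csv"))
  tests <- list()
  for (f in c("pooling_check.csv", "paired_daytype_tests.csv",
              "mean_tests.csv", "distribution_tests.csv")) {
    p <- file.path(outdir, f)
    if (file.exists(p)) tests[[f]] <- utils::read.csv(p)
  }
  test_df <- if (length(tests)) do.call(rbind, c(tests, make.row.names = FALSE))
    else NULL
  if (!is.null(test_df)) {
    write_csv_lf(test_df, file.path(outdir, "report_tests.csv"))
  }
  peak_rows <- do.call(rbind, lapply(split(gm, gm[c("group", "daytype")],
                                           drop = TRUE),
    function(d) {
      half <- d[d$t_hours < 12, ]
      data.frame(group = d$group[1], daytype = d$daytype[1],
                 morning_peak_hour = half$t_hours[which.max(half$activity)],
                 mean_activity = mean(d$activity))
    }))
  rownames(peak_rows) <- NULL
  write_csv_lf(peak_rows, file.path(outdir, "report_peaks.csv"))
  if (plots) {
    grDevices::png(file.path(outdir, "group_profiles.png"), 900, 600)
    on.exit(grDevices::dev.off())
    groups <- unique(gm$group)
    old <- graphics::par(mfrow = c(1, 2))
    for (resp in c("activity", "intensity")) {
      first <- TRUE
      cols <- stats::setNames(seq_along(groups) + 1, groups)
      for (g in groups) for (dt in c("weekday", "weekend")) {
        d <- gm[gm$group == g & gm$daytype == dt, ]
        if (first) {
          plot(d$t_hours, d[[resp]], type = "l", col = cols[[g]],
               lty = if (dt == "weekday") 1 else 2, xlab = "hour of day",
               ylab = resp, ylim = range(gm[[resp]]))
          first <- FALSE
        } else {
          graphics::lines(d$t_hours, d[[resp]], col = cols[[g]],
                          lty = if (dt == "weekday") 1 else 2)
        }
      }
      graphics::legend("topleft", legend = groups, col = cols, lty = 1,
                       bty = "n")
    }
    graphics::par(old)
  }
  invisible(peak_rows)
}
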