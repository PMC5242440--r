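#' One subject-day of per-minute activity counts
#'
#' An `epoch_series` holds exactly one calendar day of 1440 per-minute
#' accelerometer counts for one subject (minute 0 = 00:00 local clock).
#'
#' @param cat_id character subject identifier.
#' @param date a `Date` (or string coercible to one).
#' @param counts integer vector of 1440 non-negative counts.
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(cat_id, date, counts) {
  stopifnot(is.character(cat_id), length(cat_id) == 1L)
  date <- as.Date(date)
  if (length(date) != 1L || is.na(date)) {
    stop("'date' must be a single valid calendar date")
  }
  if (length(counts) != N_MINUTES) {
    stop(sprintf("epoch series for %s/%s has %d minutes, expected 1440",
                 cat_id, format(date), length(counts)))
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (any(counts != round(counts))) {
    stop("counts must be integral")
  }
  structure(list(cat_id = cat_id, date = date,
                 counts = as.integer(round(counts))),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s %s (%s): 1440 minutes, total %d counts\n",
              x$cat_id, format(x$date), split_daytype(x$date),
              sum(x$counts)))
  invisible(x)
}

# minute index 0..1439 -> "HH:MM" labels (precomputed once)
minute_labels <- function() {
  sprintf("%02d:%02d", rep(0:23, each = 60), rep(0:59, times = 24))
}

#' Write per-minute counts to the long-format epoch CSV
#'
#' Columns `cat_id,date,time,count`, one row per minute, dates ISO-8601,
#' times `HH:MM`, rows ordered by (cat_id, date, minute), LF line endings.
#' The format is deliberately long/tidy rather than the device software's
#' wide actigram layout: unambiguous, streamable and diff-able.
#'
#' @param series a list of [epoch_series] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines("cat_id,date,time,count", con, sep = "\n")
  if (length(series) == 0L) {
    return(invisible(path))
  }
  ids <- vapply(series, function(s) s$cat_id, character(1))
  dates <- vapply(series, function(s) format(s$date), character(1))
  ord <- order(ids, dates, method = "radix")
  labs <- minute_labels()
  for (i in ord) {
    s <- series[[i]]
    writeLines(paste(s$cat_id, format(s$date), labs, s$counts, sep = ","),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read the long-format epoch CSV
#'
#' Rows are grouped into subject-days; only complete days (all 1440 distinct
#' minutes) are returned. Incomplete days are dropped and reported, never
#' silently repaired: the returned list carries a `validation_log` attribute
#' with one entry per dropped day, and a warning summarises the drops.
#'
#' @param path path to a CSV with columns `cat_id,date,time,count`.
#' @return a list of [epoch_series], with attribute `validation_log`
#'   (character vector, zero length when nothing was dropped).
#' @export
read_epoch_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "character", "numeric"),
                        check.names = FALSE)
  need <- c("cat_id", "date", "time", "count")
  if (!identical(names(df), need)) {
    stop("expected columns cat_id,date,time,count; found: ",
         paste(names(df), collapse = ","))
  }
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad)) {
    stop(sprintf("non-integer or negative count at data row %d (value '%s')",
                 bad[1], df$count[bad[1]]))
  }
  minute <- match(df$time, minute_labels()) - 1L
  if (anyNA(minute)) {
    stop(sprintf("unparseable time '%s' at data row %d",
                 df$time[which(is.na(minute))[1]], which(is.na(minute))[1]))
  }
  key <- paste(df$cat_id, df$date, sep = "\r")
  dup <- which(duplicated(paste(key, minute, sep = "\r")))
  if (length(dup)) {
    stop(sprintf("duplicated minute %s for %s on %s (data row %d)",
                 df$time[dup[1]], df$cat_id[dup[1]], df$date[dup[1]], dup[1]))
  }
  out <- list()
  log <- character(0)
  idx <- split(seq_len(nrow(df)), key)
  for (k in sort(names(idx))) {
    rows <- idx[[k]]
    id <- df$cat_id[rows[1]]
    date <- as.Date(df$date[rows[1]])
    if (is.na(date)) stop("unparseable date: ", df$date[rows[1]])
    if (length(rows) != N_MINUTES) {
      log <- c(log, sprintf("dropped incomplete day %s/%s: %d of 1440 minutes",
                            id, format(date), length(rows)))
      next
    }
    rows <- rows[order(minute[rows])]
    out[[length(out) + 1L]] <- epoch_series(id, date, df$count[rows])
  }
  if (length(log)) {
    warning(paste(log, collapse = "; "), call. = FALSE)
  }
  attr(out, "validation_log") <- log
  out
}

#' Write and read the subject covariate table
#'
#' Columns `cat_id,group,study,age,bcs,sex,tpain,tdjd,max_single_joint_pain`.
#' `group` is `Normal` or `DJD`; `study` the enrolment sub-study label;
#' `age` in years (> 0); `bcs` body condition score on the 9-point scale;
#' `tpain` total orthopedic pain score (0-80); `tdjd` total radiographic
#' joint-disease score (0-200); `max_single_joint_pain` the worst single-joint
#' pain score (0-4), used only for score categorisation.
#'
#' @param covariates a data.frame with the columns above.
#' @param path file path.
#' @return `write_covariate_csv` returns `path` invisibly;
#'   `read_covariate_csv` returns the validated data.frame.
#' @export
write_covariate_csv <- function(covariates, path) {
  covariates <- validate_covariates(covariates)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(covariates), collapse = ","), con, sep = "\n")
  rows <- do.call(paste, c(lapply(covariates, as.character), sep = ","))
  if (length(rows)) writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' @rdname write_covariate_csv
#' @export
read_covariate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(
    cat_id = "character", group = "character", study = "character",
    age = "numeric", bcs = "integer", sex = "character",
    tpain = "integer", tdjd = "integer", max_single_joint_pain = "integer"))
  validate_covariates(df)
}

validate_covariates <- function(df) {
  need <- c("cat_id", "group", "study", "age", "bcs", "sex", "tpain", "tdjd",
            "max_single_joint_pain")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$cat_id)) stop("duplicated cat_id in covariate table")
  if (any(df$age <= 0)) stop("age must be > 0 years")
  if (any(df$bcs < 1 | df$bcs > 9)) stop("bcs must lie in 1..9")
  if (any(df$tpain < 0 | df$tpain > 80)) stop("tpain must lie in 0..80")
  if (any(df$tdjd < 0 | df$tdjd > 200)) stop("tdjd must lie in 0..200")
  if (any(df$max_single_joint_pain < 0 | df$max_single_joint_pain > 4)) {
    stop("max_single_joint_pain must lie in 0..4")
  }
  df
}

#' Categorise total pain and total joint-disease scores
#'
#' Maps the orthopedic-exam total pain score (0-80) and the radiographic
#' total DJD score (0-200) onto the four ordinal severity categories used in
#' the field: negligible/normal, low, moderate, high. A total pain score of
#' 2 or less counts as negligible only if no single joint scored 2; if one
#' did, the cat is placed in the low category.
#'
#' @param tpain integer vector, total pain scores (0-80).
#' @param tdjd integer vector, total DJD scores (0-200).
#' @param max_single_joint_pain integer vector (0-4), worst single-joint pain
#'   score; default 0.
#' @return a data.frame with ordered factors `pain_category` and
#'   `djd_category` (levels negligible < low < moderate < high).
#' @examples
#' categorize_scores(tpain = 7, tdjd = 30)
#' categorize_scores(tpain = 2, tdjd = 2, max_single_joint_pain = 2)
#' @export
categorize_scores <- function(tpain, tdjd, max_single_joint_pain = 0L) {
  n <- max(length(tpain), length(tdjd), length(max_single_joint_pain))
  tpain <- rep_len(tpain, n)
  tdjd <- rep_len(tdjd, n)
  msjp <- rep_len(max_single_joint_pain, n)
  if (any(tpain < 0 | tpain > 80)) stop("tpain out of range 0..80")
  if (any(tdjd < 0 | tdjd > 200)) stop("tdjd out of range 0..200")
  if (any(msjp < 0 | msjp > 4)) stop("max_single_joint_pain out of range 0..4")
  lev <- c("negligible", "low", "moderate", "high")
  pain <- ifelse(tpain >= 10, "high",
          ifelse(tpain >= 5, "moderate",
          ifelse(tpain > 2, "low",
          ifelse(msjp >= 2, "low", "negligible"))))
  djd <- ifelse(tdjd >= 25, "high",
         ifelse(tdjd >= 13, "moderate",
         ifelse(tdjd >= 4, "low", "negligible")))
  data.frame(pain_category = factor(pain, levels = lev, ordered = TRUE),
             djd_category = factor(djd, levels = lev, ordered = TRUE))
}
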