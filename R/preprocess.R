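# Wear-time preprocessing: minute-level wearable records and evening surveys
# are reduced to one observation per person-day (life-satisfaction mean and
# steps per valid wear-hour).

#' Classify valid wear-time minutes
#'
#' A minute counts as valid wear time when it carries either a non-zero step
#' count or a heart-rate reading, and the wearer is not asleep (sleep minutes
#' are excluded from wear time regardless of signal).
#'
#' @param minutes data frame with columns `person_id`, `timestamp`, `steps`,
#'   `hr_present`, `asleep`.
#' @return the input with an added logical column `valid`.
#' @export
classify_valid_minutes <- function(minutes) {
  req <- c("person_id", "timestamp", "steps", "hr_present", "asleep")
  missing_cols <- setdiff(req, names(minutes))
  if (length(missing_cols)) {
    stop("minutes table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(minutes$steps < 0, na.rm = TRUE)) stop("negative step counts")
  key <- paste(minutes$person_id, format(minutes$timestamp, "%Y-%m-%d %H:%M"))
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate person-minute record(s), e.g. ", key[which(dup)[1]])
  }
  minutes$valid <- (minutes$steps > 0 | minutes$hr_present) & !minutes$asleep
  minutes
}

#' Daily physical-activity aggregation
#'
#' Aggregates classified minute records to one row per person-day: wear hours
#' (valid minutes / 60), total wake steps over valid minutes, and the daily
#' activity measure `pa_rate` = total wake steps divided by wear hours.  Days
#' without any valid minute get `pa_rate = NA` and `wear_hours = 0`.
#'
#' @param minutes minute table (will be passed through
#'   [classify_valid_minutes()] if it has no `valid` column).
#' @return data frame `person_id`, `date`, `pa_rate`, `wear_hours`,
#'   `n_valid_minutes`.
#' @export
aggregate_daily_pa <- function(minutes) {
  if (is.null(minutes$valid)) minutes <- classify_valid_minutes(minutes)
  dt <- data.table::as.data.table(minutes)
  dt[, date := as.Date(timestamp)]
  out <- dt[, .(
    n_valid_minutes = sum(valid),
    steps_total = sum(steps[valid])
  ), by = .(person_id, date)]
  out[, wear_hours := n_valid_minutes / 60]
  out[, pa_rate := ifelse(n_valid_minutes > 0, steps_total / wear_hours, NA_real_)]
  as.data.frame(out[order(person_id, date),
                    .(person_id, date, pa_rate, wear_hours,
                      n_valid_minutes = as.integer(n_valid_minutes))])
}

#' Daily life-satisfaction score
#'
#' The daily life-satisfaction value is the arithmetic mean of the two 0-100
#' evening slider items.  By default a day with only one answered item is
#' treated as missing (the measure is defined as a two-item average);
#' `single_item = "use"` falls back to the available item instead.
#'
#' @param surveys data frame with `person_id`, `date`, `ls_item1`, `ls_item2`.
#' @param single_item policy for days with exactly one answered item:
#'   `"missing"` (default) or `"use"`.
#' @return data frame `person_id`, `date`, `ls_mean`.
#' @export
daily_ls <- function(surveys, single_item = c("missing", "use")) {
  single_item <- match.arg(single_item)
  items <- cbind(surveys$ls_item1, surveys$ls_item2)
  if (any(items < 0 | items > 100, na.rm = TRUE)) {
    stop("life-satisfaction items must lie on [0, 100]")
  }
  both <- rowSums(!is.na(items))
  ls <- rowMeans(items)
  if (single_item == "use") {
    one <- both == 1L
    ls[one] <- rowMeans(items, na.rm = TRUE)[one]
  }
  data.frame(person_id = surveys$person_id, date = as.Date(surveys$date),
             ls_mean = ls, stringsAsFactors = FALSE)
}

#' Build the daily observation table
#'
#' Joins the daily physical-activity aggregate with the daily
#' life-satisfaction score on person and date (full outer join: a day present
#' in either source appears in the output).  An optional minimum-wear-hours
#' threshold invalidates the activity measure on days with too little wear
#' time (default 0: no threshold).
#'
#' @param minutes minute-level wearable records.
#' @param surveys evening survey records.
#' @param min_wear_hours days with fewer valid wear hours than this get
#'   `pa_rate = NA` (sensitivity-analysis handle; default 0).
#' @param single_item see [daily_ls()].
#' @return data frame `person_id`, `date`, `ls_mean`, `pa_rate`,
#'   `wear_hours`, `n_valid_minutes`.
#' @export
build_daily <- function(minutes, surveys, min_wear_hours = 0,
                        single_item = "missing") {
  pa <- aggregate_daily_pa(minutes)
  ls <- daily_ls(surveys, single_item)
  out <- merge(pa, ls, by = c("person_id", "date"), all = TRUE)
  out$wear_hours[is.na(out$wear_hours)] <- 0
  out$n_valid_minutes[is.na(out$n_valid_minutes)] <- 0L
  if (min_wear_hours > 0) {
    out$pa_rate[out$wear_hours < min_wear_hours] <- NA_real_
  }
  out <- out[order(out$person_id, out$date),
             c("person_id", "date", "ls_mean", "pa_rate",
               "wear_hours", "n_valid_minutes")]
  rownames(out) <- NULL
  out
}
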