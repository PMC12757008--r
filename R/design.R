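#' Response transforms and model-ready dataset construction
#'
#' Daily life satisfaction (the mean of two 0-100 slider items) is bounded on
#' both sides and daily physical activity (steps per valid wear-hour) is
#' non-negative and right-skewed; both are mapped to the real line before they
#' enter the Gaussian vector-autoregressive model.  `transform_ls()` shifts the
#' 0-100 scale by one unit, divides by 102 so values fall strictly inside
#' (0, 1), and applies the logit; `transform_pa()` adds one (so zero activity
#' maps to zero) and takes the natural logarithm.  Both transforms are strictly
#' increasing bijections onto their range and have exact inverses,
#' [inv_transform_ls()] and [inv_transform_pa()].
#'
#' @param ls_mean numeric vector of daily life-satisfaction means on \[0, 100\].
#'   `NA` entries pass through as `NA`.
#' @return numeric vector on the transformed (real-line) scale.
#' @examples
#' transform_ls(50)          # exactly 0: (50 + 1)/102 = 1/2
#' transform_pa(exp(1) - 1)  # exactly 1
#' inv_transform_ls(transform_ls(87.5))
#' @export
transform_ls <- function(ls_mean) {
  bad <- !is.na(ls_mean) & (ls_mean < 0 | ls_mean > 100)
  if (any(bad)) {
    stop("ls_mean out of [0, 100]: ", paste(utils::head(ls_mean[bad], 3), collapse = ", "))
  }
  p <- (ls_mean + 1) / 102
  log(p) - log1p(-p)
}

#' @rdname transform_ls
#' @param L numeric vector on the logit scale.
#' @export
inv_transform_ls <- function(L) {
  102 * stats::plogis(L) - 1
}

#' @rdname transform_ls
#' @param pa_rate numeric vector of non-negative daily step rates
#'   (steps per valid wear-hour).
#' @export
transform_pa <- function(pa_rate) {
  bad <- !is.na(pa_rate) & pa_rate < 0
  if (any(bad)) {
    stop("pa_rate must be non-negative; got ", paste(utils::head(pa_rate[bad], 3), collapse = ", "))
  }
  log1p(pa_rate)
}

#' @rdname transform_ls
#' @param P numeric vector on the log scale.
#' @export
inv_transform_pa <- function(P) {
  expm1(P)
}

#' Calendar utilities
#'
#' `inclusive_day_count()` counts calendar dates from `start` through `end`,
#' both endpoints included.  `weekday_occurrences()` tabulates how often each
#' weekday (Monday through Sunday) occurs in that window; over any inclusive
#' span the counts differ by at most one.
#'
#' @param start,end `Date` scalars (or strings coercible via `as.Date`),
#'   `start <= end`.
#' @return `inclusive_day_count()`: a single integer.
#'   `weekday_occurrences()`: a named integer vector `Mon` ... `Sun`.
#' @examples
#' inclusive_day_count("2019-04-19", "2022-08-31")  # 1231
#' weekday_occurrences("2019-04-19", "2019-04-25")
#' @export
inclusive_day_count <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("start and end must be valid dates")
  if (start > end) stop("start date is after end date")
  as.integer(end - start) + 1L
}

#' @rdname inclusive_day_count
#' @export
weekday_occurrences <- function(start, end) {
  n <- inclusive_day_count(start, end)
  days <- seq(as.Date(start), by = "day", length.out = n)
  idx <- weekday_index(days)
  counts <- tabulate(idx, nbins = 7L)
  names(counts) <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  counts
}

# Monday = 1 ... Sunday = 7, independent of locale and time zone
# (1970-01-01 was a Thursday).
weekday_index <- function(dates) {
  ((as.integer(as.Date(dates)) + 3L) %% 7L) + 1L
}

# Internal covariate layout shared by the generator and the encoder.
# The reference levels are: Monday, January, female, low-pollution region,
# non-university education, below-average SES.
covariate_names <- function() {
  c("intercept", "day_in_study", "age", "gender_male", "region_high",
    paste0("wd_", c("tue", "wed", "thu", "fri", "sat", "sun")),
    paste0("mon_", c("feb", "mar", "apr", "may", "jun", "jul",
                     "aug", "sep", "oct", "nov", "dec")),
    "edu_university", "ses_average", "ses_above")
}

covariate_levels <- function() {
  list(
    gender    = c("female", "male"),
    region    = c("low_pollution", "high_pollution"),
    education = c("non_university", "university"),
    ses       = c("below_average", "average", "above_average")
  )
}

check_levels <- function(participants) {
  lv <- covariate_levels()
  for (nm in names(lv)) {
    vals <- as.character(participants[[nm]])
    bad <- setdiff(unique(vals), lv[[nm]])
    if (length(bad)) {
      stop("unseen ", nm, " level(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Encode mean-model covariates
#'
#' Builds the covariate row for every person-day: an intercept, day in study
#' (days since that person's own first study day), age, indicators for gender
#' (male vs female), region (high- vs low-pollution), weekday (Tuesday through
#' Sunday vs Monday), month (February through December vs January), education
#' (university vs not) and socioeconomic status (average and above-average vs
#' below-average).  Continuous covariates (day in study, age) and the exercise
#' identity moderator are standardized with the sample mean and SD recorded in
#' the returned codebook; 0/1 indicators are left unscaled.  Supplying an
#' existing `codebook` re-applies its stored centering, which is what makes
#' coefficients rescalable to the original covariate scale bit-exactly.
#'
#' @param participants data frame with columns `person_id`, `age`, `gender`,
#'   `region`, `education`, `ses`, `exid`.
#' @param rows data frame with columns `person_id` and `date` (one row per
#'   person-day), plus `entry_date` or an attached calendar first day.
#' @param entry_dates optional named vector/data frame of each person's first
#'   study date; defaults to the earliest `date` per person in `rows`.
#' @param codebook optional codebook from a previous call (reuse for new data).
#' @param standardize logical; `FALSE` returns raw-scale covariates (used by
#'   the simulator, where the true coefficients live on the original scale).
#' @return list with `X` (numeric matrix, one row per input row, columns
#'   [covariate_names()]), `exid_std` (per-row standardized moderator) and
#'   `codebook`.
#' @export
encode_covariates <- function(participants, rows, entry_dates = NULL,
                              codebook = NULL, standardize = TRUE) {
  check_levels(participants)
  stopifnot(all(rows$person_id %in% participants$person_id))
  pidx <- match(rows$person_id, participants$person_id)
  dates <- as.Date(rows$date)

  if (is.null(entry_dates)) {
    if (!is.null(rows$entry_date)) {
      entry <- as.Date(rows$entry_date)
    } else {
      first <- tapply(as.integer(dates), rows$person_id, min)
      entry <- as.Date(as.integer(first[as.character(rows$person_id)]),
                       origin = "1970-01-01")
    }
  } else {
    entry <- as.Date(entry_dates[as.character(rows$person_id)],
                     origin = "1970-01-01")
  }
  day_in_study <- as.numeric(dates - entry)
  if (any(day_in_study < 0)) stop("some dates precede the person's entry date")

  wd <- weekday_index(dates)
  mo <- as.integer(format(dates, "%m"))

  n <- nrow(rows)
  X <- matrix(0, n, length(covariate_names()),
              dimnames = list(NULL, covariate_names()))
  X[, "intercept"] <- 1
  X[, "day_in_study"] <- day_in_study
  X[, "age"] <- participants$age[pidx]
  X[, "gender_male"] <- as.numeric(participants$gender[pidx] == "male")
  X[, "region_high"] <- as.numeric(participants$region[pidx] == "high_pollution")
  for (k in 2:7) X[, 4L + k] <- as.numeric(wd == k)     # wd_tue..wd_sun
  for (k in 2:12) X[, 10L + k] <- as.numeric(mo == k)   # mon_feb..mon_dec
  X[, "edu_university"] <- as.numeric(participants$education[pidx] == "university")
  X[, "ses_average"] <- as.numeric(participants$ses[pidx] == "average")
  X[, "ses_above"] <- as.numeric(participants$ses[pidx] == "above_average")

  exid <- participants$exid[pidx]

  if (is.null(codebook)) {
    sd0 <- function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) 1 else s
    }
    codebook <- list(
      continuous = list(
        day_in_study = list(mean = mean(day_in_study), sd = sd0(day_in_study)),
        age          = list(mean = mean(participants$age), sd = sd0(participants$age)),
        exid         = list(mean = mean(participants$exid), sd = sd0(participants$exid))
      ),
      levels = covariate_levels(),
      columns = covariate_names()
    )
    class(codebook) <- "bvb_codebook"
  }

  exid_std <- (exid - codebook$continuous$exid$mean) / codebook$continuous$exid$sd
  if (standardize) {
    for (nm in c("day_in_study", "age")) {
      cb <- codebook$continuous[[nm]]
      X[, nm] <- (X[, nm] - cb$mean) / cb$sd
    }
  }
  list(X = X, exid_std = exid_std, codebook = codebook)
}

#' Assemble the model-ready dataset
#'
#' Joins daily observations onto the burst calendar (so skipped days stay in
#' the series as missing rows), applies the response transforms, encodes and
#' standardizes covariates, and indexes rows by person, burst and day within
#' burst.  The result is the single container consumed by [log_likelihood()]
#' and [fit_bvar()].
#'
#' @param daily daily observation table from [build_daily()] (or any data
#'   frame with `person_id`, `date`, `ls_mean`, `pa_rate`).
#' @param participants participant table (see [simulate_population()]).
#' @param calendar burst calendar from [burst_calendar()].
#' @param codebook optional codebook to reuse (see [encode_covariates()]).
#' @return object of class `bvb_dataset`: a list with elements `data` (data
#'   frame: `person_id`, `burst`, `day`, `date`, `L`, `P`, `lag_available`),
#'   `X` (covariate matrix), `exid_std` (per-person standardized moderator,
#'   named by person), `codebook`, and `persons` (person ids in model order).
#' @export
build_model_dataset <- function(daily, participants, calendar, codebook = NULL) {
  grid <- calendar_grid(calendar)
  key_g <- paste(grid$person_id, grid$date)
  key_d <- paste(daily$person_id, as.Date(daily$date))
  if (anyDuplicated(key_d)) stop("daily table has duplicated person-date rows")
  m <- match(key_g, key_d)

  ls <- daily$ls_mean[m]
  pa <- daily$pa_rate[m]
  df <- data.frame(
    person_id = grid$person_id,
    burst = grid$burst,
    day = grid$day,
    date = grid$date,
    L = transform_ls(ls),
    P = transform_pa(pa),
    lag_available = grid$day > 1L,
    stringsAsFactors = FALSE
  )

  entry <- tapply(as.integer(grid$date), grid$person_id, min)
  enc <- encode_covariates(participants, df, entry_dates = entry,
                           codebook = codebook, standardize = TRUE)

  persons <- unique(df$person_id)
  exid_std <- enc$exid_std[match(persons, df$person_id)]
  names(exid_std) <- persons

  out <- list(data = df, X = enc$X, exid_std = exid_std,
              codebook = enc$codebook, persons = persons)
  class(out) <- "bvb_dataset"
  out
}

# Expand a burst calendar into one row per person-burst-day.
calendar_grid <- function(calendar) {
  stopifnot(all(c("person_id", "burst", "start") %in% names(calendar)))
  len <- if (!is.null(calendar$length)) calendar$length else rep(14L, nrow(calendar))
  n <- sum(len)
  person_id <- rep(calendar$person_id, len)
  burst <- rep(calendar$burst, len)
  day <- unlist(lapply(len, seq_len), use.names = FALSE)
  date <- as.Date(rep(as.Date(calendar$start), len)) + (day - 1L)
  o <- order(person_id, burst, day)
  data.frame(person_id = person_id[o], burst = burst[o], day = day[o],
             date = date[o], stringsAsFactors = FALSE)
}

#' @export
print.bvb_dataset <- function(x, ...) {
  d <- x$data
  cat("<bvb_dataset> ", length(x$persons), " persons, ",
      length(unique(d$burst)), " bursts, ", nrow(d), " person-days\n", sep = "")
  cat("  observed L: ", sum(!is.na(d$L)), "  observed P: ", sum(!is.na(d$P)),
      "  covariates: ", ncol(x$X), "\n", sep = "")
  invisible(x)
}
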