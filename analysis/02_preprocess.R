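#!/usr/bin/env Rscript
# Step 2 — wear-time preprocessing of the raw streams.
#
# Reads the minute-level wearable records and the evening surveys written by
# step 1, classifies valid wear minutes (non-zero steps or a heart-rate
# reading, sleep excluded), aggregates steps per valid wear-hour and the
# two-item life-satisfaction mean per day, and checks the result against the
# generator's own daily table (they must agree exactly: the generator and
# the preprocessor are two routes to the same daily quantities).

library(burstvar)

minutes <- read.csv("results/study/minutes.csv", stringsAsFactors = FALSE)
minutes$timestamp <- as.POSIXct(minutes$timestamp,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
minutes$hr_present <- as.logical(minutes$hr_present)
minutes$asleep <- as.logical(minutes$asleep)
surveys <- read.csv("results/study/surveys.csv", stringsAsFactors = FALSE)

daily <- build_daily(minutes, surveys)
write.csv(daily, "results/daily_preprocessed.csv", row.names = FALSE)

gen <- read.csv("results/study/daily.csv", stringsAsFactors = FALSE)
key <- paste(gen$person_id, gen$date)
m <- match(key, paste(daily$person_id, daily$date))
obs <- !is.na(gen$ls_mean)
cat("days preprocessed:        ", nrow(daily), "\n")
cat("max |LS(pre) - LS(gen)|:  ",
    max(abs(daily$ls_mean[m][obs] - gen$ls_mean[obs])), "\n")
obs_pa <- !is.na(gen$pa_rate)
cat("max |PA(pre) - PA(gen)|:  ",
    max(abs(daily$pa_rate[m][obs_pa] - gen$pa_rate[obs_pa])), "\n")
cat("mean wear hours:          ",
    sprintf("%.2f", mean(daily$wear_hours[daily$wear_hours > 0])), "\n")
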