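## Unit conventions, centralized.
##
## Beat-level dynamics: volumes in mL, time in seconds, pressures in mmHg,
##   resistances in mmHg*s/mL, compliances in mL/mmHg.
## Renal flows: mL/min (water), mmol/min (sodium); upstream renal resistances
##   in mmHg*min/L (the units Table-style parameters are quoted in).
## Slow (day-scale) integration: time in days; all slow derivatives are
##   converted to per-day at the point of assembly.

MIN_PER_DAY <- 1440
SEC_PER_MIN <- 60

#' Convert a per-minute rate to a per-day rate
#' @param x rate per minute
#' @return rate per day
#' @keywords internal
per_min_to_per_day <- function(x) x * MIN_PER_DAY
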