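# Exact arithmetic decomposition of Date vectors (civil-from-days
# algorithm), avoiding as.POSIXlt in hot per-day loops over century-scale
# records. Verified against as.POSIXlt in the test suite.
date_parts <- function(dates) {
  z <- as.integer(unclass(as.Date(dates))) + 719468L
  era <- (z - ifelse(z < 0L, 146096L, 0L)) %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  y <- yoe + era * 400L
  doy_mar <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy_mar + 2L) %/% 153L
  day <- doy_mar - (153L * mp + 2L) %/% 5L + 1L
  month <- mp + ifelse(mp < 10L, 3L, -9L)
  year <- y + (month <= 2L)
  jan1 <- days_from_civil(year, 1L, 1L)
  list(year = year, month = month, day = day,
       doy = as.integer(unclass(as.Date(dates))) - jan1 + 1L)
}

# Days since 1970-01-01 for a civil (year, month, day); inverse of
# date_parts, vectorised.
days_from_civil <- function(year, month, day) {
  y <- year - (month <= 2L)
  era <- (y - ifelse(y < 0L, 399L, 0L)) %/% 400L
  yoe <- y - era * 400L
  mp <- month + ifelse(month > 2L, -3L, 9L)
  doy_mar <- (153L * mp + 2L) %/% 5L + day - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy_mar
  era * 146097L + doe - 719468L
}
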