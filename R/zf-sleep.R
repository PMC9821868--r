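#' Score larval zebrafish sleep from movement-seconds traces
#'
#' Any one-minute period with strictly less than `threshold_sec` seconds of
#' total movement is one minute of sleep.
#'
#' @param movement_sec Seconds of movement per minute, each in `[0, 60]`.
#' @param threshold_sec Sleep threshold; default 0.5 s (strict `<`).
#' @return Logical vector (TRUE = sleep minute).
#' @export
score_zf_sleep <- function(movement_sec, threshold_sec = 0.5) {
  if (anyNA(movement_sec) || any(movement_sec < 0 | movement_sec > 60))
    stop("movement seconds per minute must lie in [0, 60]")
  movement_sec < threshold_sec
}

#' Zebrafish sleep bouts and per-phase bout metrics
#'
#' A bout is any maximal run of sleep minutes (length >= 1). A bout is
#' attributed to the phase containing its start minute.
#'
#' @param state Logical sleep state from [score_zf_sleep()].
#' @param phase Optional character vector (e.g. `"day"`/`"night"`) aligned
#'   with `state`; default one phase `"all"`.
#' @return List: `bouts` (data.frame `start_minute`, `duration_min`,
#'   `phase`) and `by_phase` (`phase`, `bout_number`, `mean_bout_length_min`;
#'   the mean is NA when a phase has no bouts).
#' @export
zf_bouts <- function(state, phase = NULL) {
  if (is.null(phase)) phase <- rep("all", length(state))
  stopifnot(length(phase) == length(state))
  r <- rle(as.logical(state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  bouts <- data.frame(start_minute = starts[keep],
                      duration_min = r$lengths[keep],
                      phase = phase[starts[keep]],
                      stringsAsFactors = FALSE)
  phases <- unique(phase)
  by_phase <- do.call(rbind, lapply(phases, function(p) {
    d <- bouts$duration_min[bouts$phase == p]
    data.frame(phase = p, bout_number = length(d),
               mean_bout_length_min = if (length(d)) mean(d) else NA_real_)
  }))
  rownames(by_phase) <- NULL
  list(bouts = bouts, by_phase = by_phase)
}

#' Waking activity, seconds per awake minute per hour
#'
#' For every clock hour, total movement over waking minutes divided by the
#' number of waking minutes; hours with no waking minute are undefined and
#' excluded. Both the mean over defined hours (the headline reduction) and
#' the global mean over all waking minutes are returned.
#'
#' @param movement_sec Movement-seconds trace.
#' @param state Aligned sleep state.
#' @param hour Optional hour index per minute; defaults to consecutive
#'   60-minute blocks from the trace start.
#' @return List: `per_hour` (hour, wake_minutes, waking_activity),
#'   `mean_hourly` (mean over defined hours), `overall` (all waking minutes
#'   pooled).
#' @export
zf_waking_activity <- function(movement_sec, state, hour = NULL) {
  if (length(movement_sec) != length(state))
    stop("trace and state lengths differ")
  if (is.null(hour)) hour <- (seq_along(state) - 1L) %/% 60L
  wake <- !state
  per_hour <- do.call(rbind, lapply(unique(hour), function(h) {
    sel <- hour == h & wake
    data.frame(hour = h, wake_minutes = sum(sel),
               waking_activity = if (any(sel)) sum(movement_sec[sel]) / sum(sel)
                                 else NA_real_)
  }))
  rownames(per_hour) <- NULL
  list(per_hour = per_hour,
       mean_hourly = mean(per_hour$waking_activity, na.rm = TRUE),
       overall = if (any(wake)) sum(movement_sec[wake]) / sum(wake) else NA_real_)
}

#' Two-group comparison with optional Welch correction
#'
#' Two-sample t-test on per-larva values reporting the mean difference
#' (`mean(a) - mean(b)`) with its standard error. The Welch form (default)
#' uses the Welch-Satterthwaite degrees of freedom; the pooled form uses
#' `nA + nB - 2`. With `pretest = TRUE` an F-test of variance equality picks
#' the pooled form when variances are not detectably unequal (p >= 0.05).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's correction; default TRUE.
#' @param pretest Gate Welch vs pooled on a variance-equality F-test.
#' @return Object of class `zf_compare`: `mean_difference`, `se`,
#'   `t_statistic`, `df`, `p_value`, `correction`, `n`.
#' @examples
#' zf_group_compare(c(1, 2, 3), c(2, 4, 6))
#' @export
zf_group_compare <- function(a, b, welch = TRUE, pretest = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (pretest) {
    f <- va / vb
    pf2 <- 2 * min(stats::pf(f, na - 1, nb - 1),
                   1 - stats::pf(f, na - 1, nb - 1))
    welch <- pf2 < 0.05
  }
  diff <- mean(a) - mean(b)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(mean_difference = diff, se = se, t_statistic = t, df = df,
                 p_value = p, correction = if (welch) "welch" else "pooled",
                 n = c(na, nb)),
            class = "zf_compare")
}

#' @export
print.zf_compare <- function(x, ...) {
  cat(sprintf(
    "<zf_compare> mean difference: %.3g ± %.3g, t_%.4g = %.4g, P = %.3g (%s)\n",
    x$mean_difference, x$se, x$df, x$t_statistic, x$p_value, x$correction))
  invisible(x)
}

#' CRISPR mutation-efficiency inclusion filter
#'
#' Efficiency is the ratio of headloop to standard PCR product intensity; a
#' larva is included when efficiency is strictly greater than `cutoff`.
#'
#' @param headloop_intensity,standard_intensity Band intensities (headloop
#'   >= 0, standard > 0); vectorized.
#' @param cutoff Inclusion threshold; default 0.9 (strict `>`).
#' @param larva_id Optional ids.
#' @return data.frame: `larva_id`, `headloop_intensity`,
#'   `standard_intensity`, `efficiency`, `included`.
#' @export
mutation_efficiency <- function(headloop_intensity, standard_intensity,
                                cutoff = 0.9,
                                larva_id = seq_along(headloop_intensity)) {
  if (any(standard_intensity <= 0)) stop("standard_intensity must be > 0")
  if (any(headloop_intensity < 0)) stop("headloop_intensity must be >= 0")
  eff <- headloop_intensity / standard_intensity
  data.frame(larva_id = larva_id, headloop_intensity = headloop_intensity,
             standard_intensity = standard_intensity, efficiency = eff,
             included = eff > cutoff)
}

#' Parse "HH:MM" clock time to minutes after midnight
#' @param x Character vector like `"09:00"`.
#' @return Integer minutes in `[0, 1440)`.
#' @export
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed clock time: ", paste(x[bad], collapse = ", "))
  h <- as.integer(vapply(m, `[`, "", 2L))
  mi <- as.integer(vapply(m, `[`, "", 3L))
  if (any(h > 23 | mi > 59)) stop("clock time out of range")
  h * 60L + mi
}

#' Day/night phase labels for a zebrafish trace
#'
#' Day is lights-on (default 09:00) to lights-off (default 23:00); night is
#' the complement (the 14:10 rearing cycle).
#'
#' @param n Number of minutes.
#' @param clock_start_min Minute-of-day of the first sample.
#' @param lights_on,lights_off Clock times ("HH:MM" or minutes).
#' @return Character vector `"day"`/`"night"` of length `n`.
#' @export
zf_phase <- function(n, clock_start_min = 540L, lights_on = "09:00",
                     lights_off = "23:00") {
  on <- if (is.character(lights_on)) parse_clock(lights_on) else lights_on
  off <- if (is.character(lights_off)) parse_clock(lights_off) else lights_off
  mod <- (clock_start_min + seq_len(n) - 1L) %% 1440L
  ifelse(mod >= on & mod < off, "day", "night")
}

#' Trim the acclimation period from a zebrafish trace
#'
#' Drops all minutes before the first lights-on boundary at or after the
#' recording start and keeps exactly `analysis_days` full day/night cycles.
#'
#' @param movement_sec Movement-seconds trace.
#' @param clock_start_min Minute-of-day of the first sample (e.g.
#'   `parse_clock("14:00")`).
#' @param analysis_days Number of full cycles to keep; default 2.
#' @param lights_on Clock time of lights-on ("HH:MM" or minutes).
#' @return List: `movement_sec` (trimmed), `clock_start_min` (= lights-on).
#' @export
trim_acclimation <- function(movement_sec, clock_start_min,
                             analysis_days = 2L, lights_on = "09:00") {
  on <- if (is.character(lights_on)) parse_clock(lights_on) else lights_on
  offset <- (on - clock_start_min) %% 1440L
  need <- offset + analysis_days * 1440L
  if (length(movement_sec) < need)
    stop(sprintf("trace too short: need %d minutes, have %d",
                 need, length(movement_sec)))
  list(movement_sec = movement_sec[(offset + 1L):need],
       clock_start_min = on)
}

#' Per-larva zebrafish sleep summary
#'
#' Scores a (trimmed) trace and tabulates cumulative day and night sleep
#' (summed across the analyzed cycles), day/night bout counts, night mean
#' bout length, and waking activity.
#'
#' @param movement_sec Trimmed movement-seconds trace (see
#'   [trim_acclimation()]).
#' @param clock_start_min Minute-of-day of the first sample; default 540
#'   (09:00).
#' @param threshold_sec Sleep threshold; default 0.5 s.
#' @param lights_on,lights_off Phase boundaries.
#' @return One-row data.frame: `day_sleep_min`, `night_sleep_min`,
#'   `day_bout_number`, `night_bout_number`, `night_mean_bout_length_min`,
#'   `waking_activity` (mean of hourly values), `waking_activity_overall`.
#' @export
summarize_zf_sleep <- function(movement_sec, clock_start_min = 540L,
                               threshold_sec = 0.5, lights_on = "09:00",
                               lights_off = "23:00") {
  state <- score_zf_sleep(movement_sec, threshold_sec)
  phase <- zf_phase(length(state), clock_start_min, lights_on, lights_off)
  b <- zf_bouts(state, phase)
  wa <- zf_waking_activity(movement_sec, state)
  bp <- function(p, col) {
    v <- b$by_phase[b$by_phase$phase == p, col]
    if (length(v)) v else if (col == "bout_number") 0L else NA_real_
  }
  data.frame(
    day_sleep_min = sum(state & phase == "day"),
    night_sleep_min = sum(state & phase == "night"),
    day_bout_number = bp("day", "bout_number"),
    night_bout_number = bp("night", "bout_number"),
    night_mean_bout_length_min = bp("night", "mean_bout_length_min"),
    waking_activity = wa$mean_hourly,
    waking_activity_overall = wa$overall)
}
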