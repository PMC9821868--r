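#' Score Drosophila sleep from per-minute activity counts
#'
#' A minute is immobile when its beam-crossing count is zero; a maximal run of
#' immobile minutes of at least `immobility_min` minutes is a sleep bout, and
#' every minute inside a bout is a sleep minute. A run truncated by the trace
#' end still counts if its total length reaches the threshold.
#'
#' @param counts Integer vector of beam crossings per minute (>= 0).
#' @param immobility_min Minimum immobility run length, minutes; default 5.
#' @return List with `state` (logical, TRUE = asleep, same length as
#'   `counts`) and `bouts` (data.frame `start_minute` (1-based),
#'   `duration_min`).
#' @examples
#' score_fly_sleep(c(1, 0, 0, 0, 0, 0, 1))$bouts
#' @export
score_fly_sleep <- function(counts, immobility_min = 5L) {
  if (length(counts) == 0L) stop("empty activity trace")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be >= 0")
  if (immobility_min < 1L) stop("immobility_min must be >= 1")
  r <- rle(counts == 0)
  is_bout <- r$values & r$lengths >= immobility_min
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  state <- logical(length(counts))
  for (i in which(is_bout)) state[starts[i]:ends[i]] <- TRUE
  list(state = state,
       bouts = data.frame(start_minute = starts[is_bout],
                          duration_min = r$lengths[is_bout]))
}

fly_phase <- function(n, t0_zt = 0L, lights_off_zt = 720L) {
  zt <- (t0_zt + seq_len(n) - 1L) %% 1440L
  ifelse(zt < lights_off_zt, "day", "night")
}

#' Summarize per-animal fly sleep architecture
#'
#' Day is ZT0-ZT720 (lights on), night ZT720-ZT1440. Sleep minutes are
#' attributed to phases minute by minute (a bout spanning ZT720 contributes
#' to both); bout counts are attributed to the phase of the bout's start
#' minute. Multi-day traces are averaged per day. Waking activity is total
#' counts over waking minutes divided by the number of waking minutes;
#' with zero waking minutes it is NA and `waking_undefined` is TRUE.
#'
#' @param counts Per-minute activity counts.
#' @param scored Optional [score_fly_sleep()] result for `counts`.
#' @param t0_zt ZT minute of the first sample (default 0, lights-on).
#' @param immobility_min Passed to [score_fly_sleep()] when `scored` is NULL.
#' @return One-row data.frame: `total_sleep_min`, `day_sleep_min`,
#'   `night_sleep_min` (all per day), `bout_number`, `day_bout_number`,
#'   `night_bout_number` (per day), `mean_bout_length_min`,
#'   `waking_activity`, `waking_undefined`, `n_days`.
#' @export
summarize_fly_sleep <- function(counts, scored = NULL, t0_zt = 0L,
                                immobility_min = 5L) {
  if (is.null(scored)) scored <- score_fly_sleep(counts, immobility_min)
  state <- scored$state
  if (length(state) != length(counts)) stop("state and trace lengths differ")
  n_days <- length(counts) / 1440
  phase <- fly_phase(length(counts), t0_zt)
  wake <- !state
  bout_phase <- phase[scored$bouts$start_minute]
  data.frame(
    total_sleep_min = sum(state) / n_days,
    day_sleep_min = sum(state & phase == "day") / n_days,
    night_sleep_min = sum(state & phase == "night") / n_days,
    bout_number = nrow(scored$bouts) / n_days,
    day_bout_number = sum(bout_phase == "day") / n_days,
    night_bout_number = sum(bout_phase == "night") / n_days,
    mean_bout_length_min = if (nrow(scored$bouts)) mean(scored$bouts$duration_min) else NA_real_,
    waking_activity = if (any(wake)) sum(counts[wake]) / sum(wake) else NA_real_,
    waking_undefined = !any(wake),
    n_days = n_days)
}

#' Flag dead or escaped animals
#'
#' An animal is flagged when its trace ends with an all-zero run of at least
#' `trailing_min` minutes (a full day by default) — indistinguishable from
#' sleep by the counter, but standard activity-monitor practice excludes it.
#'
#' @param counts Per-minute activity counts.
#' @param trailing_min Minimum terminal zero run to flag; default 1440.
#' @return TRUE if flagged.
#' @export
flag_dead <- function(counts, trailing_min = 1440L) {
  nz <- which(counts > 0)
  trailing <- if (length(nz)) length(counts) - max(nz) else length(counts)
  trailing >= trailing_min
}

#' Call RNAi screen hits from total-sleep summaries
#'
#' The reference band is the pooled per-animal mean plus/minus `k_sd` pooled
#' per-animal standard deviations of total sleep. A line is called `long`
#' when its line-mean total sleep exceeds the band, `short` below it,
#' otherwise `none`.
#'
#' @param summaries data.frame with columns `line` and `total_sleep_min`
#'   (one row per animal).
#' @param reference `"all_animals"` (default; every animal tested forms the
#'   pool) or `"control_lines"` (only animals of `control_lines`).
#' @param control_lines Character vector of control line ids, required for
#'   `reference = "control_lines"`.
#' @param k_sd Band half-width in pooled SD units; default 2.
#' @return A `screen_calls` data.frame: `line`, `n`, `mean_total_sleep`,
#'   `band_low`, `band_high`, `call`; the band is repeated per line for
#'   convenience.
#' @export
call_screen_hits <- function(summaries,
                             reference = c("all_animals", "control_lines"),
                             control_lines = NULL, k_sd = 2) {
  reference <- match.arg(reference)
  stopifnot(all(c("line", "total_sleep_min") %in% names(summaries)))
  pool <- if (reference == "all_animals") summaries$total_sleep_min else {
    if (is.null(control_lines)) stop("control_lines required")
    summaries$total_sleep_min[summaries$line %in% control_lines]
  }
  if (length(pool) < 2L) stop("reference pool needs >= 2 animals")
  band_low <- mean(pool) - k_sd * stats::sd(pool)
  band_high <- mean(pool) + k_sd * stats::sd(pool)
  m <- tapply(summaries$total_sleep_min, summaries$line, mean)
  calls <- data.frame(line = names(m), n = as.integer(table(summaries$line)[names(m)]),
                      mean_total_sleep = as.numeric(m),
                      band_low = band_low, band_high = band_high,
                      call = ifelse(m > band_high, "long",
                                    ifelse(m < band_low, "short", "none")),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls[order(calls$line), ],
            class = c("screen_calls", "data.frame"))
}

#' @export
print.screen_calls <- function(x, ...) {
  hits <- sum(x$call != "none")
  cat(sprintf("<screen_calls> %d line(s), %d hit(s); band [%.1f, %.1f] min\n",
              nrow(x), hits, x$band_low[1], x$band_high[1]))
  print.data.frame(utils::head(as.data.frame(x[x$call != "none", ]), 20))
  invisible(x)
}

#' @describeIn call_screen_hits Plot line means against the reference band.
#' @param x A `screen_calls` object.
#' @param ... Passed to [plot()].
#' @export
plot.screen_calls <- function(x, ...) {
  col <- c(none = "grey40", long = "red3", short = "dodgerblue3")[x$call]
  plot(seq_len(nrow(x)), x$mean_total_sleep, pch = 19, col = col,
       xlab = "line", ylab = "mean total sleep (min/day)", ...)
  graphics::abline(h = c(x$band_low[1], x$band_high[1]), lty = 2)
  invisible(x)
}

#' Homeostatic rebound after sleep deprivation
#'
#' Per-animal percent change in daytime sleep from baseline to recovery,
#' compared between genotypes (Welch two-sample test on the percent changes
#' when two genotypes are present).
#'
#' @param baseline,recovery Paired per-animal daytime sleep minutes.
#' @param genotype Per-animal genotype labels.
#' @return List: `per_animal` (with `pct_change`; animals with zero baseline
#'   are flagged `excluded` and dropped from group statistics), `by_genotype`
#'   (mean/SE of percent change), `comparison` ([zf_group_compare()]-style
#'   result, or NULL unless exactly two genotypes).
#' @export
rebound_analysis <- function(baseline, recovery, genotype) {
  stopifnot(length(baseline) == length(recovery),
            length(baseline) == length(genotype))
  excluded <- baseline == 0
  pct <- ifelse(excluded, NA_real_, 100 * (recovery - baseline) / baseline)
  per_animal <- data.frame(genotype = genotype, baseline = baseline,
                           recovery = recovery, pct_change = pct,
                           excluded = excluded)
  ok <- per_animal[!per_animal$excluded, ]
  by_geno <- do.call(rbind, lapply(split(ok$pct_change, ok$genotype), function(v)
    data.frame(n = length(v), mean_pct_change = mean(v),
               se = stats::sd(v) / sqrt(length(v)))))
  by_geno <- data.frame(genotype = rownames(by_geno), by_geno,
                        row.names = NULL)
  comparison <- NULL
  g <- unique(ok$genotype)
  if (length(g) == 2L)
    comparison <- zf_group_compare(ok$pct_change[ok$genotype == g[1]],
                                   ok$pct_change[ok$genotype == g[2]])
  list(per_animal = per_animal, by_genotype = by_geno,
       comparison = comparison)
}

#' Detect stimulus responses in a movement trace
#'
#' A response to a stimulus is any displacement above `move_threshold_mm`
#' within `window_sec` seconds after stimulus onset.
#'
#' @param displacement_mm Per-second displacement trace.
#' @param stim_times_sec Stimulus onset times (seconds, 1-based sample index).
#' @param window_sec Response window; default 60 s.
#' @param move_threshold_mm Displacement defining movement; default 3 mm.
#' @return Logical vector, one element per stimulus.
#' @export
detect_responses <- function(displacement_mm, stim_times_sec,
                             window_sec = 60, move_threshold_mm = 3) {
  vapply(stim_times_sec, function(t) {
    win <- seq.int(t + 1L, min(t + window_sec, length(displacement_mm)))
    length(win) > 0 && any(displacement_mm[win] > move_threshold_mm)
  }, logical(1))
}

#' Arousal threshold from escalating-stimulus trials
#'
#' For each trial of escalating mechanical stimuli delivered to a fly, the
#' arousal threshold is the lowest intensity whose response window contains a
#' response. Trials in which the fly was not asleep at first-stimulus onset
#' are excluded; trials with no response at any intensity are right-censored
#' at the maximum intensity.
#'
#' @param trials data.frame with one row per delivered stimulus: `fly`,
#'   `trial`, `intensity` (strictly increasing within a trial), `responded`
#'   (logical) and `asleep_at_onset` (logical, constant within trial:
#'   whether the fly was asleep when the first stimulus of the trial fired).
#' @return data.frame, one row per (fly, trial): `threshold`, `censored`,
#'   `excluded`.
#' @export
arousal_threshold <- function(trials) {
  stopifnot(all(c("fly", "trial", "intensity", "responded",
                  "asleep_at_onset") %in% names(trials)))
  if (any(trials$intensity <= 0)) stop("intensities must be > 0")
  key <- interaction(trials$fly, trials$trial, drop = TRUE)
  out <- lapply(split(trials, key), function(tr) {
    tr <- tr[order(tr$intensity), ]
    if (any(diff(tr$intensity) <= 0))
      stop("stimulus intensities must be strictly increasing within a trial")
    excl <- !tr$asleep_at_onset[1]
    resp <- which(tr$responded)
    data.frame(fly = tr$fly[1], trial = tr$trial[1],
               threshold = if (excl) NA_real_ else
                 if (length(resp)) tr$intensity[min(resp)] else max(tr$intensity),
               censored = !excl && length(resp) == 0L,
               excluded = excl)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$fly, out$trial), ]
}

#' Reactivity to a fixed stimulus by immobility-duration bin
#'
#' Each trial (one fixed-intensity stimulus to one fly) in which the fly was
#' asleep is assigned to a bin of prior immobility duration; reactivity is
#' the proportion of responding trials per bin. When `group` has two levels,
#' a covariate-adjusted comparison (response proportion against bin midpoint
#' and group, weighted by trials per bin) reports the group elevation effect.
#'
#' @param trials data.frame: `fly`, `group`, `immobility_min` (minutes
#'   immobile at stimulus onset), `responded`, `asleep` (logical).
#' @param bin_width,bin_start Immobility bins `[bin_start + i*bin_width,
#'   ...)`, defaults 5-min bins from 5 min; trials below `bin_start` are
#'   dropped (a sleeping fly has been immobile at least 5 min). Empty bins
#'   are omitted, not zero-filled.
#' @return List of class `reactivity`: `by_bin` (group, bin bounds/midpoint,
#'   trials, responders, reactivity) and `comparison` (group effect estimate,
#'   SE, F and p from the covariate-adjusted fit; NULL unless two groups).
#' @export
reactivity <- function(trials, bin_width = 5, bin_start = 5) {
  stopifnot(all(c("fly", "group", "immobility_min", "responded", "asleep")
                %in% names(trials)))
  t2 <- trials[trials$asleep & trials$immobility_min >= bin_start, ]
  if (nrow(t2) == 0L) stop("no sleeping trials to analyze")
  bin <- floor((t2$immobility_min - bin_start) / bin_width)
  t2$bin_low <- bin_start + bin * bin_width
  agg <- aggregate(cbind(trials = rep(1, nrow(t2)), responders = t2$responded),
                   by = list(group = t2$group, bin_low = t2$bin_low), FUN = sum)
  agg$bin_high <- agg$bin_low + bin_width
  agg$bin_mid <- agg$bin_low + bin_width / 2
  agg$reactivity <- agg$responders / agg$trials
  agg <- agg[order(agg$group, agg$bin_low),
             c("group", "bin_low", "bin_high", "bin_mid", "trials",
               "responders", "reactivity")]
  rownames(agg) <- NULL
  comparison <- NULL
  if (length(unique(agg$group)) == 2L) {
    fit <- stats::lm(reactivity ~ bin_mid + group, data = agg,
                     weights = agg$trials)
    sm <- summary(fit)$coefficients
    grow <- grep("^group", rownames(sm))
    an <- stats::anova(fit)
    comparison <- data.frame(
      effect = rownames(sm)[grow], estimate = sm[grow, 1], se = sm[grow, 2],
      F_value = an["group", "F value"], p_value = an["group", "Pr(>F)"],
      row.names = NULL)
  }
  structure(list(by_bin = agg, comparison = comparison),
            class = "reactivity")
}

#' @export
print.reactivity <- function(x, ...) {
  cat("<reactivity> proportion responding by immobility bin\n")
  print.data.frame(x$by_bin)
  if (!is.null(x$comparison)) {
    cat(sprintf("group elevation effect: %.3f (SE %.3f), F = %.2f, p = %.3g\n",
                x$comparison$estimate, x$comparison$se,
                x$comparison$F_value, x$comparison$p_value))
  }
  invisible(x)
}
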