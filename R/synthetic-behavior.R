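#' Two-state sleep/wake behavior model parameters
#'
#' Per-minute wake->sleep (`p_ws`) and sleep->wake (`p_sw`) transition
#' probabilities for a discrete-time two-state Markov chain, separately for
#' day and night, plus the waking-activity intensity. This is the minimal
#' structure under which run-length sleep scoring and day/night contrasts
#' are meaningful.
#'
#' @param p_ws_day,p_sw_day,p_ws_night,p_sw_night Transition probabilities
#'   in `[0, 1]`. The fly defaults give a moderately day-active, night-sleepy
#'   animal (expected immobility ~29% of the day, ~78% of the night).
#' @param wake_intensity Waking-activity scale: mean beam crossings per
#'   waking minute for flies, Gamma mean of movement-seconds for zebrafish.
#' @return List of class `behavior_spec`.
#' @export
behavior_spec <- function(p_ws_day = 0.02, p_sw_day = 0.05,
                          p_ws_night = 0.09, p_sw_night = 0.025,
                          wake_intensity = 2) {
  p <- c(p_ws_day, p_sw_day, p_ws_night, p_sw_night)
  if (any(p < 0 | p > 1)) stop("transition probabilities must lie in [0, 1]")
  if (wake_intensity <= 0) stop("wake_intensity must be > 0")
  structure(list(p_ws_day = p_ws_day, p_sw_day = p_sw_day,
                 p_ws_night = p_ws_night, p_sw_night = p_sw_night,
                 wake_intensity = wake_intensity),
            class = "behavior_spec")
}

#' @rdname behavior_spec
#' @details `zf_behavior_spec()` gives the zebrafish defaults: larvae that
#'   are rarely asleep by day and asleep about half of each minute-pair at
#'   night, with Gamma-distributed waking movement.
#' @export
zf_behavior_spec <- function(p_ws_day = 0.003, p_sw_day = 0.15,
                             p_ws_night = 0.04, p_sw_night = 0.04,
                             wake_intensity = 6) {
  behavior_spec(p_ws_day, p_sw_day, p_ws_night, p_sw_night, wake_intensity)
}

stationary_sleep <- function(p_ws, p_sw) {
  if (p_ws + p_sw == 0) return(0)
  p_ws / (p_ws + p_sw)
}

# Simulate sleep states for n_chains animals over the phase sequence.
# Vectorized over chains; the first minute draws from the stationary
# distribution of its phase.
sim_sleep_states <- function(phase, n_chains, spec, factor_day = 1,
                             factor_night = 1) {
  n <- length(phase)
  pw <- ifelse(phase == "day", spec$p_ws_day * factor_day^2,
               spec$p_ws_night * factor_night^2)
  ps <- ifelse(phase == "day", spec$p_sw_day, spec$p_sw_night)
  pw <- pmin(pw, 1)
  state <- matrix(FALSE, n, n_chains)
  s0 <- stationary_sleep(pw[1], ps[1])
  state[1, ] <- stats::runif(n_chains) < s0
  for (t in 2:n) {
    u <- stats::runif(n_chains)
    state[t, ] <- ifelse(state[t - 1, ], u >= ps[t], u < pw[t])
  }
  state
}

# Expected stationary immobility minutes per day for a fly spec with the
# night/day wake->sleep probability scaled by f^2 (f multiplies p_ws and
# divides p_sw, leaving the product invariant so bout structure shifts
# smoothly).
expected_immobility <- function(spec, f = 1) {
  720 * stationary_sleep(spec$p_ws_day * f^2, spec$p_sw_day) +
    720 * stationary_sleep(spec$p_ws_night * f^2, spec$p_sw_night)
}

#' Generate Drosophila activity traces with planted sleep effects
#'
#' Simulates per-minute beam-crossing counts for `n_lines` RNAi lines of
#' `n_flies_per_line` flies over `n_days` 12:12 days: a two-state sleep/wake
#' Markov chain per animal (day/night transition matrices from `spec`) with
#' counts 0 during sleep-state minutes and positive Poisson counts during
#' wake minutes (truncated to >= 1 so waking minutes are never miscalled
#' immobile). Hit lines have their wake->sleep/sleep->wake probabilities
#' shifted so the expected total sleep moves by the requested number of
#' reference-animal SDs; the shift is calibrated by matching the stationary
#' immobility increase to the target, with the reference mean and SD
#' estimated from an internal simulation of reference animals.
#'
#' @param n_lines Number of lines; default 12.
#' @param n_flies_per_line Animals per line; default 16.
#' @param n_days Days of recording; default 3.
#' @param spec A [behavior_spec()].
#' @param hit_effects Named numeric vector: line index (e.g. `"3"`) or line
#'   id (`"line_03"`) mapped to an effect in SD units (positive = long
#'   sleeper). Default none.
#' @param seed Integer seed (mandatory).
#' @return List of class `fly_sim`: `counts` (minutes x animals matrix),
#'   `meta` (`animal_id`, `line`, `effect_sd`), `truth` (per line: planted
#'   `effect_sd`, calibration factor, reference mean/SD of total sleep per
#'   day).
#' @export
gen_fly_traces <- function(n_lines = 12, n_flies_per_line = 16, n_days = 3,
                           spec = behavior_spec(), hit_effects = NULL,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_lines >= 1, n_flies_per_line >= 1, n_days >= 1)
  lines <- sprintf("line_%02d", seq_len(n_lines))
  effects <- stats::setNames(numeric(n_lines), lines)
  if (!is.null(hit_effects)) {
    nm <- names(hit_effects)
    nm <- ifelse(grepl("^[0-9]+$", nm),
                 sprintf("line_%02d", as.integer(nm)), nm)
    bad <- setdiff(nm, lines)
    if (length(bad)) stop("unknown hit line(s): ", paste(bad, collapse = ", "))
    effects[nm] <- as.numeric(hit_effects)
  }
  with_seed(seed, {
    phase <- fly_phase(n_days * 1440L)
    # reference mean/SD of scored total sleep per day, from an internal
    # simulation of reference animals under the same spec
    cal <- sim_sleep_states(phase, 100L, spec)
    cal_sleep <- apply(cal, 2, function(s) {
      counts <- ifelse(s, 0L, 1L)  # scoring depends only on the zero pattern
      sum(score_fly_sleep(counts)$state) / n_days
    })
    ref_mean <- mean(cal_sleep); ref_sd <- stats::sd(cal_sleep)

    factor_for <- function(k_sd) {
      if (k_sd == 0) return(1)
      target <- k_sd * ref_sd
      g <- function(f) (expected_immobility(spec, f) -
                          expected_immobility(spec, 1)) - target
      stats::uniroot(g, lower = 1e-3, upper = 50, tol = 1e-8)$root
    }
    factors <- vapply(unique(effects), factor_for, numeric(1))
    names(factors) <- as.character(unique(effects))

    n_animals <- n_lines * n_flies_per_line
    counts <- matrix(0L, length(phase), n_animals)
    meta <- data.frame(
      animal_id = sprintf("fly_%03d", seq_len(n_animals)),
      line = rep(lines, each = n_flies_per_line),
      effect_sd = rep(effects, each = n_flies_per_line),
      stringsAsFactors = FALSE)
    animal_factor <- factors[as.character(meta$effect_sd)]
    for (f in unique(animal_factor)) {
      idx <- which(animal_factor == f)
      st <- sim_sleep_states(phase, length(idx), spec,
                             factor_day = f, factor_night = f)
      wake_counts <- matrix(
        stats::rpois(length(st), spec$wake_intensity - 1) + 1L,
        nrow(st), ncol(st))
      counts[, idx] <- ifelse(st, 0L, wake_counts)
    }
    colnames(counts) <- meta$animal_id
    truth <- data.frame(line = lines, effect_sd = as.numeric(effects),
                        factor = as.numeric(
                          factors[as.character(effects)]),
                        ref_mean_total_sleep = ref_mean,
                        ref_sd_total_sleep = ref_sd,
                        stringsAsFactors = FALSE)
    structure(list(counts = counts, meta = meta, truth = truth, spec = spec,
                   n_days = n_days, seed = seed),
              class = "fly_sim")
  })
}

#' Generate larval zebrafish movement traces with a planted night-sleep
#' effect
#'
#' Simulates per-minute movement-seconds for a scramble-injected control
#' group and a KO group on the 14:10 light cycle (day 09:00-23:00). Sleep
#' minutes carry uniform movement in `[0, 0.5)` s and wake minutes
#' Gamma-distributed movement clipped to `[0.5, 60]` s, so the 0.5-s scoring
#' boundary is respected on both sides. The KO night wake->sleep/sleep->wake
#' probabilities are tuned so the expected cumulative night-sleep difference
#' over the analyzed nights equals `night_delta_min` (KO sleeps more when
#' positive).
#'
#' @param n_scramble,n_ko Group sizes; defaults 42 and 48.
#' @param night_delta_min Planted cumulative night-sleep difference in
#'   minutes over `analysis_days` nights; default 30.
#' @param spec A [zf_behavior_spec()].
#' @param analysis_days Full day/night cycles after acclimation; default 2.
#' @param clock_start Recording start, "HH:MM"; default "14:00" (the
#'   pre-analysis acclimation runs to the next 09:00).
#' @param seed Integer seed (mandatory).
#' @return List of class `zf_sim`: `movement` (minutes x larvae matrix),
#'   `meta` (`larva_id`, `group`), `clock_start_min`, `truth` (planted delta
#'   and tuned night parameters).
#' @export
gen_zf_traces <- function(n_scramble = 42, n_ko = 48, night_delta_min = 30,
                          spec = zf_behavior_spec(), analysis_days = 2,
                          clock_start = "14:00", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_scramble >= 1, n_ko >= 1, analysis_days >= 1)
  start_min <- parse_clock(clock_start)
  acclim <- (540L - start_min) %% 1440L
  n_min <- acclim + analysis_days * 1440L
  night_minutes <- analysis_days * 600L  # 10-h nights
  s_n <- stationary_sleep(spec$p_ws_night, spec$p_sw_night)
  s_target <- s_n + night_delta_min / night_minutes
  if (s_target <= 0 || s_target >= 1)
    stop("night_delta_min infeasible for this spec")
  f_ko <- sqrt(s_target * spec$p_sw_night /
                 ((1 - s_target) * spec$p_ws_night))
  with_seed(seed, {
    phase <- zf_phase(n_min, clock_start_min = start_min)
    movement_for <- function(n, f_night) {
      st <- sim_sleep_states(phase, n, spec, factor_night = f_night)
      sleep_mov <- matrix(stats::runif(length(st), 0, 0.5), nrow(st), ncol(st))
      wake_mov <- matrix(
        pmin(pmax(stats::rgamma(length(st), shape = 2,
                                scale = spec$wake_intensity / 2), 0.5), 60),
        nrow(st), ncol(st))
      ifelse(st, sleep_mov, wake_mov)
    }
    movement <- cbind(movement_for(n_scramble, 1),
                      movement_for(n_ko, f_ko))
    meta <- data.frame(
      larva_id = sprintf("larva_%03d", seq_len(n_scramble + n_ko)),
      group = rep(c("scramble", "ko"), c(n_scramble, n_ko)),
      stringsAsFactors = FALSE)
    colnames(movement) <- meta$larva_id
    structure(list(movement = movement, meta = meta,
                   clock_start_min = start_min,
                   truth = list(night_delta_min = night_delta_min,
                                f_ko_night = f_ko,
                                stationary_night_sleep = c(
                                  scramble = s_n, ko = s_target)),
                   analysis_days = analysis_days, seed = seed),
              class = "zf_sim")
  })
}

#' Generate stimulus-response trials from sleep states
#'
#' Delivers stimuli every `period_min` minutes to every animal and draws
#' Bernoulli responses from `response_curve(intensity, immobility_min)`.
#' With several intensities, each stimulus time is one escalating trial
#' (all intensities delivered in ascending order). The prior immobility
#' duration is the length of the sleep run ending at the stimulus minute.
#'
#' @param sleep_states Logical matrix (minutes x animals), TRUE = asleep.
#' @param intensities Stimulus intensities (strictly increasing when > 1).
#' @param response_curve `function(intensity, immobility_min)` returning a
#'   response probability in `[0, 1]`.
#' @param period_min Minutes between trials; default 60.
#' @param seed Integer seed (mandatory).
#' @return data.frame of trials: `fly`, `trial`, `time_minute`, `intensity`,
#'   `immobility_min`, `asleep_at_onset`, `responded` — consumable by
#'   [arousal_threshold()] and (with a `group` column joined) [reactivity()].
#' @export
gen_stimulus_responses <- function(sleep_states, intensities, response_curve,
                                   period_min = 60, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.vector(sleep_states)) sleep_states <- matrix(sleep_states)
  if (length(intensities) > 1 && any(diff(intensities) <= 0))
    stop("intensities must be strictly increasing")
  times <- seq(period_min, nrow(sleep_states), by = period_min)
  runlen <- apply(sleep_states, 2, function(s) {
    r <- numeric(length(s)); acc <- 0
    for (i in seq_along(s)) { acc <- if (s[i]) acc + 1 else 0; r[i] <- acc }
    r
  })
  with_seed(seed, {
    grid <- expand.grid(intensity = intensities, time_minute = times,
                        fly = seq_len(ncol(sleep_states)),
                        KEEP.OUT.ATTRS = FALSE)
    grid$trial <- match(grid$time_minute, times)
    grid$immobility_min <- runlen[cbind(grid$time_minute, grid$fly)]
    grid$asleep_at_onset <- grid$immobility_min >= 5
    p <- mapply(response_curve, grid$intensity, grid$immobility_min)
    if (any(p < 0 | p > 1)) stop("response_curve must map into [0, 1]")
    grid$responded <- stats::runif(nrow(grid)) < p
    grid[order(grid$fly, grid$trial, grid$intensity),
         c("fly", "trial", "time_minute", "intensity", "immobility_min",
           "asleep_at_onset", "responded")]
  })
}
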