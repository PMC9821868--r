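test_that("five consecutive immobile minutes are required for a sleep bout", {
  expect_equal(sum(score_fly_sleep(c(1, 0, 0, 0, 0, 1))$state), 0)
  s <- score_fly_sleep(c(1, 0, 0, 0, 0, 0, 1))
  expect_equal(sum(s$state), 5)
  expect_equal(s$bouts, data.frame(start_minute = 2L, duration_min = 5L))
  # saturated day: one bout of 1440
  all0 <- score_fly_sleep(rep(0L, 1440))
  expect_equal(sum(all0$state), 1440)
  expect_equal(nrow(all0$bouts), 1L)
  # a bout truncated by the trace end still counts
  expect_equal(sum(score_fly_sleep(c(1, 0, 0, 0, 0, 0))$state), 5)
  expect_error(score_fly_sleep(c(1, -1)), ">= 0")
  expect_error(score_fly_sleep(integer(0)), "empty")
})

test_that("sleep scoring equals the run-length oracle on exhaustive short and random traces", {
  # exhaustive binary traces up to length 8 (the acceptance suite goes to 12)
  for (len in 1:8) {
    for (code in 0:(2^len - 1)) {
      counts <- as.integer(intToBits(code))[1:len]
      expect_equal(score_fly_sleep(counts)$state, oracle_fly_state(counts))
    }
  }
  set.seed(31)
  for (rep in 1:200) {
    counts <- rpois(sample(10:200, 1), 0.5)
    s <- score_fly_sleep(counts)
    expect_equal(s$state, oracle_fly_state(counts))
    # sleep + wake = trace length; runs match the oracle
    runs <- oracle_runs(s$state)
    expect_equal(s$bouts$start_minute, runs$start)
    expect_equal(s$bouts$duration_min, runs$len)
  }
})

test_that("scoring depends only on the zero pattern and is monotone in activity", {
  set.seed(32)
  counts <- rpois(500, 0.6)
  base <- score_fly_sleep(counts)$state
  expect_equal(score_fly_sleep(counts * 7L)$state, base)
  # adding activity to any minute never increases total sleep
  for (rep in 1:20) {
    bumped <- counts
    i <- sample(500, 1)
    bumped[i] <- bumped[i] + 1L
    expect_lte(sum(score_fly_sleep(bumped)$state), sum(base))
  }
})

test_that("per-animal summaries split day and night and average per day", {
  # 840 wake minutes with 2 crossings each across a full day
  counts <- rep(0L, 1440)
  counts[1:840] <- 2L
  sm <- summarize_fly_sleep(counts)
  expect_equal(sm$waking_activity, 2)
  expect_equal(sm$total_sleep_min, 600)
  expect_equal(sm$day_sleep_min, 0)       # sleep run starts at ZT840
  expect_equal(sm$night_sleep_min, 600)
  expect_equal(sm$night_bout_number, 1)
  # all-sleep day: both phases saturated, waking activity undefined
  sm0 <- summarize_fly_sleep(rep(0L, 1440))
  expect_equal(sm0$day_sleep_min, 720)
  expect_equal(sm0$night_sleep_min, 720)
  expect_true(sm0$waking_undefined)
  expect_true(is.na(sm0$waking_activity))
  # multi-day averaging and independent recomputation from the state
  set.seed(33)
  c3 <- rpois(3 * 1440, 0.8)
  sc <- score_fly_sleep(c3)
  sm3 <- summarize_fly_sleep(c3)
  expect_equal(sm3$total_sleep_min, sum(sc$state) / 3)
  expect_equal(sm3$day_sleep_min + sm3$night_sleep_min, sm3$total_sleep_min)
  wake <- !sc$state
  expect_equal(sm3$waking_activity, sum(c3[wake]) / sum(wake))
  expect_error(summarize_fly_sleep(c3, score_fly_sleep(c3[-1])), "lengths")
})

test_that("dead animals are flagged from their terminal zero run", {
  expect_true(flag_dead(c(rpois(100, 2), rep(0L, 1440))))
  expect_false(flag_dead(c(rpois(100, 2), rep(0L, 1439))))
  expect_true(flag_dead(rep(0L, 1500)))
})

test_that("screen hit calling applies the +/- 2 SD band to line means", {
  set.seed(34)
  # reference pool engineered to mean 600, sd 50
  pool <- as.numeric(scale(rnorm(200))) * 50 + 600
  sm <- data.frame(line = rep(c("ctrl_a", "ctrl_b"), 100),
                   total_sleep_min = pool)
  long_line <- data.frame(line = "hit_long", total_sleep_min = rep(710, 8))
  short_line <- data.frame(line = "hit_short", total_sleep_min = rep(495, 8))
  calls <- call_screen_hits(rbind(sm, long_line, short_line),
                            reference = "control_lines",
                            control_lines = c("ctrl_a", "ctrl_b"))
  expect_equal(calls$band_low[1], 500)
  expect_equal(calls$band_high[1], 700)
  expect_equal(calls$call[calls$line == "hit_long"], "long")
  expect_equal(calls$call[calls$line == "hit_short"], "short")
  expect_equal(calls$call[calls$line == "ctrl_a"], "none")
  expect_error(call_screen_hits(sm[1, ]), ">= 2")
})

test_that("the screen band is translation-equivariant", {
  set.seed(35)
  sm <- data.frame(line = rep(paste0("l", 1:10), each = 12),
                   total_sleep_min = rnorm(120, 600, 60))
  c0 <- call_screen_hits(sm)
  sm$total_sleep_min <- sm$total_sleep_min + 123
  c1 <- call_screen_hits(sm)
  expect_equal(c1$band_low, c0$band_low + 123)
  expect_equal(c1$band_high, c0$band_high + 123)
  expect_equal(c1$call, c0$call)
})

test_that("rebound analysis reports paired percent change and excludes zero baselines", {
  rb <- rebound_analysis(baseline = c(200, 300, 0, 250),
                         recovery = c(260, 300, 100, 300),
                         genotype = c("wt", "wt", "wt", "wt"))
  expect_equal(rb$per_animal$pct_change[1], 30)
  expect_equal(rb$per_animal$pct_change[2], 0)
  expect_true(rb$per_animal$excluded[3])
  expect_equal(rb$by_genotype$n, 3L)
  # equal planted rebound in two genotypes -> difference centered at 0
  set.seed(36)
  diffs <- replicate(200, {
    b <- runif(30, 150, 400); r <- b * runif(30, 1.2, 1.6)
    g <- rep(c("a", "b"), 15)
    rebound_analysis(b, r, g)$comparison$mean_difference
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(200))
})

test_that("arousal threshold is the lowest responding intensity, with censoring and exclusion", {
  trials <- rbind(
    data.frame(fly = 1, trial = 1, intensity = c(0.6, 1.2, 2.4),
               responded = c(FALSE, TRUE, TRUE), asleep_at_onset = TRUE),
    data.frame(fly = 1, trial = 2, intensity = c(0.6, 1.2, 2.4),
               responded = FALSE, asleep_at_onset = TRUE),
    data.frame(fly = 2, trial = 1, intensity = c(0.6, 1.2, 2.4),
               responded = TRUE, asleep_at_onset = FALSE))
  at <- arousal_threshold(trials)
  expect_equal(at$threshold[at$fly == 1 & at$trial == 1], 1.2)
  r2 <- at[at$fly == 1 & at$trial == 2, ]
  expect_equal(r2$threshold, 2.4)
  expect_true(r2$censored)
  expect_true(at$excluded[at$fly == 2])
  bad <- trials; bad$intensity[2] <- 0.6
  expect_error(arousal_threshold(bad), "strictly increasing")
})

test_that("mean arousal threshold falls as the response curve steepens", {
  set.seed(37)
  mk <- function(slope) {
    p <- pmin(1, slope * c(0.3, 0.6, 1.2, 2.4))
    trials <- do.call(rbind, lapply(1:200, function(f)
      data.frame(fly = f, trial = 1, intensity = c(0.3, 0.6, 1.2, 2.4),
                 responded = runif(4) < p, asleep_at_onset = TRUE)))
    mean(arousal_threshold(trials)$threshold)
  }
  expect_gt(mk(0.15), mk(0.8))
})

test_that("reactivity bins sleeping trials and recovers a planted group offset", {
  trials <- data.frame(fly = rep(1:10, 2), group = "g1",
                       immobility_min = rep(c(7, 20), each = 10),
                       responded = c(rep(TRUE, 7), rep(FALSE, 3),
                                     rep(TRUE, 3), rep(FALSE, 7)),
                       asleep = TRUE)
  r <- reactivity(trials)
  expect_equal(r$by_bin$reactivity[r$by_bin$bin_low == 5], 0.7)
  expect_equal(r$by_bin$reactivity[r$by_bin$bin_low == 20], 0.3)
  expect_equal(nrow(r$by_bin), 2L)   # empty bins omitted, not zero-filled

  # identical groups -> elevation effect ~ 0; planted offset -> sign recovered
  set.seed(38)
  mk_group <- function(g, drop) {
    imm <- runif(600, 5, 60)
    p <- pmax(0.05, 0.9 - 0.012 * imm - drop)
    data.frame(fly = seq_along(imm), group = g, immobility_min = imm,
               responded = runif(600) < p, asleep = TRUE)
  }
  same <- reactivity(rbind(mk_group("a", 0), mk_group("b", 0)))
  expect_lt(abs(same$comparison$estimate), 3 * same$comparison$se)
  shifted <- reactivity(rbind(mk_group("a", 0), mk_group("b", 0.3)))
  expect_lt(shifted$comparison$estimate, 0)   # group b sits lower
  expect_lt(shifted$comparison$p_value, 0.05)
})
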