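test_that("landscape generation is deterministic and honors empty input", {
  a <- gen_landscape(n_loci = 6, seed = 51)
  b <- gen_landscape(n_loci = 6, seed = 51)
  expect_identical(a, b)
  c <- gen_landscape(n_loci = 6, seed = 52)
  expect_false(identical(a$genome, c$genome))
  # n_loci = 0: valid empty tables, empty ledger
  z <- gen_landscape(n_loci = 0, genome_length = 5000, seed = 51)
  expect_equal(nrow(z$sentinels), 0L)
  expect_equal(nrow(z$ledger), 0L)
  expect_gt(nrow(z$map1), 0L)
  expect_error(gen_landscape(n_loci = 500, genome_length = 20000, seed = 1),
               "infeasible geometry")
  expect_error(gen_landscape(n_loci = 2), "seed")
})

test_that("the pipeline reproduces exactly the ledger's planted links", {
  land <- gen_landscape(seed = 53)   # default config
  res <- v2g_map(land$sentinels, land$ld, land$peaks, land$baits,
                 land$interactions, land$expression, land$map1, land$map4)
  planted <- land$ledger[land$ledger$kind == "planted", ]
  got <- paste(res$links$rsid, res$links$gene)
  want <- paste(planted$rsid, planted$gene)
  expect_setequal(got, want)                       # 100% recall, no extras
  # expression expectation carries through the filter
  i <- match(want, got)
  expect_equal(res$links$expressed_flag[i], planted$expressed_expected)
  # every decoy failure mode is present and produces no link
  expect_setequal(unique(land$ledger$violated[land$ledger$kind == "decoy"]),
                  c("closed_proxy", "baited_proxy", "low_score", "closed_bait"))
  decoy_rs <- land$ledger$rsid[land$ledger$kind == "decoy"]
  expect_false(any(res$links$rsid %in% decoy_rs))
})

test_that("saturated landscapes link every proxy", {
  land <- gen_landscape(n_loci = 8, fraction_open = 1, fraction_looped = 1,
                        seed = 54)
  expect_true(all(land$ledger$kind == "planted"))
  res <- v2g_map(land$sentinels, land$ld, land$peaks, land$baits,
                 land$interactions, land$expression, land$map1, land$map4)
  open_rs <- res$proxies$rsid[res$proxies$open_flag]
  expect_setequal(unique(res$links$rsid), open_rs)
})

test_that("fly trace generation is deterministic with sleep-state structure", {
  a <- gen_fly_traces(n_lines = 3, n_flies_per_line = 4, n_days = 1, seed = 55)
  b <- gen_fly_traces(n_lines = 3, n_flies_per_line = 4, n_days = 1, seed = 55)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))
  # wake minutes are never zero (so scoring recovers the latent state): an
  # absorbing night (sleep->wake prob 0) pins the animal asleep all night
  spec <- behavior_spec(p_ws_night = 0.5, p_sw_night = 0)
  s <- gen_fly_traces(n_lines = 1, n_flies_per_line = 6, n_days = 1,
                      spec = spec, seed = 56)
  night <- 721:1440
  night_sleep <- apply(s$counts[night, ], 2,
                       function(x) sum(score_fly_sleep(x)$state))
  expect_true(all(night_sleep >= 715))   # asleep once night starts
})

test_that("generated fly traces recover the generator's expected sleep level", {
  sim <- gen_fly_traces(n_lines = 4, n_flies_per_line = 16, n_days = 2,
                        seed = 57)
  tot <- apply(sim$counts, 2, function(x) sum(score_fly_sleep(x)$state) / 2)
  ref <- sim$truth$ref_mean_total_sleep[1]
  sdr <- sim$truth$ref_sd_total_sleep[1]
  # mean within 4 SE of the calibration mean
  expect_lt(abs(mean(tot) - ref), 4 * sdr / sqrt(length(tot)))
})

test_that("planted fly effects shift scored sleep by the requested SDs", {
  sim <- gen_fly_traces(n_lines = 8, n_flies_per_line = 16, n_days = 2,
                        hit_effects = c(line_02 = 3), seed = 58)
  tot <- apply(sim$counts, 2, function(x) sum(score_fly_sleep(x)$state) / 2)
  hit <- sim$meta$line == "line_02"
  shift <- mean(tot[hit]) - mean(tot[!hit])
  sdr <- sim$truth$ref_sd_total_sleep[1]
  expect_gt(shift, 2 * sdr)      # a +3 SD plant lands well above +2 SD
  expect_lt(shift, 4.5 * sdr)
  expect_error(gen_fly_traces(hit_effects = c(nope = 2), seed = 1),
               "unknown hit line")
})

test_that("zebrafish traces respect the 0.5-s boundary and the movement range", {
  sim <- gen_zf_traces(n_scramble = 5, n_ko = 5, seed = 59)
  expect_true(all(sim$movement >= 0 & sim$movement <= 60))
  expect_identical(sim$movement,
                   gen_zf_traces(n_scramble = 5, n_ko = 5, seed = 59)$movement)
  # the latent state is exactly recoverable at the 0.5-s threshold:
  # scored sleep equals the planted stationary fraction within noise
  st <- score_zf_sleep(sim$movement[, 1])
  expect_true(all(sim$movement[st, 1] < 0.5))
  expect_true(all(sim$movement[!st, 1] >= 0.5))
})

test_that("the planted night-sleep delta is centered on its target", {
  deltas <- vapply(1:25, function(i) {
    sim <- gen_zf_traces(n_scramble = 20, n_ko = 20, night_delta_min = 60,
                         seed = 600 + i)
    night <- zf_phase(nrow(sim$movement), sim$clock_start_min) == "night"
    # drop the acclimation segment
    keep <- seq_len(nrow(sim$movement)) >
      (540 - sim$clock_start_min) %% 1440
    ns <- colSums(sim$movement[night & keep, ] < 0.5)
    mean(ns[sim$meta$group == "ko"]) - mean(ns[sim$meta$group == "scramble"])
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 60), 3 * se + 5)
  # delta = 0: difference centered at zero
  d0 <- vapply(1:15, function(i) {
    sim <- gen_zf_traces(n_scramble = 20, n_ko = 20, night_delta_min = 0,
                         seed = 700 + i)
    night <- zf_phase(nrow(sim$movement), sim$clock_start_min) == "night"
    ns <- colSums(sim$movement[night, ] < 0.5)
    mean(ns[sim$meta$group == "ko"]) - mean(ns[sim$meta$group == "scramble"])
  }, numeric(1))
  expect_lt(abs(mean(d0)), 3 * sd(d0) / sqrt(length(d0)) + 5)
})

test_that("stimulus responses follow the planted response curve", {
  set.seed(61)
  states <- matrix(runif(600 * 20) < 0.6, 600, 20)
  # deterministic curve = 1: threshold is the lowest intensity everywhere
  tr <- gen_stimulus_responses(states, c(0.6, 1.2, 2.4),
                               function(i, d) 1, seed = 62)
  at <- arousal_threshold(tr)
  ok <- at[!at$excluded, ]
  expect_true(all(ok$threshold == 0.6))
  expect_false(any(ok$censored))
  # curve = 0: every sleeping trial right-censored at the maximum
  tr0 <- gen_stimulus_responses(states, c(0.6, 1.2, 2.4),
                                function(i, d) 0, seed = 62)
  at0 <- arousal_threshold(tr0)
  ok0 <- at0[!at0$excluded, ]
  expect_true(all(ok0$censored))
  expect_true(all(ok0$threshold == 2.4))
  # curve declining in immobility: reactivity declines across bins
  sim <- gen_fly_traces(n_lines = 1, n_flies_per_line = 30, n_days = 1,
                        seed = 63)
  st <- apply(sim$counts, 2, function(x) score_fly_sleep(x)$state)
  tr1 <- gen_stimulus_responses(st, 1.2,
                                function(i, d) max(0.05, 0.95 - 0.02 * d),
                                seed = 64)
  tr1$group <- "g"; tr1$asleep <- tr1$asleep_at_onset
  r <- reactivity(tr1)
  fit <- coef(lm(reactivity ~ bin_mid, r$by_bin, weights = r$by_bin$trials))
  expect_lt(fit[["bin_mid"]], 0)
  # invalid curve rejected
  expect_error(gen_stimulus_responses(states, 1, function(i, d) 2, seed = 1),
               "\\[0, 1\\]")
})
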