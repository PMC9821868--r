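#' Default pipeline configuration
#'
#' All thresholds of the analysis chain in one place, overridable per run.
#' Thresholds are strict inequalities where the methods are (r2 > 0.7,
#' score > 5, TPM > 1.5, percentile > 50, movement < 0.5 s, efficiency >
#' 0.9).
#'
#' @param seed Integer seed driving every source of randomness.
#' @param out_dir Run directory for outputs.
#' @param ... Overrides for any default entry.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("run_"), ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    r2_cutoff = 0.7, chicago_cutoff = 5, tpm_min = 1.5, pct_min = 50,
    immobility_min = 5L, zf_threshold_sec = 0.5, screen_k_sd = 2,
    efficiency_cutoff = 0.9,
    lights_on = "09:00", lights_off = "23:00",
    n_loci = 36, n_proxies_per_locus = 3, genome_length = 400000,
    enzyme = "DpnII", fraction_open = 0.75, fraction_looped = 0.75,
    fly_n_lines = 24, fly_n_flies = 16, fly_n_days = 3,
    fly_hit_effects = c(line_03 = 3, line_07 = -3),
    zf_n_scramble = 42, zf_n_ko = 48, zf_night_delta_min = 30,
    zf_analysis_days = 2)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entr(y/ies): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_min0 <- c("r2_cutoff", "chicago_cutoff", "tpm_min", "pct_min",
                "immobility_min", "zf_threshold_sec", "screen_k_sd",
                "efficiency_cutoff")
  for (k in num_min0) {
    v <- cfg[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("config: `", k, "` must be a single nonnegative number")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("config: seed is mandatory")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Entries in the file override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @param ... Further overrides (take precedence over the file).
#' @return A `pipeline_config`.
#' @export
read_config_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$fly_hit_effects)) y$fly_hit_effects <- unlist(y$fly_hit_effects)
  do.call(pipeline_config, utils::modifyList(y, list(...)))
}

write_ordered_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a seeded synthetic dataset (regulatory landscape, fly activity
#' traces, zebrafish movement traces), writes every input file in its
#' standard dialect, re-reads them, runs each analysis stage, and writes
#' per-stage outputs plus a summary report under `config$out_dir`. All
#' outputs are deterministically ordered, so reruns under the same seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param stages Subset of `c("v2g", "flysleep", "zfsleep")`; dependencies
#'   (digestion, synthesis) run as needed.
#' @return List of class `pipeline_run`: per-stage result objects plus
#'   `files` (all written paths) and `report` (headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("v2g", "flysleep", "zfsleep")) {
  if (is.character(config)) config <- read_config_yaml(config)
  config <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(config$out_dir, x)
  files <- character(0)
  out <- list(config = config)
  report <- list(seed = config$seed)

  if ("v2g" %in% stages) {
    land <- gen_landscape(config$n_loci, config$n_proxies_per_locus,
                          config$genome_length, config$enzyme,
                          config$fraction_open, config$fraction_looped,
                          seed = config$seed)
    files <- c(files, write_landscape(land, f("landscape")))
    # consume the written files, not the in-memory objects
    genome <- read_genome_fasta(files[["genome"]])
    map1 <- digest_genome(genome, config$enzyme)
    map4 <- concat_fragments(map1, 4)
    files <- c(files, map_bed = write_fragment_bed(map1, f("fragments.bed")))
    res <- v2g_map(read_sentinels_tsv(files[["sentinels"]]),
                   read_ld_tsv(files[["ld"]]),
                   read_peaks_bed(files[["peaks"]]),
                   read_baits_bed(files[["baits"]]),
                   read_interactions_ibed(files[["interactions"]]),
                   read_expression_tsv(files[["expression"]]),
                   map1, map4,
                   r2_cutoff = config$r2_cutoff,
                   score_cutoff = config$chicago_cutoff,
                   tpm_min = config$tpm_min, pct_min = config$pct_min)
    links <- as.data.frame(res$links)
    links <- links[order(links$locus_id, links$rsid, links$gene), ]
    files <- c(files, links = write_ordered_tsv(links, f("links.tsv")))
    sm <- res$summary
    files <- c(files, v2g_summary = write_ordered_tsv(
      data.frame(metric = names(unclass(sm)),
                 value = unlist(unclass(sm), use.names = FALSE)),
      f("v2g_summary.tsv")))
    st <- fragment_stats(map1)
    out$landscape <- land; out$v2g <- res
    report$fragment_mean_bp <- st$mean_length
    report$fragment_median_bp <- st$median_length
    report$v2g <- unclass(sm)
  }

  if ("flysleep" %in% stages) {
    hits <- config$fly_hit_effects
    if (!is.null(hits)) {   # ignore planted hits beyond the simulated lines
      nm <- names(hits)
      nm <- ifelse(grepl("^[0-9]+$", nm), sprintf("line_%02d", as.integer(nm)), nm)
      hits <- hits[nm %in% sprintf("line_%02d", seq_len(config$fly_n_lines))]
    }
    sim <- gen_fly_traces(config$fly_n_lines, config$fly_n_flies,
                          config$fly_n_days, hit_effects = hits,
                          seed = config$seed + 1L)
    # round-trip through monitor files, 32 channels per monitor
    dir.create(f("dam"), showWarnings = FALSE)
    n_mon <- ceiling(ncol(sim$counts) / 32)
    counts <- NULL
    for (m in seq_len(n_mon)) {
      idx <- ((m - 1) * 32 + 1):min(m * 32, ncol(sim$counts))
      p <- f(file.path("dam", sprintf("Monitor%02d.txt", m)))
      write_dam(sim$counts[, idx, drop = FALSE], p)
      got <- read_dam(p)$counts[, seq_along(idx), drop = FALSE]
      counts <- cbind(counts, got)
      files <- c(files, stats::setNames(p, sprintf("dam_%02d", m)))
    }
    colnames(counts) <- sim$meta$animal_id
    summaries <- do.call(rbind, lapply(seq_len(ncol(counts)), function(i)
      data.frame(animal_id = sim$meta$animal_id[i], line = sim$meta$line[i],
                 summarize_fly_sleep(counts[, i],
                                     immobility_min = config$immobility_min))))
    calls <- call_screen_hits(
      data.frame(line = summaries$line,
                 total_sleep_min = summaries$total_sleep_min),
      k_sd = config$screen_k_sd)
    files <- c(files,
               fly_summary = write_ordered_tsv(
                 summaries[order(summaries$animal_id), ], f("fly_summary.tsv")),
               screen_calls = write_ordered_tsv(as.data.frame(calls),
                                                f("screen_calls.tsv")))
    out$fly <- list(sim = sim, summaries = summaries, calls = calls)
    report$fly <- list(
      n_lines = nrow(calls),
      n_long = sum(calls$call == "long"), n_short = sum(calls$call == "short"),
      planted_long = sim$truth$line[sim$truth$effect_sd > 0],
      planted_short = sim$truth$line[sim$truth$effect_sd < 0])
  }

  if ("zfsleep" %in% stages) {
    sim <- gen_zf_traces(config$zf_n_scramble, config$zf_n_ko,
                         config$zf_night_delta_min,
                         analysis_days = config$zf_analysis_days,
                         seed = config$seed + 2L)
    p <- f("zf_tracking.csv")
    write_tracking_csv(sim$movement, p, sim$clock_start_min)
    files <- c(files, zf_tracking = p)
    tr <- read_tracking_csv(p)
    # genotype inclusion: simulate band intensities so high-efficiency
    # crispants pass the headloop filter; scramble controls are all kept
    eff <- with_seed(config$seed + 3L, ifelse(
      sim$meta$group == "ko", pmin(stats::runif(nrow(sim$meta), 0.85, 1), 1), 1))
    calls <- mutation_efficiency(eff, rep(1, length(eff)),
                                 cutoff = config$efficiency_cutoff,
                                 larva_id = sim$meta$larva_id)
    included <- sim$meta$group == "scramble" | calls$included
    summaries <- do.call(rbind, lapply(which(included), function(i) {
      trm <- trim_acclimation(tr$movement[, i], tr$clock_start_min,
                              config$zf_analysis_days, config$lights_on)
      data.frame(larva_id = sim$meta$larva_id[i], group = sim$meta$group[i],
                 summarize_zf_sleep(trm$movement_sec, trm$clock_start_min,
                                    config$zf_threshold_sec,
                                    config$lights_on, config$lights_off))
    }))
    cmp <- zf_group_compare(
      summaries$night_sleep_min[summaries$group == "ko"],
      summaries$night_sleep_min[summaries$group == "scramble"])
    files <- c(files,
               zf_summary = write_ordered_tsv(
                 summaries[order(summaries$larva_id), ], f("zf_summary.tsv")),
               zf_compare = write_ordered_tsv(
                 data.frame(measure = "night_sleep_min",
                            mean_difference = cmp$mean_difference,
                            se = cmp$se, t = cmp$t_statistic, df = cmp$df,
                            p = cmp$p_value, correction = cmp$correction),
                 f("zf_compare.tsv")),
               genotype_inclusion = write_ordered_tsv(calls,
                                                      f("genotype_inclusion.tsv")))
    out$zf <- list(sim = sim, summaries = summaries, compare = cmp,
                   inclusion = calls)
    report$zf <- list(planted_delta = config$zf_night_delta_min,
                      estimated_delta = cmp$mean_difference,
                      p_value = cmp$p_value,
                      n_included = sum(included))
  }

  manifest <- data.frame(name = names(files), path = unname(files))
  files <- c(files, manifest = write_ordered_tsv(manifest, f("manifest.tsv")))
  out$files <- files
  out$report <- report
  structure(out, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed", x$report$seed, "->", x$config$out_dir, "\n")
  if (!is.null(x$v2g)) print(x$v2g$summary)
  if (!is.null(x$fly))
    cat(sprintf("  fly screen: %d line(s), %d long / %d short hit(s)\n",
                x$report$fly$n_lines, x$report$fly$n_long,
                x$report$fly$n_short))
  if (!is.null(x$zf))
    cat(sprintf("  zf night sleep: planted delta %.1f, estimated %.2f (p=%.3g)\n",
                x$report$zf$planted_delta, x$report$zf$estimated_delta,
                x$report$zf$p_value))
  invisible(x)
}
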