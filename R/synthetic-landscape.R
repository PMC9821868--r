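#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the generator, runs `expr`, and restores the previous RNG state, so
#' generators are reproducible without disturbing the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_genome <- function(length, chrom = "chr1") {
  stats::setNames(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""), chrom)
}

#' Generate a synthetic regulatory landscape with planted effector genes
#'
#' Builds a random genome, digests it, and plants, for each locus, a GWAS
#' sentinel with LD proxies, open-chromatin peaks, a baited promoter, a
#' promoter interaction, and an expression record — such that a known subset
#' of (proxy, gene) pairs satisfies all four link conditions of
#' [annotate_loops()]. The remaining loci are decoys, each violating exactly
#' one condition (closed proxy, proxy inside a baited region, sub-threshold
#' interaction score, or closed bait); a ledger records the expectation for
#' every locus. Some planted genes are additionally given low expression so
#' the expression filter is exercised.
#'
#' @param n_loci Number of GWAS loci; default 36.
#' @param n_proxies_per_locus Proxies per locus above the LD cutoff
#'   (including the sentinel itself); each locus also gets one low-r2 record
#'   that the proxy expansion must drop. Default 3.
#' @param genome_length Length of the single synthetic chromosome; default
#'   400000 bp.
#' @param enzyme Digestion enzyme; default `"DpnII"`.
#' @param fraction_open,fraction_looped Fraction of loci whose designated
#'   proxy is open, and of those, fraction with a qualifying loop; the
#'   product sets the planted-locus share (defaults 0.75 each). Decoy loci
#'   cycle through the four failure modes.
#' @param seed Integer seed (mandatory).
#' @return List of class `v2g_landscape`: `genome` (named character),
#'   `map1`, `map4`, `sentinels`, `ld`, `peaks`, `baits`, `interactions`,
#'   `expression`, and `ledger` (columns `locus_id`, `rsid`, `gene`, `kind`
#'   = `"planted"`/`"decoy"`, `violated`, `expressed_expected`).
#' @export
gen_landscape <- function(n_loci = 36, n_proxies_per_locus = 3,
                          genome_length = 400000, enzyme = "DpnII",
                          fraction_open = 0.75, fraction_looped = 0.75,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_loci >= 0, n_proxies_per_locus >= 1, genome_length > 0,
            fraction_open >= 0, fraction_open <= 1,
            fraction_looped >= 0, fraction_looped <= 1)
  with_seed(seed, {
    genome <- random_genome(genome_length)
    map1 <- digest_genome(genome, enzyme)
    map4 <- concat_fragments(map1, 4)

    empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
    sentinels <- empty(signal_id = character(), locus_id = character(),
                       rsid = character(), chrom = character(),
                       pos0 = integer())
    ld <- empty(sentinel_id = character(), rsid = character(),
                chrom = character(), pos0 = integer(), r2 = numeric())
    peaks <- empty(peak_id = character(), chrom = character(),
                   start = integer(), end = integer())
    baits <- empty(bait_id = character(), chrom = character(),
                   start = integer(), end = integer(), gene = character(),
                   coding = logical())
    interactions <- empty(bait_id = character(), oe_chrom = character(),
                          oe_start = integer(), oe_end = integer(),
                          score = numeric(), resolution = character())
    expression <- empty(gene = character(), tpm = numeric())
    ledger <- empty(locus_id = character(), rsid = character(),
                    gene = character(), kind = character(),
                    violated = character(), expressed_expected = logical())

    if (n_loci > 0) {
      # one usable fragment per slot, spaced >= 8 indices apart so distinct
      # loci never share a four-fragment bin or adjacent fragments
      elig <- which(map1$end - map1$start >= 120 & map1$index >= 2)
      slots <- integer(0); last <- -10L
      for (i in elig) {
        if (map1$index[i] >= last + 8L) { slots <- c(slots, i); last <- map1$index[i] }
        if (length(slots) >= 2L * n_loci) break
      }
      if (length(slots) < 2L * n_loci)
        stop("infeasible geometry: genome too short for ", n_loci, " loci")

      n_planted <- round(n_loci * fraction_open * fraction_looped)
      modes <- c("closed_proxy", "baited_proxy", "low_score", "closed_bait")
      locus_mode <- c(rep("planted", n_planted),
                      rep_len(modes, n_loci - n_planted))

      chrom <- "chr1"
      pk <- 0L
      add_peak <- function(start, end) {
        pk <<- pk + 1L
        peaks[nrow(peaks) + 1L, ] <<- list(sprintf("peak_%03d", pk), chrom,
                                           as.integer(start), as.integer(end))
        invisible(NULL)
      }

      for (i in seq_len(n_loci)) {
        mode <- locus_mode[i]
        fp <- map1[slots[2L * i - 1L], ]  # proxy fragment
        fb <- map1[slots[2L * i], ]       # bait fragment
        mid <- as.integer((fp$start + fp$end) %/% 2)
        locus_id <- sprintf("locus_%02d", i)
        signal_id <- sprintf("sig_%02d", i)
        srs <- sprintf("rs%d_0", i)
        sentinels[nrow(sentinels) + 1L, ] <- list(signal_id, locus_id, srs,
                                                  chrom, mid)
        prox <- data.frame(rsid = srs, pos0 = mid, stringsAsFactors = FALSE)
        if (n_proxies_per_locus > 1) {
          for (j in seq_len(n_proxies_per_locus - 1L)) {
            rs <- sprintf("rs%d_%d", i, j)
            pos <- mid + c(-1L, 1L)[1L + j %% 2L] * ((j + 1L) %/% 2L) * 7L
            ld[nrow(ld) + 1L, ] <- list(signal_id, rs, chrom, pos,
                                        round(stats::runif(1, 0.75, 0.99), 3))
            prox <- rbind(prox, data.frame(rsid = rs, pos0 = pos))
          }
        }
        # a low-LD record the expansion must drop
        ld[nrow(ld) + 1L, ] <- list(signal_id, sprintf("rs%d_low", i), chrom,
                                    mid + 3L, 0.5)

        # open chromatin over the proxies (except closed-proxy decoys)
        if (mode != "closed_proxy")
          add_peak(min(prox$pos0) - 10L, max(prox$pos0) + 11L)

        bait_id <- sprintf("bait_%02d", i)
        genes <- sprintf("GENE%03d", i)
        if (mode == "planted" && i %% 4L == 0L)
          genes <- c(genes, sprintf("GENE%03db", i))
        for (g in genes)
          baits[nrow(baits) + 1L, ] <- list(bait_id, chrom, fb$start, fb$end,
                                            g, i %% 3L != 0L)
        if (mode != "closed_bait")
          add_peak(fb$start + 5L, fb$start + 45L)
        if (mode == "baited_proxy")
          baits[nrow(baits) + 1L, ] <- list(sprintf("bait_%02dx", i), chrom,
                                            fp$start, fp$end,
                                            sprintf("GENE%03dx", i), FALSE)

        # interaction: other end covers the proxy fragment at the stated
        # resolution; alternate resolutions across loci
        if (i %% 2L == 0L) {
          oe <- fp; res <- "one_fragment"
        } else {
          b4 <- map4[locate_fragment(map4, chrom, mid), ]
          oe <- b4; res <- "four_fragment"
        }
        score <- if (mode == "low_score") round(stats::runif(1, 1, 4.5), 2) else
          round(stats::runif(1, 6, 12), 2)
        interactions[nrow(interactions) + 1L, ] <-
          list(bait_id, chrom, oe$start, oe$end, score, res)

        # expression: every 5th planted locus is planted low (filter decoy)
        low_expr <- mode == "planted" && i %% 5L == 0L
        for (g in genes)
          expression[nrow(expression) + 1L, ] <-
            list(g, if (low_expr) round(stats::runif(1, 0, 0.5), 3) else
                      round(stats::runif(1, 5, 50), 2))

        if (mode == "planted") {
          for (rs in prox$rsid) for (g in genes)
            ledger[nrow(ledger) + 1L, ] <- list(locus_id, rs, g, "planted",
                                                NA_character_, !low_expr)
        } else {
          ledger[nrow(ledger) + 1L, ] <- list(locus_id, srs, genes[1],
                                              "decoy", mode, NA)
        }
      }
      # background genes so planted genes sit above the 50th percentile
      n_bg <- 2L * nrow(expression) + 10L
      expression <- rbind(expression,
                          data.frame(gene = sprintf("BG%04d", seq_len(n_bg)),
                                     tpm = round(stats::runif(n_bg, 0, 1), 3)))
    }
    structure(list(genome = genome, map1 = map1, map4 = map4,
                   sentinels = sentinels, ld = ld, peaks = peaks,
                   baits = baits, interactions = interactions,
                   expression = expression, ledger = ledger,
                   params = list(n_loci = n_loci,
                                 n_proxies_per_locus = n_proxies_per_locus,
                                 genome_length = genome_length,
                                 enzyme = enzyme,
                                 fraction_open = fraction_open,
                                 fraction_looped = fraction_looped,
                                 seed = seed)),
              class = "v2g_landscape")
  })
}

#' @export
print.v2g_landscape <- function(x, ...) {
  cat(sprintf(paste0("<v2g_landscape> %d locus/loci (%d planted link(s), ",
                     "%d decoy(s)), %d fragment(s)\n"),
              nrow(x$sentinels), sum(x$ledger$kind == "planted"),
              sum(x$ledger$kind == "decoy"), nrow(x$map1)))
  invisible(x)
}
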