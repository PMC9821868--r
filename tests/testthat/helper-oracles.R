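# Independent brute-force oracles used across the suite. These deliberately
# use naive algorithms (linear scans, all-pairs joins) so they share no code
# with the implementations they check.

# all cut positions by scanning every substring, then interval bounds
oracle_digest <- function(seq, site, cut_offset) {
  n <- nchar(seq); w <- nchar(site)
  cuts <- integer(0)
  if (w <= n) {
    for (i in seq_len(n - w + 1L)) {
      if (substr(seq, i, i + w - 1L) == site)
        cuts <- c(cuts, (i - 1L) + cut_offset)
    }
  }
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < n], n))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# per-minute sleep state by explicit run accumulation
oracle_fly_state <- function(counts, thr = 5L) {
  n <- length(counts)
  state <- logical(n)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1L] == 0) j <- j + 1L
      if (j - i + 1L >= thr) state[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  state
}

# maximal sleep runs (length >= 1) by explicit scan
oracle_runs <- function(state) {
  out <- NULL
  i <- 1L; n <- length(state)
  while (i <= n) {
    if (state[i]) {
      j <- i
      while (j < n && state[j + 1L]) j <- j + 1L
      out <- rbind(out, data.frame(start = i, len = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) data.frame(start = integer(0), len = integer(0)) else out
}

# all-pairs point-in-interval containment
oracle_overlap <- function(pos0, chrom, peaks) {
  vapply(seq_along(pos0), function(i) {
    hit <- which(peaks$chrom == chrom[i] &
                   peaks$start <= pos0[i] & pos0[i] < peaks$end)
    if (length(hit)) peaks$peak_id[hit[1]] else NA_character_
  }, character(1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# tiny hand-enumerable v2g fixture: 2 loci, one bait of two genes each,
# fragment map built from an explicit sequence
tiny_v2g_fixture <- function() {
  # G-free backbone, then plant the only GATC sites -> cuts at 60, 120, 200
  # and fragments [0,60) [60,120) [120,200) [200,300)
  set.seed(99)
  seq <- paste(sample(c("A", "C", "T"), 300, TRUE), collapse = "")
  substr(seq, 61, 64) <- "GATC"
  substr(seq, 121, 124) <- "GATC"
  substr(seq, 201, 204) <- "GATC"
  map1 <- digest_genome(c(chrT = seq), "DpnII")
  list(
    map1 = map1, map4 = concat_fragments(map1, 4),
    sentinels = data.frame(signal_id = c("s1", "s2"),
                           locus_id = c("L1", "L2"),
                           rsid = c("rsA", "rsB"), chrom = "chrT",
                           pos0 = c(30L, 90L)),
    ld = data.frame(sentinel_id = character(0), rsid = character(0),
                    chrom = character(0), pos0 = integer(0),
                    r2 = numeric(0)),
    peaks = data.frame(peak_id = c("pk1", "pk2", "pk3"), chrom = "chrT",
                       start = c(25L, 85L, 205L), end = c(35L, 95L, 215L)),
    baits = data.frame(bait_id = c("b1", "b1", "b2"), chrom = "chrT",
                       start = c(200L, 200L, 124L), end = c(220L, 220L, 160L),
                       gene = c("G1", "G2", "G3"),
                       coding = c(TRUE, FALSE, TRUE)),
    interactions = data.frame(
      bait_id = c("b1", "b2"), oe_chrom = "chrT",
      oe_start = c(0L, 64L), oe_end = c(60L, 120L),
      score = c(7.5, 6.1), resolution = "one_fragment"),
    expression = data.frame(gene = c("G1", "G2", "G3", "X1", "X2"),
                            tpm = c(10, 0.2, 8, 0.1, 0.3)))
}
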