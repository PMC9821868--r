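test_that("proxy expansion keeps r2 strictly above the cutoff plus the sentinel", {
  sent <- data.frame(signal_id = "s1", locus_id = "L1", rsid = "rs0",
                     chrom = "chr1", pos0 = 100L)
  ld <- data.frame(sentinel_id = "s1", rsid = c("rs1", "rs2", "rs3"),
                   chrom = "chr1", pos0 = c(1L, 2L, 3L),
                   r2 = c(0.84, 0.71, 0.70))
  px <- expand_proxies(sent, ld, 0.7)
  expect_setequal(px$rsid, c("rs0", "rs1", "rs2"))   # 0.70 dropped (strict)
  expect_equal(px$r2[px$rsid == "rs0"], 1)

  # sentinel with no records -> exactly itself
  px0 <- expand_proxies(sent, ld[0, ], 0.7)
  expect_equal(px0$rsid, "rs0")
  # duplicate rsid under one sentinel collapses to max r2
  ld2 <- data.frame(sentinel_id = "s1", rsid = "rs1", chrom = "chr1",
                    pos0 = c(1L, 1L), r2 = c(0.8, 0.95))
  expect_equal(expand_proxies(sent, ld2, 0.7)$r2[2], 0.95)
  # unknown sentinel errors
  ld3 <- data.frame(sentinel_id = "nope", rsid = "rs9", chrom = "chr1",
                    pos0 = 5L, r2 = 0.9)
  expect_error(expand_proxies(sent, ld3, 0.7), "unknown sentinel")
})

test_that("proxy expansion equals a row-by-row filter on random LD tables", {
  set.seed(21)
  sent <- data.frame(signal_id = paste0("s", 1:5), locus_id = paste0("L", 1:5),
                     rsid = paste0("rs_s", 1:5), chrom = "chr1",
                     pos0 = 1:5 * 1000L)
  ld <- data.frame(sentinel_id = sample(sent$signal_id, 200, TRUE),
                   rsid = paste0("rs", sample(1:120, 200, TRUE)),
                   chrom = "chr1", pos0 = sample.int(1e5, 200),
                   r2 = round(runif(200), 3))
  px <- expand_proxies(sent, ld, 0.7)
  naive <- unique(ld[ld$r2 > 0.7, c("sentinel_id", "rsid")])
  got <- px[px$r2 < 1 | px$rsid %in% naive$rsid, ]
  # every kept (sentinel, rsid) is in the naive filter or is the sentinel
  keyp <- paste(px$sentinel_id, px$rsid)
  keyn <- c(paste(naive$sentinel_id, naive$rsid),
            paste(sent$signal_id, sent$rsid))
  expect_setequal(keyp, unique(keyn))
  # max-r2 collapse agrees with aggregate
  agg <- aggregate(r2 ~ sentinel_id + rsid, ld[ld$r2 > 0.7, ], max)
  i <- match(paste(agg$sentinel_id, agg$rsid), keyp)
  expect_equal(px$r2[i], agg$r2)
})

test_that("peak overlap is half-open at single-base resolution", {
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 100L, end = 200L)
  px <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1",
                   pos0 = c(100L, 199L, 200L), r2 = 1,
                   sentinel_id = "s", locus_id = "L",
                   open_flag = NA, peak_id = NA_character_)
  out <- overlap_peaks(px, peaks)
  expect_equal(out$open_flag, c(TRUE, TRUE, FALSE))
  expect_equal(out$peak_id, c("p1", "p1", NA))
  # empty peak set -> all closed
  expect_false(any(overlap_peaks(px, peaks[0, ])$open_flag))
})

test_that("peak overlap equals the all-pairs containment oracle", {
  set.seed(22)
  n <- 2000
  peaks <- data.frame(peak_id = paste0("p", 1:300), chrom = "chr1",
                      start = sort(sample.int(1e5, 300)))
  peaks$end <- peaks$start + sample(50:500, 300, TRUE)
  px <- data.frame(rsid = paste0("r", 1:n), chrom = "chr1",
                   pos0 = sample.int(1e5, n, TRUE), r2 = 1,
                   sentinel_id = "s", locus_id = "L",
                   open_flag = NA, peak_id = NA_character_)
  out <- overlap_peaks(px, peaks)
  want <- oracle_overlap(px$pos0, px$chrom, peaks)
  expect_equal(out$open_flag, !is.na(want))
  expect_equal(out$peak_id, want)
})

test_that("loop annotation applies all four link conditions on the tiny fixture", {
  fx <- tiny_v2g_fixture()
  px <- overlap_peaks(expand_proxies(fx$sentinels, fx$ld, 0.7), fx$peaks)
  baits <- flag_open_baits(fx$baits, fx$peaks)
  links <- annotate_loops(px, fx$interactions, baits, fx$map1, fx$map4, 5)
  # rsA loops to both genes of the open bait b1; rsB's bait b2 is closed
  expect_setequal(paste(links$rsid, links$gene), c("rsA G1", "rsA G2"))
  expect_true(all(links$peak_id == "pk1"))

  # threshold exclusion: score must be strictly above the cutoff
  ints <- fx$interactions; ints$score <- c(5.0, 6.1)
  l2 <- annotate_loops(px, ints, baits, fx$map1, fx$map4, 5)
  expect_equal(nrow(l2), 0L)

  # a proxy inside any baited region yields no link even with a loop
  baits3 <- rbind(baits, data.frame(bait_id = "bx", chrom = "chrT",
                                    start = 25L, end = 40L, gene = "GX",
                                    coding = FALSE, open_flag = FALSE))
  l3 <- annotate_loops(px, fx$interactions, baits3, fx$map1, fx$map4, 5)
  expect_equal(nrow(l3), 0L)

  # unknown bait id in interactions errors
  ints4 <- fx$interactions; ints4$bait_id[1] <- "ghost"
  expect_error(annotate_loops(px, ints4, baits, fx$map1, fx$map4, 5),
               "unknown bait_id")
})

test_that("four-fragment resolution matches the proxy's concatenated fragment", {
  fx <- tiny_v2g_fixture()
  px <- overlap_peaks(expand_proxies(fx$sentinels, fx$ld, 0.7), fx$peaks)
  baits <- flag_open_baits(fx$baits, fx$peaks)
  # other end is the proxies' four-fragment bin (the whole 300 bp here), so
  # both open proxies reach the open bait's genes
  ints <- data.frame(bait_id = "b1", oe_chrom = "chrT", oe_start = 0L,
                     oe_end = 300L, score = 9, resolution = "four_fragment")
  l <- annotate_loops(px, ints, baits, fx$map1, fx$map4, 5)
  expect_setequal(paste(l$rsid, l$gene),
                  c("rsA G1", "rsA G2", "rsB G1", "rsB G2"))
  # but at one-fragment resolution an other end off the proxy fragment fails
  ints1 <- data.frame(bait_id = "b1", oe_chrom = "chrT", oe_start = 120L,
                      oe_end = 200L, score = 9, resolution = "one_fragment")
  expect_equal(nrow(annotate_loops(px, ints1, baits, fx$map1, fx$map4, 5)), 0L)
})

test_that("expression filter uses strict conjunctive thresholds", {
  links <- structure(data.frame(locus_id = "L", sentinel_id = "s",
                                rsid = "r", peak_id = "p", bait_id = "b",
                                gene = c("g1", "g2", "g3", "g4"),
                                coding = TRUE, oe_chrom = "c",
                                oe_start = 0L, oe_end = 1L,
                                resolution = "one_fragment", score = 6,
                                expressed_flag = NA),
                     class = c("v2g_links", "data.frame"))
  expr <- data.frame(gene = c("g1", "g2", "g3"),
                     tpm = c(1.6, 1.5, 100),
                     percentile = c(51, 99, 50))
  out <- filter_expression(links, expr, 1.5, 50)
  # 1.6/51 passes; 1.5 fails (strict); percentile 50 fails (strict);
  # absent gene fails
  expect_equal(out$expressed_flag, c(TRUE, FALSE, FALSE, FALSE))
  # internally computed percentile is an average-tie percent rank
  expect_equal(expression_percentile(c(5, 1, 1, 3)),
               c(100, 37.5, 37.5, 75))
})

test_that("summary counts match hand enumeration on the tiny fixture", {
  fx <- tiny_v2g_fixture()
  res <- v2g_map(fx$sentinels, fx$ld, fx$peaks, fx$baits, fx$interactions,
                 fx$expression, fx$map1, fx$map4)
  s <- res$summary
  expect_equal(s$n_loci_linked, 1L)
  expect_equal(s$n_informative_proxies, 2L)    # rsA and rsB are both open
  expect_equal(s$n_open_regions_linked, 1L)
  expect_equal(s$n_baits, 1L)
  expect_equal(s$n_genes, 2L)
  expect_equal(s$n_coding_genes, 1L)
  expect_equal(s$n_interactions, 1L)
  expect_equal(s$n_expressed_genes, 1L)
  # empty link list -> all-zero counts
  e <- summarize_v2g(annotate_loops(res$proxies, fx$interactions[0, ],
                                    res$baits, fx$map1, fx$map4, 5),
                     res$baits, res$proxies)
  expect_equal(e$n_loci_linked, 0L)
  expect_equal(e$n_genes, 0L)
})

test_that("links are monotone in the interaction set and the score cutoff", {
  land <- gen_landscape(n_loci = 12, seed = 301)
  px <- overlap_peaks(expand_proxies(land$sentinels, land$ld, 0.7), land$peaks)
  baits <- flag_open_baits(land$baits, land$peaks)
  full <- annotate_loops(px, land$interactions, baits, land$map1, land$map4, 5)
  # every emitted link's proxy is open and non-baited; bait open
  expect_true(all(full$rsid %in% px$rsid[px$open_flag]))
  expect_true(all(full$bait_id %in% baits$bait_id[baits$open_flag]))
  # deleting all interactions yields zero links
  expect_equal(nrow(annotate_loops(px, land$interactions[0, ], baits,
                                   land$map1, land$map4, 5)), 0L)
  # dropping interactions never adds links
  sub <- annotate_loops(px, land$interactions[1:5, ], baits,
                        land$map1, land$map4, 5)
  expect_true(all(paste(sub$rsid, sub$gene) %in% paste(full$rsid, full$gene)))
  # raising the cutoff never increases the link count
  n <- vapply(c(5, 6, 8, 10, 12),
              function(ct) nrow(annotate_loops(px, land$interactions, baits,
                                               land$map1, land$map4, ct)), 1L)
  expect_true(all(diff(n) <= 0))
})
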