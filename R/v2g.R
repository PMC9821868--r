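#' Expand GWAS sentinels into LD proxies
#'
#' Keeps every LD record with `r2` strictly greater than `cutoff` and adds
#' each sentinel as its own proxy with `r2 = 1`. Duplicate rsids under the
#' same sentinel are collapsed keeping the maximum r2.
#'
#' @param sentinels data.frame with columns `signal_id`, `locus_id`, `rsid`,
#'   `chrom`, `pos0` (0-based variant position).
#' @param ld data.frame of LD records: `sentinel_id`, `rsid`, `chrom`, `pos0`,
#'   `r2`. May be empty.
#' @param cutoff Proxies require `r2 > cutoff` (strict); default 0.7.
#' @return data.frame of proxies: `rsid`, `chrom`, `pos0`, `r2`,
#'   `sentinel_id`, `locus_id`, `open_flag` (NA until [overlap_peaks()]),
#'   `peak_id`.
#' @export
expand_proxies <- function(sentinels, ld, cutoff = 0.7) {
  stopifnot(all(c("signal_id", "locus_id", "rsid", "chrom", "pos0") %in%
                  names(sentinels)))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (nrow(ld) > 0) {
    stopifnot(all(c("sentinel_id", "rsid", "chrom", "pos0", "r2") %in% names(ld)))
    if (any(ld$r2 < 0 | ld$r2 > 1)) stop("r2 outside [0, 1]")
    unknown <- setdiff(ld$sentinel_id, sentinels$signal_id)
    if (length(unknown))
      stop("ld records reference unknown sentinel_id: ",
           paste(unknown, collapse = ", "))
    keep <- ld[ld$r2 > cutoff, c("sentinel_id", "rsid", "chrom", "pos0", "r2")]
  } else {
    keep <- data.frame(sentinel_id = character(), rsid = character(),
                       chrom = character(), pos0 = integer(), r2 = numeric())
  }
  self <- data.frame(sentinel_id = sentinels$signal_id,
                     rsid = sentinels$rsid, chrom = sentinels$chrom,
                     pos0 = sentinels$pos0, r2 = 1,
                     stringsAsFactors = FALSE)
  all <- rbind(self, keep)
  # collapse duplicates per (sentinel, rsid), keeping max r2
  all <- all[order(all$sentinel_id, all$rsid, -all$r2), ]
  all <- all[!duplicated(all[, c("sentinel_id", "rsid")]), ]
  all$locus_id <- sentinels$locus_id[match(all$sentinel_id, sentinels$signal_id)]
  all$open_flag <- NA
  all$peak_id <- NA_character_
  rownames(all) <- NULL
  all[order(all$locus_id, all$sentinel_id, all$rsid),
      c("rsid", "chrom", "pos0", "r2", "sentinel_id", "locus_id",
        "open_flag", "peak_id")]
}

df_to_granges <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(df[[chrom]],
                         IRanges::IRanges(start = df[[start]] + 1L,
                                          end = df[[end]]))
}

#' Flag proxies residing in open chromatin
#'
#' Sets `open_flag`/`peak_id` on every proxy whose single-base position falls
#' inside an open-chromatin peak (`start <= pos0 < end`). Overlap is computed
#' with an interval-index join, not all pairs.
#'
#' @param proxies data.frame from [expand_proxies()].
#' @param peaks data.frame with `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return `proxies` with `open_flag` and `peak_id` filled in. When several
#'   peaks cover a position the first peak in `peaks` order is recorded.
#' @export
overlap_peaks <- function(proxies, peaks) {
  proxies$open_flag <- FALSE
  proxies$peak_id <- NA_character_
  if (nrow(peaks) == 0L || nrow(proxies) == 0L) return(proxies)
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)),
            all(peaks$start < peaks$end))
  pg <- GenomicRanges::GRanges(proxies$chrom,
                               IRanges::IRanges(proxies$pos0 + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(pg, df_to_granges(peaks),
                                     select = "first")
  got <- !is.na(hit)
  proxies$open_flag[got] <- TRUE
  proxies$peak_id[got] <- peaks$peak_id[hit[got]]
  proxies
}

#' Flag baited promoters overlapping open chromatin
#'
#' A bait is "open" when its genomic interval overlaps at least one peak.
#'
#' @param baits data.frame with one row per (bait, gene): `bait_id`, `chrom`,
#'   `start`, `end`, `gene`, `coding` (logical).
#' @param peaks Peak data.frame as in [overlap_peaks()].
#' @return `baits` with a logical `open_flag` column.
#' @export
flag_open_baits <- function(baits, peaks) {
  if (nrow(baits) == 0L) {
    baits$open_flag <- logical(0)
    return(baits)
  }
  if (nrow(peaks) == 0L) {
    baits$open_flag <- FALSE
    return(baits)
  }
  hit <- GenomicRanges::findOverlaps(df_to_granges(baits),
                                     df_to_granges(peaks), select = "first")
  baits$open_flag <- !is.na(hit)
  baits
}

#' Annotate chromatin loops between open proxies and open promoters
#'
#' Emits one candidate variant-to-gene link for every gene of every baited
#' promoter such that (i) the proxy lies in open chromatin, (ii) the proxy
#' does not fall inside any baited region (non-bait-to-bait), (iii) an
#' interaction with score strictly above `score_cutoff` has its other end
#' overlapping the proxy's restriction fragment at the interaction's stated
#' resolution, and (iv) the bait is open. Links are deduplicated on
#' (proxy, bait, gene), keeping the highest-scoring qualifying interaction.
#'
#' @param proxies data.frame from [overlap_peaks()] (needs `open_flag`).
#' @param interactions data.frame: `bait_id`, `oe_chrom`, `oe_start`,
#'   `oe_end`, `score`, `resolution` (`"one_fragment"` or `"four_fragment"`).
#' @param baits data.frame from [flag_open_baits()].
#' @param map1,map4 [digest_genome()] maps at native and four-fragment
#'   resolution (see [concat_fragments()]).
#' @param score_cutoff Interactions require `score > score_cutoff`; default 5.
#' @return data.frame of links, class `v2g_links`: `locus_id`, `sentinel_id`,
#'   `rsid`, `peak_id`, `bait_id`, `gene`, `coding`, `oe_chrom`, `oe_start`,
#'   `oe_end`, `resolution`, `score`, `expressed_flag` (NA until
#'   [filter_expression()]). The distinct qualifying interactions (before link
#'   deduplication) are kept in `attr(, "qualifying_interactions")`.
#' @export
annotate_loops <- function(proxies, interactions, baits, map1, map4,
                           score_cutoff = 5) {
  if (score_cutoff <= 0) stop("score_cutoff must be > 0")
  stopifnot(all(c("bait_id", "oe_chrom", "oe_start", "oe_end", "score",
                  "resolution") %in% names(interactions)),
            all(c("bait_id", "chrom", "start", "end", "gene", "coding",
                  "open_flag") %in% names(baits)))
  if (nrow(interactions) > 0) {
    bad_res <- setdiff(unique(interactions$resolution),
                       c("one_fragment", "four_fragment"))
    if (length(bad_res)) stop("unknown resolution: ", paste(bad_res, collapse = ", "))
    unknown <- setdiff(interactions$bait_id, baits$bait_id)
    if (length(unknown))
      stop("interaction references unknown bait_id: ",
           paste(unknown, collapse = ", "))
    if (any(interactions$score < 0)) stop("negative interaction score")
  }

  empty <- data.frame(locus_id = character(), sentinel_id = character(),
                      rsid = character(), peak_id = character(),
                      bait_id = character(), gene = character(),
                      coding = logical(), oe_chrom = character(),
                      oe_start = integer(), oe_end = integer(),
                      resolution = character(), score = numeric(),
                      expressed_flag = logical(), stringsAsFactors = FALSE)
  qual0 <- empty[, c("bait_id", "oe_chrom", "oe_start", "oe_end",
                     "resolution", "score")]

  open <- proxies[isTRUE_v(proxies$open_flag), , drop = FALSE]
  ints <- interactions[interactions$score > score_cutoff, , drop = FALSE]
  if (nrow(open) == 0L || nrow(ints) == 0L)
    return(structure(empty, qualifying_interactions = qual0,
                     class = c("v2g_links", "data.frame")))

  # non-bait-to-bait: drop proxies whose position lies inside ANY bait region
  bait_regions <- unique(baits[, c("bait_id", "chrom", "start", "end")])
  pg <- GenomicRanges::GRanges(open$chrom,
                               IRanges::IRanges(open$pos0 + 1L, width = 1L))
  in_bait <- !is.na(GenomicRanges::findOverlaps(pg, df_to_granges(bait_regions),
                                                select = "first"))
  open <- open[!in_bait, , drop = FALSE]
  if (nrow(open) == 0L)
    return(structure(empty, qualifying_interactions = qual0,
                     class = c("v2g_links", "data.frame")))

  # proxy fragment interval at each resolution
  frag_interval <- function(map) {
    i <- locate_fragment(map, open$chrom, open$pos0)
    data.frame(chrom = map$chrom[i], start = map$start[i], end = map$end[i])
  }
  pieces <- lapply(c(one_fragment = 1, four_fragment = 4), function(res_k) {
    map <- if (res_k == 1) map1 else map4
    res <- if (res_k == 1) "one_fragment" else "four_fragment"
    sub <- ints[ints$resolution == res, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    fi <- frag_interval(map)
    hits <- GenomicRanges::findOverlaps(
      df_to_granges(fi),
      df_to_granges(sub, "oe_chrom", "oe_start", "oe_end"))
    if (length(hits) == 0L) return(NULL)
    data.frame(proxy_row = S4Vectors::queryHits(hits),
               sub[S4Vectors::subjectHits(hits),
                   c("bait_id", "oe_chrom", "oe_start", "oe_end",
                     "resolution", "score")],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pieces)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(structure(empty, qualifying_interactions = qual0,
                     class = c("v2g_links", "data.frame")))

  open_baits <- baits[baits$open_flag, , drop = FALSE]
  links <- merge(pairs, open_baits[, c("bait_id", "gene", "coding")],
                 by = "bait_id")
  if (nrow(links) == 0L)
    return(structure(empty, qualifying_interactions = qual0,
                     class = c("v2g_links", "data.frame")))
  links <- data.frame(open[links$proxy_row,
                           c("locus_id", "sentinel_id", "rsid", "peak_id")],
                      links[, c("bait_id", "gene", "coding", "oe_chrom",
                                "oe_start", "oe_end", "resolution", "score")],
                      stringsAsFactors = FALSE)
  qual <- unique(links[, c("bait_id", "oe_chrom", "oe_start", "oe_end",
                           "resolution", "score")])
  rownames(qual) <- NULL
  # dedupe (proxy, bait, gene), keep best score; deterministic ordering
  links <- links[order(links$locus_id, links$rsid, links$gene, -links$score,
                       links$oe_start), ]
  links <- links[!duplicated(links[, c("rsid", "bait_id", "gene")]), ]
  links$expressed_flag <- NA
  rownames(links) <- NULL
  structure(links, qualifying_interactions = qual,
            class = c("v2g_links", "data.frame"))
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.v2g_links <- function(x, ...) {
  cat(sprintf("<v2g_links> %d link(s): %d locus/loci, %d gene(s)\n",
              nrow(x), length(unique(x$locus_id)), length(unique(x$gene))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Percent rank of expression
#'
#' Percentile of each gene's TPM among all genes in the table: ties get the
#' average rank, and the top-ranked gene has percentile 100.
#'
#' @param tpm Numeric vector of TPM values.
#' @return Percentiles in (0, 100].
#' @export
expression_percentile <- function(tpm) {
  100 * rank(tpm, ties.method = "average") / length(tpm)
}

#' Annotate links with an expression filter
#'
#' A link's gene is flagged expressed when `tpm > tpm_min` AND
#' `percentile > pct_min` (both strict). Genes absent from the table are
#' flagged not expressed. Links are annotated, never removed.
#'
#' @param links [annotate_loops()] output.
#' @param expression data.frame `gene`, `tpm` and optionally `percentile`
#'   (computed with [expression_percentile()] when absent).
#' @param tpm_min,pct_min Strict lower thresholds; defaults 1.5 TPM and the
#'   50th percentile.
#' @return `links` with `expressed_flag` set.
#' @export
filter_expression <- function(links, expression, tpm_min = 1.5, pct_min = 50) {
  if (tpm_min < 0 || pct_min < 0) stop("thresholds must be >= 0")
  stopifnot(all(c("gene", "tpm") %in% names(expression)))
  if (!"percentile" %in% names(expression))
    expression$percentile <- expression_percentile(expression$tpm)
  i <- match(links$gene, expression$gene)
  links$expressed_flag <- !is.na(i) &
    expression$tpm[i] > tpm_min & expression$percentile[i] > pct_min
  links
}

#' Summarize a variant-to-gene mapping
#'
#' Tabulates the headline counts of a V2G run: loci implicated in at least
#' one loop, informative (open-chromatin) proxies, distinct open regions,
#' baited promoters, genes (and coding genes), distinct looping interactions,
#' and expressed genes.
#'
#' @param links [annotate_loops()] (optionally [filter_expression()]) output.
#' @param baits,proxies The inputs the links were derived from.
#' @return A `v2g_summary` (named list of counts).
#' @export
summarize_v2g <- function(links, baits, proxies) {
  qi <- attr(links, "qualifying_interactions")
  if (is.null(qi))
    qi <- unique(links[, c("bait_id", "oe_chrom", "oe_start", "oe_end",
                           "resolution")])
  expressed <- if (all(is.na(links$expressed_flag))) NA_integer_ else
    length(unique(links$gene[isTRUE_v(links$expressed_flag)]))
  structure(list(
    n_loci_linked = length(unique(links$locus_id)),
    n_informative_proxies = sum(isTRUE_v(proxies$open_flag)),
    n_informative_loci = length(unique(
      proxies$locus_id[isTRUE_v(proxies$open_flag)])),
    n_open_regions_linked = length(unique(links$peak_id)),
    n_baits = length(unique(links$bait_id)),
    n_genes = length(unique(links$gene)),
    n_coding_genes = length(unique(links$gene[links$coding])),
    n_interactions = nrow(unique(qi[, c("bait_id", "oe_chrom", "oe_start",
                                        "oe_end", "resolution")])),
    n_expressed_genes = expressed
  ), class = "v2g_summary")
}

#' @export
print.v2g_summary <- function(x, ...) {
  cat("<v2g_summary>\n")
  lab <- c(n_loci_linked = "loci implicated in a chromatin loop",
           n_informative_proxies = "informative proxies in open chromatin",
           n_informative_loci = "loci with informative proxies",
           n_open_regions_linked = "open regions connected to promoters",
           n_baits = "open baited promoter regions",
           n_genes = "genes", n_coding_genes = "coding genes",
           n_interactions = "distinct looping interactions",
           n_expressed_genes = "expressed genes")
  for (k in names(lab))
    cat(sprintf("  %-42s %s\n", lab[[k]],
                ifelse(is.na(x[[k]]), "-", x[[k]])))
  invisible(x)
}

#' Run the full variant-to-gene mapping chain
#'
#' Convenience wrapper: [expand_proxies()] -> [overlap_peaks()] ->
#' [flag_open_baits()] -> [annotate_loops()] -> [filter_expression()] ->
#' [summarize_v2g()].
#'
#' @param sentinels,ld,peaks,baits,interactions,expression Input tables, in
#'   the internal dialects (see the respective stage functions and the
#'   readers in [read_sentinels_tsv()] and friends).
#' @param map1 Native-resolution fragment map; `map4` defaults to
#'   `concat_fragments(map1, 4)`.
#' @param map4 Four-fragment map.
#' @param r2_cutoff,score_cutoff,tpm_min,pct_min Thresholds, all strict.
#' @return List of class `v2g_result`: `proxies`, `baits`, `links`, `summary`.
#' @export
v2g_map <- function(sentinels, ld, peaks, baits, interactions, expression,
                    map1, map4 = concat_fragments(map1, 4),
                    r2_cutoff = 0.7, score_cutoff = 5,
                    tpm_min = 1.5, pct_min = 50) {
  proxies <- overlap_peaks(expand_proxies(sentinels, ld, r2_cutoff), peaks)
  baits <- flag_open_baits(baits, peaks)
  links <- annotate_loops(proxies, interactions, baits, map1, map4,
                          score_cutoff)
  links <- filter_expression(links, expression, tpm_min, pct_min)
  structure(list(proxies = proxies, baits = baits, links = links,
                 summary = summarize_v2g(links, baits, proxies)),
            class = "v2g_result")
}

#' @export
print.v2g_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
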