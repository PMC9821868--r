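#' Read a genome FASTA
#'
#' @param path Plain or gzipped FASTA file.
#' @return A [Biostrings::DNAStringSet] with header descriptions stripped to
#'   the first word.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences as FASTA
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output file.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

stop_malformed <- function(path, lines, what) {
  stop(sprintf("%s: malformed %s at line(s) %s", path, what,
               paste(utils::head(lines, 5), collapse = ", ")))
}

read_tsv_cols <- function(path, cols, what, numeric_cols = character(0)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s in %s", path,
                 paste(miss, collapse = ", "), what))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) stop_malformed(path, bad + 1L, paste(what, "column", cc))
    df[[cc]] <- v
  }
  df
}

#' Fragment maps and peaks as BED
#'
#' `write_fragment_bed()` writes a [digest_genome()] map as 4-column BED
#' with `name = chrom.index`; `read_peaks_bed()`/`write_peaks_bed()` handle
#' open-chromatin peaks (name = `peak_id`, autogenerated when the file has
#' only 3 columns).
#'
#' @param map A `fragment_map`.
#' @param path File path.
#' @return The path (writers, invisibly) or a data.frame (readers).
#' @export
write_fragment_bed <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  utils::write.table(
    data.frame(map$chrom, map$start, map$end,
               paste0(map$chrom, ".", map$index)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed3plus <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  bad <- which(nf < 3L)
  if (length(bad)) stop_malformed(path, bad, what)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stop_malformed(path, bad, what)
  data.frame(chrom = vapply(parts, `[`, "", 1L), start = start, end = end,
             name = ifelse(nf >= 4L, vapply(parts, function(p)
               if (length(p) >= 4L) p[4L] else NA_character_, ""),
               NA_character_),
             stringsAsFactors = FALSE)
}

#' @rdname write_fragment_bed
#' @export
read_peaks_bed <- function(path) {
  df <- read_bed3plus(path, "peak BED record")
  df$peak_id <- ifelse(is.na(df$name), sprintf("peak_%03d", seq_len(nrow(df))),
                       df$name)
  df[, c("peak_id", "chrom", "start", "end")]
}

#' @rdname write_fragment_bed
#' @param peaks Peak data.frame (`peak_id`, `chrom`, `start`, `end`).
#' @export
write_peaks_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Baited-promoter BED with gene annotation
#'
#' The BED name field encodes `bait_id|gene1,gene2|coding_flags` with one
#' 0/1 coding flag per gene; the reader expands to one row per (bait, gene).
#'
#' @param path File path.
#' @return Reader: data.frame `bait_id`, `chrom`, `start`, `end`, `gene`,
#'   `coding`.
#' @export
read_baits_bed <- function(path) {
  df <- read_bed3plus(path, "bait BED record")
  if (nrow(df) == 0L)
    return(data.frame(bait_id = character(), chrom = character(),
                      start = integer(), end = integer(), gene = character(),
                      coding = logical()))
  fields <- strsplit(df$name, "|", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 3L | is.na(df$name))
  if (length(bad)) stop_malformed(path, bad, "bait name field")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    genes <- strsplit(fields[[i]][2], ",", fixed = TRUE)[[1]]
    flags <- strsplit(fields[[i]][3], "", fixed = TRUE)[[1]]
    if (length(flags) != length(genes) || any(!flags %in% c("0", "1")))
      stop_malformed(path, i, "bait coding flags")
    data.frame(bait_id = fields[[i]][1], chrom = df$chrom[i],
               start = df$start[i], end = df$end[i], gene = genes,
               coding = flags == "1", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname read_baits_bed
#' @param baits data.frame as returned by `read_baits_bed()`.
#' @export
write_baits_bed <- function(baits, path) {
  key <- baits[!duplicated(baits$bait_id), c("bait_id", "chrom", "start", "end")]
  name <- vapply(key$bait_id, function(b) {
    sub <- baits[baits$bait_id == b, ]
    paste(b, paste(sub$gene, collapse = ","),
          paste(ifelse(sub$coding, "1", "0"), collapse = ""), sep = "|")
  }, "")
  utils::write.table(data.frame(key$chrom, key$start, key$end, name), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Sentinel, LD, interaction and expression tables
#'
#' TSV dialects with headers. Variant positions are 1-based in files
#' (`pos_1based`) and converted to the internal 0-based `pos0` here, the
#' only place base conversion happens.
#'
#' @param path File path.
#' @name v2g_io
NULL

#' @rdname v2g_io
#' @export
read_sentinels_tsv <- function(path) {
  df <- read_tsv_cols(path, c("signal_id", "locus_id", "rsid", "chrom",
                              "pos_1based"), "sentinel table", "pos_1based")
  if (any(df$pos_1based < 1)) stop(path, ": pos_1based must be >= 1")
  df$pos0 <- as.integer(df$pos_1based) - 1L
  df[, c("signal_id", "locus_id", "rsid", "chrom", "pos0")]
}

#' @rdname v2g_io
#' @param sentinels Internal sentinel table.
#' @export
write_sentinels_tsv <- function(sentinels, path) {
  out <- data.frame(sentinels[, c("signal_id", "locus_id", "rsid", "chrom")],
                    pos_1based = sentinels$pos0 + 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname v2g_io
#' @export
read_ld_tsv <- function(path) {
  df <- read_tsv_cols(path, c("sentinel_id", "rsid", "chrom", "pos_1based",
                              "r2"), "LD table", c("pos_1based", "r2"))
  df$pos0 <- as.integer(df$pos_1based) - 1L
  df[, c("sentinel_id", "rsid", "chrom", "pos0", "r2")]
}

#' @rdname v2g_io
#' @param ld Internal LD table.
#' @export
write_ld_tsv <- function(ld, path) {
  out <- data.frame(ld[, c("sentinel_id", "rsid", "chrom")],
                    pos_1based = ld$pos0 + 1L, r2 = ld$r2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname v2g_io
#' @export
read_interactions_ibed <- function(path) {
  df <- read_tsv_cols(path, c("bait_chrom", "bait_start", "bait_end",
                              "bait_id", "oe_chrom", "oe_start", "oe_end",
                              "score", "resolution"), "ibed table",
                      c("bait_start", "bait_end", "oe_start", "oe_end",
                        "score"))
  bad <- which(!df$resolution %in% c("one_fragment", "four_fragment"))
  if (length(bad)) stop_malformed(path, bad + 1L, "ibed resolution")
  df
}

#' @rdname v2g_io
#' @param interactions Interaction table with bait coordinates (the
#'   internal `bait_id`-keyed table is joined against `baits` by
#'   [write_interactions_ibed()]).
#' @param baits Bait table supplying bait coordinates.
#' @export
write_interactions_ibed <- function(interactions, baits, path) {
  key <- baits[!duplicated(baits$bait_id), c("bait_id", "chrom", "start", "end")]
  i <- match(interactions$bait_id, key$bait_id)
  if (anyNA(i)) stop("interaction references unknown bait_id")
  out <- data.frame(bait_chrom = key$chrom[i], bait_start = key$start[i],
                    bait_end = key$end[i], bait_id = interactions$bait_id,
                    interactions[, c("oe_chrom", "oe_start", "oe_end",
                                     "score", "resolution")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname v2g_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("gene", "tpm")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (any(df$tpm < 0)) stop(path, ": negative TPM")
  df
}

#' @rdname v2g_io
#' @param expression Expression table.
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drosophila activity-monitor files
#'
#' Tab-delimited monitor dialect: reading index, date (`d Mon yy`), time
#' (`HH:MM:SS`), a status flag (1 = valid reading), six unused metadata
#' fields, then 32 per-channel beam-crossing counts — one row per minute.
#'
#' @param path File path.
#' @return `read_dam()`: list with `counts` (minutes x 32 matrix) and
#'   `time` (character vector of row times).
#' @export
read_dam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 42L)
  if (length(bad)) stop_malformed(path, bad, "monitor row (42 fields expected)")
  counts <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.integer(p[11:42]))
    v
  }, integer(32)))
  bad <- which(apply(is.na(counts), 1, any))
  if (length(bad)) stop_malformed(path, bad, "monitor counts")
  status <- vapply(parts, `[`, "", 4L)
  if (any(status != "1"))
    stop_malformed(path, which(status != "1"), "monitor status flag")
  colnames(counts) <- sprintf("ch%02d", 1:32)
  list(counts = counts, time = vapply(parts, `[`, "", 3L))
}

#' @rdname read_dam
#' @param counts Minutes x channels matrix (up to 32 channels; zero-padded).
#' @param start_time First row's clock time in minutes after midnight.
#' @export
write_dam <- function(counts, path, start_time = 540L) {
  n <- nrow(counts)
  full <- matrix(0L, n, 32)
  full[, seq_len(ncol(counts))] <- counts
  mins <- (start_time + seq_len(n) - 1L)
  day <- 1L + mins %/% 1440L
  tod <- mins %% 1440L
  rows <- paste(seq_len(n),
                sprintf("%d Jan 24", day),
                sprintf("%02d:%02d:00", tod %/% 60L, tod %% 60L),
                "1", "1", "0", "0", "0", "0", "0",
                apply(full, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Zebrafish tracking export
#'
#' Long-format CSV (`larva_id`, `clock_time` "HH:MM", `movement_sec`), one
#' row per larva-minute, as produced by quantization-mode tracking at 60-s
#' bins.
#'
#' @param path File path.
#' @return `read_tracking_csv()`: list with `movement` (minutes x larvae
#'   matrix, in file order) and `clock_start_min`.
#' @export
read_tracking_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "clock_time", "movement_sec")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  ids <- unique(df$larva_id)
  per <- split(df, factor(df$larva_id, levels = ids))
  n <- unique(vapply(per, nrow, 1L))
  if (length(n) != 1L) stop(path, ": larvae have unequal trace lengths")
  movement <- vapply(per, function(d) d$movement_sec, numeric(n))
  list(movement = movement,
       clock_start_min = parse_clock(df$clock_time[1]))
}

#' @rdname read_tracking_csv
#' @param movement Minutes x larvae matrix (column names = larva ids).
#' @param clock_start_min Minute-of-day of the first row.
#' @export
write_tracking_csv <- function(movement, path, clock_start_min = 540L) {
  n <- nrow(movement)
  tod <- (clock_start_min + seq_len(n) - 1L) %% 1440L
  clock <- sprintf("%02d:%02d", tod %/% 60L, tod %% 60L)
  ids <- colnames(movement)
  if (is.null(ids)) ids <- sprintf("larva_%03d", seq_len(ncol(movement)))
  out <- data.frame(
    larva_id = rep(ids, each = n),
    clock_time = rep(clock, ncol(movement)),
    movement_sec = as.vector(movement))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all landscape files in their consumed dialects
#'
#' Materializes a [gen_landscape()] result as FASTA + TSV/BED files exactly
#' as the readers in this package expect them.
#'
#' @param landscape A `v2g_landscape`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_genome_fasta(landscape$genome, f("genome.fa"))
  write_sentinels_tsv(landscape$sentinels, f("sentinels.tsv"))
  write_ld_tsv(landscape$ld, f("ld.tsv"))
  write_peaks_bed(landscape$peaks, f("peaks.bed"))
  write_baits_bed(landscape$baits, f("baits.bed"))
  write_interactions_ibed(landscape$interactions, landscape$baits,
                          f("interactions.ibed"))
  write_expression_tsv(landscape$expression, f("expression.tsv"))
  utils::write.table(landscape$ledger, f("ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(genome = f("genome.fa"), sentinels = f("sentinels.tsv"),
    ld = f("ld.tsv"), peaks = f("peaks.bed"), baits = f("baits.bed"),
    interactions = f("interactions.ibed"), expression = f("expression.tsv"),
    ledger = f("ledger.tsv"))
}
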