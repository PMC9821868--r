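#' Restriction enzyme definition
#'
#' Describes a restriction enzyme by its recognition site and the offset,
#' in bases from the start of the site, at which the enzyme cleaves.
#' Only palindromic recognition sites are supported: for those, scanning the
#' forward strand finds every cut site, so a single-strand scan is complete.
#'
#' @param name Enzyme name. The built-ins `"DpnII"` (GATC, cleaves 5' of the
#'   site, offset 0) and `"HindIII"` (A^AGCTT, offset 1) can be requested by
#'   name alone; case is ignored.
#' @param site Recognition site, uppercase ACGT only. Ignored for built-ins.
#' @param cut_offset Integer in `[0, nchar(site)]`: bases from the site start
#'   to the cleavage position. Ignored for built-ins.
#' @return An object of class `restriction_enzyme`: a list with elements
#'   `name`, `site` and `cut_offset`.
#' @examples
#' restriction_enzyme("DpnII")
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, site = NULL, cut_offset = NULL) {
  builtin <- list(
    dpnii   = list(name = "DpnII",   site = "GATC",   cut_offset = 0L),
    hindiii = list(name = "HindIII", site = "AAGCTT", cut_offset = 1L)
  )
  key <- tolower(gsub("[ _-]", "", name))
  if (is.null(site) && key %in% names(builtin)) {
    enz <- builtin[[key]]
  } else {
    if (is.null(site) || is.null(cut_offset))
      stop("unknown enzyme '", name, "': supply `site` and `cut_offset`")
    enz <- list(name = name, site = toupper(site),
                cut_offset = as.integer(cut_offset))
  }
  if (!nzchar(enz$site) || grepl("[^ACGT]", enz$site))
    stop("recognition site must be a nonempty uppercase ACGT string")
  if (enz$cut_offset < 0L || enz$cut_offset > nchar(enz$site))
    stop("cut_offset must lie in [0, site length]")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(enz$site)))
  if (rc != enz$site)
    stop("recognition site '", enz$site,
         "' is not palindromic; forward-strand scanning would miss cuts")
  structure(enz, class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s, cut offset %d\n",
              x$name, x$site, x$cut_offset))
  invisible(x)
}

new_fragment_map <- function(frags, chrom_lengths, resolution_k) {
  rownames(frags) <- NULL
  structure(frags,
            chrom_lengths = chrom_lengths,
            resolution_k = as.integer(resolution_k),
            class = c("fragment_map", "data.frame"))
}

#' In-silico restriction digestion of a genome
#'
#' Scans each sequence for occurrences of the enzyme's recognition site on the
#' forward strand (sufficient because sites are palindromic; sites overlapping
#' an N never match) and cuts at `site start + cut_offset`. Fragments are the
#' intervals between consecutive cut positions plus the sequence ends, so each
#' chromosome is tiled exactly by its fragments.
#'
#' @param seqs A named [Biostrings::DNAStringSet], or a named character vector
#'   of DNA sequences (one per chromosome).
#' @param enzyme A [restriction_enzyme()], or a name understood by it.
#' @return A `fragment_map`: a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `index` (0-based ordinal within chromosome), with
#'   attributes `chrom_lengths` and `resolution_k = 1`.
#' @examples
#' digest_genome(c(chr1 = "AAGATCCGATCAA"), "DpnII")
#' @export
digest_genome <- function(seqs, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (!methods::is(seqs, "DNAStringSet"))
    stop("`seqs` must be a DNAStringSet or named character vector")
  if (length(seqs) == 0L) stop("no sequences to digest")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  lens <- Biostrings::width(seqs)
  if (any(lens == 0L)) stop("empty sequence: ", names(seqs)[lens == 0L][1L])
  # names in FASTA headers may carry descriptions; keep first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  hits <- Biostrings::vmatchPattern(enzyme$site, seqs, fixed = TRUE)
  frags <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    len <- lens[i]
    cuts <- Biostrings::startIndex(hits)[[i]]
    cuts <- if (is.null(cuts)) integer(0) else (cuts - 1L) + enzyme$cut_offset
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < len], len))
    data.frame(chrom = names(seqs)[i],
               start = bounds[-length(bounds)],
               end   = bounds[-1L],
               index = seq_len(length(bounds) - 1L) - 1L,
               stringsAsFactors = FALSE)
  }))
  new_fragment_map(frags, stats::setNames(as.integer(lens), names(seqs)), 1L)
}

#' @export
print.fragment_map <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("<fragment_map> %d fragments on %d sequence(s), resolution k=%d\n",
              nrow(x), length(cl), attr(x, "resolution_k")))
  st <- fragment_stats(x)
  cat(sprintf("  fragment length: mean %.1f bp, median %.1f bp\n",
              st$mean_length, st$median_length))
  invisible(x)
}

#' Concatenate consecutive restriction fragments
#'
#' Merges runs of `k` consecutive fragments within each chromosome into a
#' single spanning fragment (a final run shorter than `k` forms one smaller
#' fragment), as used to call promoter interactions at four-fragment
#' resolution. Tiling is preserved.
#'
#' @param map A native-resolution `fragment_map` (`resolution_k = 1`).
#' @param k Number of consecutive fragments per merged bin (`k >= 1`).
#' @return A `fragment_map` with `resolution_k = k`.
#' @export
concat_fragments <- function(map, k) {
  stopifnot(inherits(map, "fragment_map"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (attr(map, "resolution_k") != 1L)
    stop("`map` must be at native resolution (resolution_k = 1)")
  if (k == 1L) return(map)
  parts <- lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    grp <- map$index[idx] %/% k
    data.frame(chrom = map$chrom[idx[1L]],
               start = tapply(map$start[idx], grp, min),
               end   = tapply(map$end[idx], grp, max),
               index = sort(unique(grp)),
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, parts)
  frags <- frags[order(match(frags$chrom, names(attr(map, "chrom_lengths"))),
                       frags$start), ]
  new_fragment_map(frags, attr(map, "chrom_lengths"), k)
}

#' Fragment length statistics
#'
#' @param map A `fragment_map`.
#' @return List with `mean_length` and `median_length` of all fragment lengths
#'   across chromosomes (an even count's median averages the two central
#'   values, as [stats::median] does).
#' @export
fragment_stats <- function(map) {
  stopifnot(inherits(map, "fragment_map"))
  if (nrow(map) == 0L) stop("empty fragment map")
  len <- map$end - map$start
  list(mean_length = mean(len), median_length = stats::median(len),
       n_fragments = nrow(map))
}

#' Map genomic positions to restriction fragments
#'
#' Binary-search lookup of the unique fragment containing each position.
#'
#' @param map A `fragment_map`.
#' @param chrom Chromosome name(s), recycled against `position`.
#' @param position 0-based position(s) within the chromosome.
#' @return The row indices into `map` of the containing fragments.
#' @export
locate_fragment <- function(map, chrom, position) {
  stopifnot(inherits(map, "fragment_map"))
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n); position <- rep_len(position, n)
  cl <- attr(map, "chrom_lengths")
  bad <- !(chrom %in% names(cl))
  if (any(bad)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[bad]), collapse = ", "))
  oob <- position < 0 | position >= cl[chrom]
  if (any(oob)) stop("position out of bounds on ",
                     paste(unique(chrom[oob]), collapse = ", "))
  out <- integer(n)
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    rows <- which(map$chrom == cn)
    out[sel] <- rows[findInterval(position[sel], map$start[rows])]
  }
  out
}
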