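#' Construct a set of genomic intervals
#'
#' Intervals are represented as a plain data frame in the package's internal
#' coordinate convention: 0-based, half-open `[start, end)`. Conversions to
#' and from 1-based file formats (MAF) happen only at file boundaries.
#'
#' @param chrom Character vector of chromosome names. A leading `"chr"`
#'   prefix is stripped so UCSC-style and ensembl-style naming interoperate.
#' @param start Integer vector, 0-based inclusive start positions (bp).
#' @param end Integer vector, 0-based exclusive end positions (bp).
#' @param source Optional character vector of per-interval source tags.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   supplied, `source`.
#' @export
genomic_intervals <- function(chrom, start, end, source = NULL) {
  chrom <- norm_chrom(as.character(chrom))
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0) {
    if (any(is.na(chrom) | !nzchar(chrom))) stop("chromosome names must be non-empty")
    if (any(is.na(start)) || any(is.na(end))) stop("interval coordinates must not be NA")
    if (any(start < 0)) stop("interval start must be >= 0")
    if (any(end <= start)) stop("interval end must be > start")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(source)) out$source <- as.character(source)
  out
}

# strip a UCSC-style "chr" prefix; "chrM"/"MT" naming differences beyond the
# prefix are the caller's concern
norm_chrom <- function(x) sub("^chr", "", x)

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

# 0-based half-open data frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# merge overlapping/abutting intervals; result sorted by (chrom, start)
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(empty_intervals())
  gr <- GenomicRanges::reduce(GenomicRanges::sort(as_granges0(df)))
  granges_to_df0(gr)
}

#' Scan a nucleotide sequence for homopolymer runs
#'
#' Finds all maximal runs of a single repeated base with run length at least
#' `min_len`. The scan is case-insensitive (soft-masked references do not
#' hide repeats); runs of `N` are never reported and an `N` always breaks a
#' run.
#'
#' @param sequence A nucleotide string (character scalar or
#'   [Biostrings::DNAString]) over the alphabet `A,C,G,T,N` in either case.
#' @param chrom Chromosome name attached to the reported intervals.
#' @param min_len Minimum run length to report (default 5, the conventional
#'   mononucleotide-repeat cutoff).
#' @return A data frame of intervals (0-based half-open) with
#'   `source = "homopolymer"`.
#' @examples
#' scan_homopolymers("AAAACCCCC", "chr1")  # only the C run qualifies
#' @export
scan_homopolymers <- function(sequence, chrom, min_len = 5L) {
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1)
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 2) stop("min_len must be >= 2")
  if (nchar(sequence) == 0) return(empty_intervals())
  s <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0)
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  r <- rle(v)
  ends <- cumsum(r$lengths)           # 1-based inclusive run ends
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values != "N"
  if (!any(keep)) return(empty_intervals())
  genomic_intervals(chrom = rep(chrom, sum(keep)),
                    start = starts[keep] - 1L,
                    end = ends[keep],
                    source = "homopolymer")
}

#' Scan every sequence of a FASTA file for homopolymer runs
#'
#' @param path Path to a FASTA file. Sequence names are truncated at the
#'   first whitespace and `"chr"` prefixes are stripped.
#' @param min_len Minimum run length (see [scan_homopolymers()]).
#' @return A data frame of homopolymer intervals across all sequences.
#' @export
scan_homopolymers_fasta <- function(path, min_len = 5L) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- norm_chrom(sub("\\s.*$", "", names(seqs)))
  out <- lapply(seq_along(seqs), function(i)
    scan_homopolymers(as.character(seqs[[i]]), names(seqs)[i], min_len))
  do.call(rbind, c(out, list(empty_intervals())))
}

#' Load di-/tri-/tetranucleotide repeats from a simpleRepeats-style table
#'
#' Reads a tab-separated tandem-repeat table in the UCSC `simpleRepeats`
#' layout (0-based half-open coordinates) and keeps only rows whose repeat
#' period (unit size) is 2, 3 or 4 — the microsatellite classes used for
#' MSI assessment. Filtering uses the `period` column only; motif lengths
#' are never inferred.
#'
#' @param path Path to a TSV with at least columns `chrom`, `chromStart`,
#'   `chromEnd`, `period`.
#' @return A data frame of intervals with `source = "tandem"`.
#' @export
load_tandem_repeat_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("chrom", "chromStart", "chromEnd", "period")
  missing_col <- setdiff(req, names(tab))
  if (length(missing_col))
    stop("tandem-repeat table is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  for (col in c("chromStart", "chromEnd", "period")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) | is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data line %d", col, bad[1]))
    tab[[col]] <- v
  }
  bad <- which(tab$chromEnd <= tab$chromStart)
  if (length(bad))
    stop(sprintf("chromEnd <= chromStart at data line %d", bad[1]))
  keep <- tab$period %in% c(2, 3, 4)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) return(empty_intervals())
  genomic_intervals(tab$chrom, tab$chromStart, tab$chromEnd,
                    source = "tandem")
}

#' Build a merged, queryable simple-repeat track
#'
#' Merges interval sets (typically homopolymer runs plus tandem-repeat
#' intervals) into one sorted, non-overlapping track supporting fast overlap
#' queries. Source tags of intervals contributing to a merged interval are
#' collapsed with `","`.
#'
#' @param ... Interval data frames (as from [scan_homopolymers()] or
#'   [load_tandem_repeat_table()]).
#' @return An object of class `repeat_track` with elements `intervals`
#'   (merged data frame with `source` tags) and `n_sources`.
#' @export
repeat_track <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0, TRUE)]
  if (length(parts) == 0) {
    iv <- empty_intervals()
    iv$source <- character()
    return(structure(list(intervals = iv, granges = as_granges0(iv)),
                     class = "repeat_track"))
  }
  parts <- lapply(parts, function(p) {
    if (is.null(p$source)) p$source <- "unknown"
    p[, c("chrom", "start", "end", "source")]
  })
  all_iv <- do.call(rbind, parts)
  merged <- merge_intervals(all_iv)
  mgr <- as_granges0(merged)
  hits <- GenomicRanges::findOverlaps(as_granges0(all_iv), mgr)
  src <- rep(NA_character_, nrow(merged))
  qs <- all_iv$source[S4Vectors::queryHits(hits)]
  sh <- S4Vectors::subjectHits(hits)
  nhits <- tabulate(sh, nrow(merged))
  one <- which(nhits[sh] == 1)
  src[sh[one]] <- qs[one]
  multi <- which(nhits > 1)
  if (length(multi)) {
    sp <- split(qs[sh %in% multi], sh[sh %in% multi])
    src[as.integer(names(sp))] <-
      vapply(sp, function(s) paste(sort(unique(s)), collapse = ","), "")
  }
  merged$source <- src
  structure(list(intervals = merged, granges = mgr), class = "repeat_track")
}

#' Union of two repeat tracks
#'
#' A base is covered by the result iff it is covered by either input
#' (coverage-level union); the result is sorted and non-overlapping.
#'
#' @param a,b `repeat_track` objects or interval data frames.
#' @return A `repeat_track`.
#' @export
merge_tracks <- function(a, b) {
  ivs <- lapply(list(a, b), function(x)
    if (inherits(x, "repeat_track")) x$intervals else x)
  do.call(repeat_track, ivs)
}

#' Test whether intervals overlap a repeat track
#'
#' Half-open semantics: `[a, b)` and `[c, d)` overlap iff `a < d` and
#' `c < b`; an abutting interval does not overlap.
#'
#' @param track A `repeat_track`.
#' @param query An interval data frame (one or more rows).
#' @param pad Non-negative padding (bp) added to each side of every track
#'   interval before testing; default 0 (no flanks).
#' @return Logical vector, one element per query row.
#' @export
track_overlaps <- function(track, query, pad = 0L) {
  stopifnot(inherits(track, "repeat_track"))
  if (nrow(query) == 0) return(logical(0))
  gr <- track$granges
  if (pad > 0) {
    gr <- GenomicRanges::reduce(gr + as.integer(pad))
  }
  qgr <- as_granges0(genomic_intervals(query$chrom, query$start, query$end))
  # querying a chromosome absent from the track is a legitimate non-overlap,
  # not a seqlevel mismatch worth warning about
  suppressWarnings(IRanges::overlapsAny(qgr, gr))
}

#' @export
print.repeat_track <- function(x, ...) {
  iv <- x$intervals
  cat("Simple-repeat track:", nrow(iv), "merged intervals on",
      length(unique(iv$chrom)), "sequence(s);",
      sum(iv$end - iv$start), "bp covered\n")
  if (nrow(iv)) {
    tab <- table(iv$source)
    cat("  sources:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a repeat track as BED
#'
#' Four columns: chrom, start, end (0-based half-open) and the source tag.
#' @param track A `repeat_track`.
#' @param path Output path.
#' @export
write_repeat_track <- function(track, path) {
  iv <- track$intervals
  utils::write.table(iv[, c("chrom", "start", "end", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a repeat track written by [write_repeat_track()]
#' @param path BED path (3 or 4 columns).
#' @return A `repeat_track`.
#' @export
read_repeat_track <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  src <- if (ncol(tab) >= 4) tab[[4]] else "unknown"
  repeat_track(genomic_intervals(tab[[1]], tab[[2]], tab[[3]], source = src))
}
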