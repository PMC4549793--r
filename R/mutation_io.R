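#' Read a somatic mutation catalog from a MAF file
#'
#' Parses the TCGA Mutation Annotation Format dialect: tab-separated,
#' 1-based inclusive coordinates, leading `#` lines skipped. Each record is
#' typed as a single-nucleotide substitution (`Variant_Type` `SNP` -> `SNS`)
#' or a microindel (`INS`, `DEL`). Multi-nucleotide substitution types
#' (`DNP`, `TNP`, `ONP`, ...) are excluded from the catalog and tallied, not
#' silently dropped: the mutation-rate variables are defined over SNSs and
#' microindels only.
#'
#' @param path Path to a MAF file. The header must contain `Chromosome`,
#'   `Start_Position` (or `Start_position`), `End_Position` (or
#'   `End_position`), `Variant_Type` and `Tumor_Sample_Barcode`.
#' @return A `mutation_catalog`: list with `mutations` (data frame with
#'   columns `sample_id`, `chrom`, `start`, `end`, `variant_class`),
#'   `samples` (unique sample ids) and `skipped` (named integer tally of
#'   excluded `Variant_Type`s).
#' @export
read_maf <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  if (nrow(tab) == 0) stop("MAF file contains no mutation records: ", path)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(nm)
    stop("MAF is missing required column: ", ..1)
  }
  col_chrom <- pick("Chromosome")
  col_start <- pick("Start_Position", "Start_position")
  col_end <- pick("End_Position", "End_position")
  col_type <- pick("Variant_Type")
  col_samp <- pick("Tumor_Sample_Barcode")
  type <- toupper(tab[[col_type]])
  class_map <- c(SNP = "SNS", INS = "INS", DEL = "DEL")
  variant_class <- unname(class_map[type])
  keep <- !is.na(variant_class)
  skipped <- table(type[!keep])
  skipped <- stats::setNames(as.integer(skipped), names(skipped))
  mut <- data.frame(
    sample_id = as.character(tab[[col_samp]][keep]),
    chrom = norm_chrom(as.character(tab[[col_chrom]][keep])),
    start = as.integer(tab[[col_start]][keep]),
    end = as.integer(tab[[col_end]][keep]),
    variant_class = variant_class[keep],
    stringsAsFactors = FALSE)
  if (any(is.na(mut$start) | is.na(mut$end)))
    stop("non-numeric mutation coordinates in ", path)
  bad <- with(mut, variant_class != "INS" & end < start)
  if (any(bad))
    stop("MAF record with end < start at data row ", which(bad)[1])
  new_mutation_catalog(mut, skipped = skipped)
}

new_mutation_catalog <- function(mutations, skipped = integer()) {
  structure(list(mutations = mutations,
                 samples = unique(mutations$sample_id),
                 skipped = skipped),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  m <- x$mutations
  cat("Somatic mutation catalog:", nrow(m), "mutations in",
      length(x$samples), "sample(s)\n")
  if (nrow(m)) print(table(m$variant_class))
  if (length(x$skipped))
    cat("  skipped records:",
        paste(sprintf("%s=%d", names(x$skipped), x$skipped), collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a mutation catalog as a minimal MAF file
#'
#' Inverse of [read_maf()] up to the columns the catalog retains; used for
#' fixtures and round-trip checks. `SNS` is written back as `SNP`.
#'
#' @param catalog A `mutation_catalog`.
#' @param path Output path.
#' @export
write_maf <- function(catalog, path) {
  m <- catalog$mutations
  type_map <- c(SNS = "SNP", INS = "INS", DEL = "DEL")
  out <- data.frame(
    Hugo_Symbol = ".",
    Chromosome = m$chrom,
    Start_Position = m$start,
    End_Position = m$end,
    Variant_Type = unname(type_map[m$variant_class]),
    Tumor_Sample_Barcode = m$sample_id,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a capture design from a BED file
#'
#' Regions are 0-based half-open. Overlapping or abutting regions are merged
#' before the total targeted length is computed; the targeted length in Mb
#' is the denominator for all per-Mb mutation-rate variables.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A `capture_design`: list with `regions` (merged, sorted data
#'   frame), `raw` (regions in file order, for region-group statistics),
#'   `total_length_bp` and `total_length_mb`.
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3) stop("BED file must have at least 3 columns: ", path)
  start <- suppressWarnings(as.integer(tab[[2]]))
  end <- suppressWarnings(as.integer(tab[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop(sprintf("invalid BED region (end <= start or non-numeric) at line %d",
                 bad[1]))
  capture_design(genomic_intervals(tab[[1]], start, end))
}

#' Construct a capture design from intervals
#' @param regions Interval data frame (0-based half-open).
#' @return A `capture_design`.
#' @export
capture_design <- function(regions) {
  raw <- regions[, c("chrom", "start", "end")]
  merged <- merge_intervals(raw)
  total <- sum(as.numeric(merged$end - merged$start))
  structure(list(regions = merged, raw = raw,
                 granges = as_granges0(merged),
                 total_length_bp = total,
                 total_length_mb = total / 1e6),
            class = "capture_design")
}

#' @export
print.capture_design <- function(x, ...) {
  cat("Capture design:", nrow(x$regions), "merged regions,",
      sprintf("%.3f Mb targeted\n", x$total_length_mb))
  invisible(x)
}

#' Half-open genomic span of a mutation
#'
#' Normalizes 1-based inclusive MAF coordinates to the internal 0-based
#' half-open convention used for overlap tests. SNSs and deletions map to
#' `[start - 1, end)`; an insertion (MAF records its two flanking bases,
#' `end = start + 1`) maps to the span covering both flanks, which is the
#' same formula.
#'
#' @param mutations Mutation data frame (or a `mutation_catalog`).
#' @return An interval data frame with one row per mutation.
#' @export
mutation_span <- function(mutations) {
  if (inherits(mutations, "mutation_catalog")) mutations <- mutations$mutations
  if (nrow(mutations) == 0) return(empty_intervals())
  genomic_intervals(mutations$chrom, mutations$start - 1L, mutations$end)
}

#' Read per-sample metadata
#'
#' A tab-separated sidecar table with columns `sample_id`, `cancer_type`
#' and optionally `lab_msi_status` (values `MSI-H`, `MSI-L`, `MSS`).
#' Explicit metadata is used rather than inferring cancer type from sample
#' barcodes.
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_sample_info <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("sample metadata is missing required column: sample_id")
  if ("lab_msi_status" %in% names(tab)) {
    ok <- tab$lab_msi_status %in% c("MSI-H", "MSI-L", "MSS") | is.na(tab$lab_msi_status)
    if (!all(ok))
      stop("lab_msi_status must be one of MSI-H, MSI-L, MSS (row ",
           which(!ok)[1], ")")
  }
  tab
}
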