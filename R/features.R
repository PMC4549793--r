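#' Compute per-tumor mutation-rate input variables
#'
#' For every sample the ten classifier input variables are computed from the
#' somatic mutation catalog, the simple-repeat track and the capture design:
#'
#' * `T.sns`, `S.sns` — SNSs per Mb in all targeted sequence / in simple repeats
#' * `T.ind`, `S.ind` — microindels per Mb in all targeted sequence / in simple repeats
#' * `T`, `S` — all mutations per Mb / in simple repeats
#' * `ratio.sns` = `S.sns/T.sns`, `ratio.ind` = `S.ind/T.ind`, `ratio` = `S/T`
#' * `cancer_type` — categorical label from the sample metadata
#'
#' The denominator for every rate is the total targeted length in Mb.
#' A mutation counts toward the `S` variables iff its half-open span overlaps
#' the repeat track (any-overlap rule; a length change touching a repeat
#' changes the repeat's length). Mutations whose span lies entirely outside
#' the capture design are excluded from all counts and tallied in a warning:
#' the denominator is the targeted length, so off-target calls would inflate
#' the rates. A ratio with zero denominator is `NA`, never 0 or infinity.
#'
#' @param catalog A `mutation_catalog`.
#' @param repeats A `repeat_track`.
#' @param capture A `capture_design` with positive targeted length.
#' @param sample_info Optional metadata data frame (`sample_id`,
#'   `cancer_type`, ...). Samples present in the metadata but absent from
#'   the catalog receive all-zero rates (and `NA` ratios).
#' @param pad Padding (bp) added around repeat intervals for the overlap
#'   test; default 0.
#' @param ins_rule `"any"` (default) counts an insertion as in-repeat when
#'   either flanking base touches a repeat; `"within"` requires both flanks
#'   inside.
#' @param warn_off_target Emit the off-target exclusion warning (default
#'   `TRUE`).
#' @return A data frame with one row per sample and columns `sample_id`,
#'   `T.sns`, `S.sns`, `T.ind`, `S.ind`, `T`, `S`, `ratio.sns`,
#'   `ratio.ind`, `ratio`, `cancer_type`. The number of excluded off-target
#'   mutations is attached as attribute `n_off_target`.
#' @export
compute_features <- function(catalog, repeats, capture, sample_info = NULL,
                             pad = 0L, ins_rule = c("any", "within"),
                             warn_off_target = TRUE) {
  ins_rule <- match.arg(ins_rule)
  stopifnot(inherits(catalog, "mutation_catalog"),
            inherits(repeats, "repeat_track"),
            inherits(capture, "capture_design"))
  if (capture$total_length_mb <= 0) stop("capture design is empty")
  mb <- capture$total_length_mb

  m <- catalog$mutations
  samples <- union(catalog$samples,
                   if (!is.null(sample_info)) sample_info$sample_id else character())
  n_off <- 0L
  if (nrow(m)) {
    span <- mutation_span(m)
    sgr <- as_granges0(span)
    in_cap <- suppressWarnings(IRanges::overlapsAny(sgr, capture$granges))
    n_off <- sum(!in_cap)
    if (n_off > 0 && warn_off_target)
      warning(n_off, " mutation(s) outside the capture design excluded from all counts")
    m <- m[in_cap, , drop = FALSE]
    span <- span[in_cap, , drop = FALSE]
    in_rep <- track_overlaps(repeats, span, pad = pad)
    if (ins_rule == "within" && any(m$variant_class == "INS")) {
      ins <- which(m$variant_class == "INS")
      rgr <- repeats$granges
      if (pad > 0) rgr <- GenomicRanges::reduce(rgr + as.integer(pad))
      within <- suppressWarnings(
        IRanges::overlapsAny(as_granges0(span[ins, , drop = FALSE]),
                             rgr, type = "within"))
      in_rep[ins] <- within
    }
  } else {
    in_rep <- logical(0)
  }

  count_by <- function(sel) {
    v <- integer(length(samples))
    names(v) <- samples
    if (any(sel)) {
      t <- table(factor(m$sample_id[sel], levels = samples))
      v[] <- as.integer(t)
    }
    v
  }
  is_sns <- m$variant_class == "SNS"
  is_ind <- !is_sns
  n_sns <- count_by(is_sns)
  n_sns_rep <- count_by(is_sns & in_rep)
  n_ind <- count_by(is_ind)
  n_ind_rep <- count_by(is_ind & in_rep)

  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  feats <- data.frame(
    sample_id = samples,
    T.sns = n_sns / mb,
    S.sns = n_sns_rep / mb,
    T.ind = n_ind / mb,
    S.ind = n_ind_rep / mb,
    T = (n_sns + n_ind) / mb,
    S = (n_sns_rep + n_ind_rep) / mb,
    ratio.sns = safe_ratio(n_sns_rep, n_sns),
    ratio.ind = safe_ratio(n_ind_rep, n_ind),
    ratio = safe_ratio(n_sns_rep + n_ind_rep, n_sns + n_ind),
    cancer_type = NA_character_,
    stringsAsFactors = FALSE, check.names = FALSE, row.names = NULL)

  if (!is.null(sample_info) && "cancer_type" %in% names(sample_info)) {
    idx <- match(feats$sample_id, sample_info$sample_id)
    feats$cancer_type <- sample_info$cancer_type[idx]
  }
  feats <- feats[order(feats$sample_id), , drop = FALSE]
  rownames(feats) <- NULL
  attr(feats, "n_off_target") <- n_off
  feats
}

#' Write a feature table as TSV
#' @param features Feature data frame from [compute_features()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path TSV path.
#' @return Feature data frame.
#' @export
read_features <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
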