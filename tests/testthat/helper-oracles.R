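# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval machinery (no GRanges): plain loops, regexes
# and bitmaps.

# maximal homopolymer runs via one regex per base
regex_homopolymers <- function(sequence, chrom, min_len = 5) {
  s <- toupper(sequence)
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    m <- gregexpr(sprintf("%s{%d,}", b, min_len), s)[[1]]
    if (m[1] != -1) {
      len <- attr(m, "match.length")
      out[[b]] <- data.frame(chrom = chrom, start = as.integer(m) - 1L,
                             end = as.integer(m) - 1L + len,
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# linear-scan any-overlap test, half-open semantics
scan_overlap <- function(iv, chrom, s, e) {
  any(iv$chrom == chrom & iv$start < e & s < iv$end)
}

# per-base coverage bitmap of intervals on one chromosome
coverage_bitmap <- function(iv, chrom, len) {
  bits <- logical(len)
  sel <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sel)))
    bits[(sel$start[i] + 1):sel$end[i]] <- TRUE
  bits
}

random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1000,
                             max_len = 30) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exact one-sided Fisher p by summing hypergeometric terms written with
# binomial coefficients (independent of phyper)
enum_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  sum(probs[xs >= a])
}

# AUC by explicit pair counting, ties = 1/2
pair_count_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

# brute-force recomputation of all ten input variables: per-mutation loops
# over every repeat interval and capture region
oracle_features <- function(catalog, repeat_iv, capture_iv, mb,
                            sample_ids = NULL) {
  m <- catalog$mutations
  samples <- sort(union(unique(m$sample_id),
                        if (is.null(sample_ids)) character() else sample_ids))
  res <- list()
  for (sid in samples) {
    ms <- m[m$sample_id == sid, , drop = FALSE]
    n_sns <- n_sns_rep <- n_ind <- n_ind_rep <- 0
    for (j in seq_len(nrow(ms))) {
      s0 <- ms$start[j] - 1L      # 1-based inclusive -> 0-based half-open
      e0 <- ms$end[j]
      if (!scan_overlap(capture_iv, ms$chrom[j], s0, e0)) next
      inrep <- scan_overlap(repeat_iv, ms$chrom[j], s0, e0)
      if (ms$variant_class[j] == "SNS") {
        n_sns <- n_sns + 1
        n_sns_rep <- n_sns_rep + inrep
      } else {
        n_ind <- n_ind + 1
        n_ind_rep <- n_ind_rep + inrep
      }
    }
    rat <- function(x, y) if (y > 0) x / y else NA_real_
    res[[sid]] <- data.frame(
      sample_id = sid, T.sns = n_sns / mb, S.sns = n_sns_rep / mb,
      T.ind = n_ind / mb, S.ind = n_ind_rep / mb,
      T = (n_sns + n_ind) / mb, S = (n_sns_rep + n_ind_rep) / mb,
      ratio.sns = rat(n_sns_rep, n_sns), ratio.ind = rat(n_ind_rep, n_ind),
      ratio = rat(n_sns_rep + n_ind_rep, n_sns + n_ind),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

random_sequence <- function(n, with_masking = TRUE) {
  alpha <- c("A", "C", "G", "T")
  if (with_masking) alpha <- c(alpha, "a", "c", "g", "t", "N")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}
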