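#' One-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for enrichment of the top-left
#' cell: with all margins fixed, the probability of a table at least as
#' extreme in the direction of larger `a`. The sum is exact (no normal
#' approximation). Degenerate margins give p = 1.
#'
#' @param a,b,c,d Cell counts: rows are condition present/absent, columns
#'   outcome present/absent. Alternatively `a` may be a 2x2 matrix.
#' @return The one-sided p-value.
#' @examples
#' fisher_exact_one_sided(5, 20, 1, 500)
#' @export
fisher_exact_one_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("table total must be > 0")
  # P(X >= a) with X ~ Hypergeom(white = a+c, black = b+d, drawn = a+b)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' ROC curve and AUC for MSI scoring
#'
#' Ranks samples by a score (conventionally `S.ind`) against binary labels.
#' The AUC is the probability that a random positive outscores a random
#' negative, with ties counted 1/2 (pair-count definition, computed via the
#' rank-sum identity). Curve points are (FPR, TPR) at every distinct
#' threshold, predicting positive for score >= threshold.
#'
#' @param scores Numeric scores, higher meaning more MSI-like.
#' @param labels Laboratory statuses; `MSI-H` is the positive class and
#'   `MSI-L`/`MSS` are grouped as negative. Logical vectors also accepted.
#' @return An `msi_roc` list: `auc`, `curve` (data frame with `threshold`,
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    pos <- group_non_msih(labels) == "MSI-H"
  }
  if (anyNA(scores) || anyNA(pos)) stop("scores and labels must not be NA")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "msi_roc")
}

#' @export
print.msi_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.msi_roc <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Concordance between predicted and laboratory MSI status
#'
#' Percentage of samples on which the classifier call agrees with the
#' laboratory status; laboratory `MSI-L` and `MSS` are both grouped as
#' `Non-MSI-H` before comparison. Inputs may be named by sample id, in
#' which case they are aligned and set differences are an error.
#'
#' @param predicted Character vector of calls (`MSI-H`/`Non-MSI-H`).
#' @param laboratory Character vector of laboratory statuses.
#' @return The percentage agreement (0-100).
#' @export
concordance <- function(predicted, laboratory) {
  if (!is.null(names(predicted)) && !is.null(names(laboratory))) {
    extra_p <- setdiff(names(predicted), names(laboratory))
    extra_l <- setdiff(names(laboratory), names(predicted))
    if (length(extra_p) || length(extra_l))
      stop("sample sets differ; only in predicted: ",
           paste(extra_p, collapse = ", "), "; only in laboratory: ",
           paste(extra_l, collapse = ", "))
    laboratory <- laboratory[names(predicted)]
  }
  if (length(predicted) != length(laboratory))
    stop("predicted and laboratory must have equal length")
  p <- group_non_msih(predicted)
  l <- group_non_msih(laboratory)
  100 * mean(p == l)
}

#' Classifier robustness on random capture subsets
#'
#' Emulates targeted panels smaller than an exome: for each requested total
#' length, whole target regions are sampled without replacement (the
#' sampling unit is the region, never a partial region) until the
#' accumulated length first reaches the request; the final region may
#' overshoot and the achieved length is used as the per-Mb denominator.
#' Features are recomputed on each subset, samples are reclassified, and
#' accuracy is the concordance of subset-based calls with the laboratory
#' labels. Results are fully determined by the seed.
#'
#' @param catalog A `mutation_catalog`.
#' @param capture A `capture_design` (its merged regions are the sampling
#'   units).
#' @param repeats A `repeat_track`.
#' @param classifier An `msi_classifier`.
#' @param sample_info Metadata with `sample_id` and `lab_msi_status`.
#' @param lengths_mb Numeric vector of requested subset lengths (Mb).
#' @param n_reps Replicates per length (default 50).
#' @param seed Integer seed.
#' @return A `subset_experiment` data frame: one row per length with
#'   `target_mb`, `mean_accuracy`, `sd_accuracy`, `n_reps`,
#'   `mean_achieved_mb`; per-replicate accuracies in attribute
#'   `replicates`.
#' @export
subset_experiment <- function(catalog, capture, repeats, classifier,
                              sample_info, lengths_mb, n_reps = 50L,
                              seed = 1L) {
  stopifnot(inherits(capture, "capture_design"), n_reps >= 1)
  if (any(lengths_mb > capture$total_length_mb + 1e-9))
    stop("requested subset length exceeds the capture total (",
         sprintf("%.3f Mb)", capture$total_length_mb))
  lab <- stats::setNames(sample_info$lab_msi_status, sample_info$sample_id)
  regions <- capture$regions
  widths <- as.numeric(regions$end - regions$start)
  res <- vector("list", length(lengths_mb))
  reps_detail <- vector("list", length(lengths_mb))
  with_seed(seed, {
    for (li in seq_along(lengths_mb)) {
      target_bp <- lengths_mb[li] * 1e6
      acc <- numeric(n_reps)
      achieved <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        o <- sample.int(nrow(regions))
        cum <- cumsum(widths[o])
        take <- o[seq_len(which(cum >= target_bp - 1e-9)[1])]
        sub <- capture_design(regions[take, , drop = FALSE])
        feats <- compute_features(catalog, repeats, sub,
                                  sample_info = sample_info,
                                  warn_off_target = FALSE)
        calls <- classify_msi(feats, classifier)
        acc[r] <- concordance(
          stats::setNames(calls$predicted_status, calls$sample_id),
          lab)
        achieved[r] <- sub$total_length_mb
      }
      res[[li]] <- data.frame(
        target_mb = lengths_mb[li],
        mean_accuracy = mean(acc),
        sd_accuracy = if (n_reps > 1) stats::sd(acc) else 0,
        n_reps = n_reps,
        mean_achieved_mb = mean(achieved))
      reps_detail[[li]] <- acc
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps_detail
  class(out) <- c("subset_experiment", "data.frame")
  out
}

#' @export
plot.subset_experiment <- function(x, ...) {
  graphics::plot(x$target_mb, x$mean_accuracy, type = "b", log = "x",
                 ylim = c(min(x$mean_accuracy - x$sd_accuracy, 90), 100),
                 xlab = "Subset length (Mb)", ylab = "Mean accuracy (%)", ...)
  graphics::arrows(x$target_mb, x$mean_accuracy - x$sd_accuracy,
                   x$target_mb, x$mean_accuracy + x$sd_accuracy,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Simple-repeat density over consecutive groups of target regions
#'
#' Regions (in file order) are partitioned into consecutive groups of
#' `group_size`; for each group the density is the number of repeat
#' intervals overlapping the group's regions divided by the group's total
#' region length in Kb.
#'
#' @param repeats A `repeat_track`.
#' @param regions A `capture_design` (its file-order regions are used) or
#'   an interval data frame.
#' @param group_size Regions per group (default 1000). A group size larger
#'   than the region count yields a single group.
#' @return A list with `densities` (per-group, /Kb), `mean` and `sd`.
#' @export
repeat_density <- function(repeats, regions, group_size = 1000L) {
  stopifnot(group_size >= 1)
  if (inherits(regions, "capture_design")) regions <- regions$raw
  n <- nrow(regions)
  if (n == 0) stop("no regions supplied")
  grp <- ceiling(seq_len(n) / group_size)
  dens <- vapply(split(seq_len(n), grp), function(idx) {
    g <- merge_intervals(regions[idx, , drop = FALSE])
    kb <- sum(as.numeric(g$end - g$start)) / 1000
    hits <- IRanges::overlapsAny(repeats$granges, as_granges0(g))
    sum(hits) / kb
  }, 0)
  list(densities = unname(dens), mean = mean(dens),
       sd = if (length(dens) > 1) stats::sd(dens) else 0)
}
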