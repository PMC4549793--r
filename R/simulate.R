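#' Parameters of a synthetic tumor cohort
#'
#' The generator emulates the three sample classes the classifier assumes:
#' non-MSI-H (low substitution burden, almost no repeat microindels), MSI-H
#' (elevated `T.sns`, high `S.ind`) and POLE-like ultra-hypermutated (very
#' high `T.sns`, low `S.ind`). Per-sample mutation counts are drawn from a
#' negative binomial around the class means (tumor burdens are
#' overdispersed), in-repeat microindels are placed uniformly on simple
#' repeats inside the capture, and everything else uniformly off-repeat
#' within the capture.
#'
#' @param n_msih,n_non,n_pole Sample counts per class.
#' @param capture_mb Total targeted length (Mb); the capture is tiled with
#'   exon-like regions of `region_bp` separated by equally sized gaps.
#' @param repeat_density_per_kb Planted simple-repeat density within target
#'   regions (intervals/Kb).
#' @param rates Named list of per-class mean rates per Mb:
#'   `list(non = c(t_sns=, s_ind=), msih = ..., pole = ...)`.
#' @param t_ind_off Mean off-repeat microindel rate per Mb (all classes).
#' @param dispersion Negative-binomial `size` (within-class dispersion).
#' @param boundary Optional planted decision boundary on `S.ind`: when set,
#'   in-repeat indel counts are drawn uniformly on the integer count ranges
#'   strictly below (non-MSI-H, POLE) / strictly above (MSI-H)
#'   `boundary * capture_mb`, and substitution rates are equalized across
#'   classes so `S.ind` is the only planted signal.
#' @param region_bp Length of each target region (bp).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_msih = 20L, n_non = 60L, n_pole = 5L,
                        capture_mb = 30, repeat_density_per_kb = 5.6,
                        rates = list(non = c(t_sns = 3, s_ind = 0.05),
                                     msih = c(t_sns = 30, s_ind = 1.5),
                                     pole = c(t_sns = 80, s_ind = 0.05)),
                        t_ind_off = 0.3, dispersion = 50, boundary = NULL,
                        region_bp = 2000L, seed = 1L) {
  counts <- c(n_msih, n_non, n_pole)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (sum(counts) == 0) stop("cohort must contain at least one sample")
  for (cl in c("non", "msih", "pole"))
    if (!all(c("t_sns", "s_ind") %in% names(rates[[cl]])))
      stop("rates$", cl, " must name t_sns and s_ind")
  if (capture_mb <= 0 || repeat_density_per_kb < 0 || dispersion <= 0)
    stop("invalid cohort parameters")
  structure(list(n_msih = as.integer(n_msih), n_non = as.integer(n_non),
                 n_pole = as.integer(n_pole), capture_mb = capture_mb,
                 repeat_density_per_kb = repeat_density_per_kb,
                 rates = rates, t_ind_off = t_ind_off,
                 dispersion = dispersion, boundary = boundary,
                 region_bp = as.integer(region_bp), seed = as.integer(seed)),
            class = "cohort_spec")
}

CANCER_TYPES <- c("colon", "rectal", "endometrial", "gastric")

# plant non-overlapping repeat intervals into [region_start, region_start +
# region_bp) slots; returns intervals with type and period columns
plant_repeats <- function(region_start, region_bp, n_per_region, chrom) {
  n_rep <- sum(n_per_region)
  if (n_rep == 0) {
    out <- empty_intervals()
    out$source <- character()
    out$type <- character()
    out$period <- integer()
    return(out)
  }
  keep <- n_per_region > 0
  slot_w <- rep(region_bp %/% pmax(n_per_region[keep], 1L), n_per_region[keep])
  slot_id <- sequence(n_per_region[keep])
  reg_start <- rep(region_start[keep], n_per_region[keep])
  type <- sample(c("homopolymer", "tandem"), n_rep, replace = TRUE)
  period <- integer(n_rep)
  width <- integer(n_rep)
  is_h <- type == "homopolymer"
  width[is_h] <- sample(5:12, sum(is_h), replace = TRUE)
  period[is_h] <- 1L
  period[!is_h] <- sample(2:4, sum(!is_h), replace = TRUE)
  width[!is_h] <- period[!is_h] * sample(3:8, sum(!is_h), replace = TRUE)
  if (any(slot_w < width + 3))
    stop("repeat density infeasible for the region length")
  offset <- 1L + floor(stats::runif(n_rep) * (slot_w - width - 2L))
  start <- reg_start + (slot_id - 1L) * slot_w + offset
  out <- genomic_intervals(rep(chrom, n_rep), start, start + width,
                           source = type)
  out$type <- type
  out$period <- period
  out
}

#' Generate a reference sequence with planted simple repeats
#'
#' Produces a random nucleotide sequence with homopolymer runs (length
#' 5-12, flanked by a different base so each run is maximal) and di-/tri-/
#' tetranucleotide tandem arrays (3-8 copies, units never a single repeated
#' base) planted at the requested density, together with the ground-truth
#' intervals. Chance homopolymer runs in the random background are possible
#' and legitimate scanner output; the truth set records the planted
#' intervals only.
#'
#' @param length_bp Sequence length (>= 10 kb).
#' @param repeat_density_per_kb Planted repeats per Kb.
#' @param seed Integer seed; the output is byte-reproducible.
#' @param chrom Sequence name.
#' @return A list: `sequence` ([Biostrings::DNAStringSet]), `homopolymers`
#'   and `tandems` (truth interval data frames, tandems carrying `period`),
#'   `track` (merged truth `repeat_track`).
#' @export
generate_reference <- function(length_bp, repeat_density_per_kb, seed = 1L,
                               chrom = "1") {
  length_bp <- as.integer(length_bp)
  if (length_bp < 10000) stop("reference length must be >= 10 kb")
  with_seed(seed, {
    n_rep <- round(repeat_density_per_kb * length_bp / 1000)
    v <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
    if (n_rep > 0) {
      iv <- plant_repeats(0L, length_bp, n_rep, chrom)
      for (i in seq_len(nrow(iv))) {
        s <- iv$start[i]            # 0-based; 1-based positions s+1 .. end
        e <- iv$end[i]
        if (iv$type[i] == "homopolymer") {
          b <- sample(c("A", "C", "G", "T"), 1)
          v[(s + 1):e] <- b
          other <- setdiff(c("A", "C", "G", "T"), b)
          if (s >= 1) v[s] <- sample(other, 1)
          if (e < length_bp) v[e + 1] <- sample(other, 1)
        } else {
          p <- iv$period[i]
          repeat {
            unit <- sample(c("A", "C", "G", "T"), p, replace = TRUE)
            if (length(unique(unit)) > 1) break
          }
          v[(s + 1):e] <- rep_len(unit, e - s)
        }
      }
    } else {
      iv <- plant_repeats(0L, length_bp, 0L, chrom)
    }
    seqs <- Biostrings::DNAStringSet(paste(v, collapse = ""))
    names(seqs) <- chrom
    hp <- iv[iv$type == "homopolymer", c("chrom", "start", "end", "source")]
    td <- iv[iv$type == "tandem",
             c("chrom", "start", "end", "source", "period")]
    rownames(hp) <- rownames(td) <- NULL
    list(sequence = seqs, homopolymers = hp, tandems = td,
         track = repeat_track(hp, td[, c("chrom", "start", "end", "source")]))
  })
}

# uniform positions over a set of disjoint intervals (width-weighted)
sample_positions <- function(iv, n) {
  if (n == 0) return(integer(0))
  w <- iv$end - iv$start
  i <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  iv$start[i] + floor(stats::runif(n) * w[i])
}

#' Generate a synthetic tumor cohort
#'
#' Draws per-sample mutation counts from the class model in the
#' [cohort_spec()], places them on a synthetic capture design with planted
#' simple repeats, and returns a fully cross-consistent set of objects:
#' every mutation lies inside the capture, in-repeat microindels overlap the
#' repeat track, and off-repeat mutations do not. Ground-truth per-sample
#' counts and class labels are returned so downstream computations can be
#' checked exactly. Laboratory labels in the metadata use `MSI-H` for the
#' MSI-H class and randomly `MSS` or `MSI-L` for the rest, exercising the
#' label-grouping path.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given, MAF/BED/TSV fixtures are
#'   written via [write_cohort()].
#' @return An `msi_cohort` list: `catalog`, `capture`, `repeats`,
#'   `tandems`, `sample_info`, `truth`, `spec` (and `paths` when `dir` is
#'   given).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  res <- with_seed(spec$seed, {
    M <- spec$capture_mb
    region_bp <- spec$region_bp
    n_regions <- ceiling(M * 1e6 / region_bp)
    region_start <- (seq_len(n_regions) - 1L) * 2L * region_bp
    chrom <- "1"
    capture <- capture_design(
      genomic_intervals(rep(chrom, n_regions), region_start,
                        region_start + region_bp))

    mu_rep <- spec$repeat_density_per_kb * region_bp / 1000
    n_per_region <- floor(mu_rep) +
      (stats::runif(n_regions) < (mu_rep - floor(mu_rep)))
    planted <- plant_repeats(region_start, region_bp,
                             as.integer(n_per_region), chrom)
    repeats <- repeat_track(
      planted[, c("chrom", "start", "end", "source")])

    classes <- rep(c("msih", "non", "pole"),
                   c(spec$n_msih, spec$n_non, spec$n_pole))
    n <- length(classes)
    sample_id <- sprintf("S%03d", seq_len(n))
    disp <- spec$dispersion

    if (is.null(spec$boundary)) {
      t_sns_mu <- vapply(classes, function(cl) spec$rates[[cl]]["t_sns"], 0) * M
      s_ind_mu <- vapply(classes, function(cl) spec$rates[[cl]]["s_ind"], 0) * M
      n_sns <- stats::rnbinom(n, mu = t_sns_mu, size = disp)
      n_sind <- stats::rnbinom(n, mu = s_ind_mu, size = disp)
    } else {
      bM <- spec$boundary * M
      lo_max <- as.integer(ceiling(bM) - 1)
      hi_min <- as.integer(floor(bM) + 1)
      hi_max <- as.integer(round(3 * bM))
      n_sns <- stats::rnbinom(n, mu = spec$rates$non["t_sns"] * M, size = disp)
      n_sind <- integer(n)
      is_hi <- classes == "msih"
      n_sind[!is_hi] <- sample(0:lo_max, sum(!is_hi), replace = TRUE)
      n_sind[is_hi] <- sample(hi_min:hi_max, sum(is_hi), replace = TRUE)
    }
    n_off <- stats::rnbinom(n, mu = spec$t_ind_off * M, size = disp)

    if (any(n_sind > 0) && nrow(repeats$intervals) == 0)
      stop("no repeats within the capture to place in-repeat microindels on")

    rep_iv <- repeats$intervals
    cap_iv <- capture$regions
    truth <- data.frame(sample_id = sample_id, class = classes,
                        n_sns = n_sns, n_sns_in_repeat = 0L,
                        n_ind = n_sind + n_off, n_ind_in_repeat = n_sind,
                        stringsAsFactors = FALSE)

    # substitutions, batched across samples: uniform over the capture
    sid_s <- rep(seq_len(n), n_sns)
    pos_s <- sample_positions(cap_iv, length(sid_s))
    if (length(sid_s)) {
      in_rep_s <- track_overlaps(
        repeats, genomic_intervals(rep(chrom, length(pos_s)), pos_s, pos_s + 1L))
      hits <- tapply(in_rep_s, factor(sid_s, levels = seq_len(n)), sum)
      truth$n_sns_in_repeat <- as.integer(ifelse(is.na(hits), 0L, hits))
    }
    sns <- data.frame(sample_id = sample_id[sid_s],
                      chrom = rep(chrom, length(sid_s)),
                      start = pos_s + 1L, end = pos_s + 1L,
                      variant_class = rep("SNS", length(sid_s)),
                      stringsAsFactors = FALSE)

    # in-repeat microindels: uniform over repeat intervals
    sid_r <- rep(seq_len(n), n_sind)
    pos_r <- sample_positions(rep_iv, length(sid_r))
    ins_r <- stats::runif(length(sid_r)) < 0.5
    len_r <- sample(1:3, max(length(sid_r), 1),
                    replace = TRUE)[seq_len(length(sid_r))]
    ind_in <- data.frame(sample_id = sample_id[sid_r],
                         chrom = rep(chrom, length(sid_r)),
                         start = pos_r + 1L,
                         end = ifelse(ins_r, pos_r + 2L, pos_r + len_r),
                         variant_class = ifelse(ins_r, "INS", "DEL"),
                         stringsAsFactors = FALSE)

    # off-repeat microindels: rejection-sample until every span misses the
    # repeat track
    sid_o <- rep(seq_len(n), n_off)
    off <- NULL
    tries <- 0
    while (length(sid_o) > 0 && tries < 50) {
      k <- length(sid_o)
      pos_o <- sample_positions(cap_iv, k)
      ins_o <- stats::runif(k) < 0.5
      len_o <- sample(1:3, max(k, 1), replace = TRUE)[seq_len(k)]
      span_end <- ifelse(ins_o, pos_o + 2L, pos_o + len_o)
      clean <- which(!track_overlaps(
        repeats, genomic_intervals(rep(chrom, k), pos_o, span_end)))
      off <- rbind(off, data.frame(
        sample_id = sample_id[sid_o[clean]],
        chrom = rep(chrom, length(clean)),
        start = pos_o[clean] + 1L,
        end = span_end[clean],
        variant_class = ifelse(ins_o[clean], "INS", "DEL"),
        stringsAsFactors = FALSE))
      if (length(clean)) sid_o <- sid_o[-clean]
      tries <- tries + 1
    }
    if (length(sid_o) > 0)
      stop("could not place off-repeat microindels; repeat density too high")

    mutations <- rbind(sns, ind_in, off)
    mutations <- mutations[order(mutations$sample_id, mutations$start,
                                 mutations$variant_class), , drop = FALSE]
    rownames(mutations) <- NULL
    catalog <- new_mutation_catalog(mutations)

    lab <- character(n)
    lab[classes == "msih"] <- "MSI-H"
    lab[classes == "non"] <- sample(c("MSS", "MSI-L"), sum(classes == "non"),
                                    replace = TRUE)
    lab[classes == "pole"] <- "MSS"
    sample_info <- data.frame(
      sample_id = sample_id,
      cancer_type = sample(CANCER_TYPES, n, replace = TRUE),
      lab_msi_status = lab, stringsAsFactors = FALSE)
    truth$lab_msi_status <- lab

    tandems <- planted[planted$type == "tandem",
                       c("chrom", "start", "end", "period")]
    rownames(tandems) <- NULL
    structure(list(catalog = catalog, capture = capture, repeats = repeats,
                   tandems = tandems, sample_info = sample_info,
                   truth = truth, spec = spec),
              class = "msi_cohort")
  })
  if (!is.null(dir)) res$paths <- write_cohort(res, dir)
  res
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat("Synthetic MSI cohort:", nrow(x$sample_info), "samples (",
      sum(x$truth$class == "msih"), "MSI-H,",
      sum(x$truth$class == "non"), "non-MSI-H,",
      sum(x$truth$class == "pole"), "POLE-like ),",
      sprintf("%.1f Mb capture\n", x$capture$total_length_mb))
  invisible(x)
}

#' Write cohort fixtures to disk
#'
#' Writes `cohort.maf` (TCGA-dialect MAF), `capture.bed` (0-based
#' half-open), `samples.tsv` (sample metadata), `truth.tsv` (ground truth),
#' `repeats.bed` (the merged repeat track) and `tandem_repeats.tsv`
#' (simpleRepeats-style table of the planted tandem arrays).
#'
#' @param cohort An `msi_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(maf = file.path(dir, "cohort.maf"),
             bed = file.path(dir, "capture.bed"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"),
             repeats = file.path(dir, "repeats.bed"),
             tandem = file.path(dir, "tandem_repeats.tsv"))
  write_maf(cohort$catalog, paths["maf"])
  utils::write.table(cohort$capture$regions[, c("chrom", "start", "end")],
                     paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$sample_info, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_repeat_track(cohort$repeats, paths["repeats"])
  td <- cohort$tandems
  names(td) <- c("chrom", "chromStart", "chromEnd", "period")
  utils::write.table(td, paths["tandem"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
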