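test_that("one-sided Fisher test matches the published POLE enrichment", {
  p <- fisher_exact_one_sided(5, 20, 1, 500)
  expect_equal(signif(p, 2), 9.4e-7)
  expect_equal(fisher_exact_one_sided(matrix(c(5, 1, 20, 500), 2)), p)
  # degenerate margins
  expect_equal(fisher_exact_one_sided(0, 10, 0, 10), 1.0)
  expect_equal(fisher_exact_one_sided(0, 0, 0, 5), 1.0)
  expect_error(fisher_exact_one_sided(1, -1, 0, 0), "non-negative")
  expect_error(fisher_exact_one_sided(0, 0, 0, 0), "total")
})

test_that("Fisher tail equals full enumeration on all tables with margins <= 12", {
  worst <- 0
  for (a in 0:12) for (b in 0:(12 - a)) for (c in 0:(12 - a)) {
    for (d in 0:(12 - max(b, c))) {
      if (a + b + c + d == 0) next
      got <- fisher_exact_one_sided(a, b, c, d)
      want <- enum_fisher_greater(a, b, c, d)
      worst <- max(worst, abs(got - want) / want)
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random larger tables", {
  set.seed(13)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 40), 2)
    expect_equal(fisher_exact_one_sided(tb),
                 stats::fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("AUC handles separation and complete ties", {
  r <- roc_auc(c(1, 2, 3, 10, 11), c("MSS", "MSI-L", "MSS", "MSI-H", "MSI-H"))
  expect_equal(r$auc, 1.0)
  expect_equal(max(r$curve$tpr), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("MSI-H", "MSS"), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("MSS", 3)), "both classes")
})

test_that("AUC equals brute-force pair counting on random instances", {
  set.seed(14)
  for (i in 1:10) {
    n <- 30
    scores <- round(runif(n), 1)           # rounding forces ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, pair_count_auc(scores, pos))
    # complement symmetry (ties make both computations shift equally)
    expect_equal(roc_auc(-scores, pos)$auc, 1 - r$auc)
  }
})

test_that("AUC matches the pROC reference implementation", {
  set.seed(15)
  scores <- runif(50)
  pos <- runif(50) < 0.5
  got <- roc_auc(scores, pos)$auc
  want <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                         quiet = TRUE, direction = "<")))
  expect_equal(got, want)
})

test_that("concordance groups MSI-L and MSS as non-MSI-H", {
  expect_equal(concordance(rep("MSI-H", 4), rep("MSI-H", 4)), 100)
  expect_equal(concordance(c(rep("MSI-H", 9), "Non-MSI-H"),
                           rep("MSI-H", 10)), 90)
  expect_equal(concordance(rep("Non-MSI-H", 4),
                           c("MSI-L", "MSS", "MSI-L", "MSS")), 100)
  p <- stats::setNames(c("MSI-H", "Non-MSI-H"), c("A", "B"))
  l <- stats::setNames(c("MSS", "MSI-H"), c("B", "A"))
  expect_equal(concordance(p, l), 100)     # aligned by name
  l2 <- stats::setNames(c("MSS", "MSI-H"), c("B", "C"))
  expect_error(concordance(p, l2), "C")
  expect_error(concordance(p, l2), "A")
})

small_cohort <- function(seed = 61, sep10 = FALSE) {
  if (sep10) {
    # MSI-H S.ind sits 10x above the decision threshold; the other classes
    # essentially never produce repeat microindels
    cohort_spec(n_msih = 10, n_non = 18, n_pole = 2, capture_mb = 20,
                rates = list(non = c(t_sns = 3, s_ind = 0.001),
                             msih = c(t_sns = 30, s_ind = 4.0),
                             pole = c(t_sns = 80, s_ind = 0.001)),
                seed = seed)
  } else {
    cohort_spec(n_msih = 10, n_non = 18, n_pole = 2, capture_mb = 3,
                seed = seed)
  }
}

test_that("the identity subset reproduces the full-data accuracy with zero spread", {
  co <- generate_cohort(small_cohort())
  f <- compute_features(co$catalog, co$repeats, co$capture, co$sample_info)
  calls <- classify_msi(f)
  full_acc <- concordance(
    stats::setNames(calls$predicted_status, calls$sample_id),
    stats::setNames(co$sample_info$lab_msi_status, co$sample_info$sample_id))
  res <- subset_experiment(co$catalog, co$capture, co$repeats,
                           default_exome_classifier(), co$sample_info,
                           lengths_mb = co$capture$total_length_mb,
                           n_reps = 3, seed = 5)
  expect_equal(res$mean_accuracy, full_acc)
  expect_equal(res$sd_accuracy, 0)
  expect_equal(res$mean_achieved_mb, co$capture$total_length_mb)
  # determinism
  res2 <- subset_experiment(co$catalog, co$capture, co$repeats,
                            default_exome_classifier(), co$sample_info,
                            lengths_mb = co$capture$total_length_mb,
                            n_reps = 3, seed = 5)
  expect_identical(res, res2)
  expect_error(
    subset_experiment(co$catalog, co$capture, co$repeats,
                      default_exome_classifier(), co$sample_info,
                      lengths_mb = 99, n_reps = 1, seed = 1),
    "exceeds")
})

test_that("wide class separation keeps subset accuracy at 100%", {
  co <- generate_cohort(small_cohort(seed = 62, sep10 = TRUE))
  res <- subset_experiment(co$catalog, co$capture, co$repeats,
                           default_exome_classifier(), co$sample_info,
                           lengths_mb = 0.2 * co$capture$total_length_mb,
                           n_reps = 50, seed = 8)
  expect_equal(res$mean_accuracy, 100)
  expect_equal(res$n_reps, 50)
  # achieved length may overshoot the request, never undershoot
  expect_gte(res$mean_achieved_mb, res$target_mb)
})

test_that("repeat density is counted per consecutive region group", {
  tr <- repeat_track(genomic_intervals("1", seq(0, by = 200, length.out = 10),
                                       seq(10, by = 200, length.out = 10),
                                       source = "tandem"))
  regions <- genomic_intervals("1", c(0, 1000), c(1000, 2000))
  d <- repeat_density(tr, regions, group_size = 2)
  expect_equal(d$densities, 5.0)   # 10 repeats over 2 Kb, single group
  expect_equal(d$sd, 0)
  # group_size larger than the region count: one group
  d2 <- repeat_density(tr, regions, group_size = 100)
  expect_equal(length(d2$densities), 1L)
})

test_that("planted repeat density is recovered on a synthetic reference", {
  ref <- generate_reference(1e6, repeat_density_per_kb = 7, seed = 3)
  regions <- genomic_intervals("1", seq(0L, 999000L, by = 1000L),
                               seq(1000L, 1000000L, by = 1000L))
  d <- repeat_density(ref$track, regions, group_size = 100)
  expect_equal(length(d$densities), 10L)
  expect_lt(abs(d$mean - 7), 0.3)
  expect_lt(d$sd, 1)
})
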