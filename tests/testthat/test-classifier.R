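# feature table where S.ind is the only informative numeric column
feat_table <- function(s_ind, t_sns = 10) {
  n <- length(s_ind)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             T.sns = rep_len(t_sns, n), S.sns = 1, T.ind = 1,
             S.ind = s_ind, T = 10, S = 1 + s_ind, ratio.sns = 0.1,
             ratio.ind = 0.2, ratio = 0.15, cancer_type = "colon",
             stringsAsFactors = FALSE, check.names = FALSE)
}

test_that("packaged classifiers carry the published thresholds", {
  ex <- default_exome_classifier()
  expect_equal(coef(ex), c(S.ind = 0.395))
  expect_equal(ex$regime, "exome")
  ge <- default_genome_classifier()
  expect_equal(coef(ge), c(S.ind = 0.909))
  expect_equal(ge$regime, "genome")
  s <- summary(ex)
  expect_equal(s$n_leaves, 2L)
  expect_equal(s$features, "S.ind")
})

test_that("classification is a strict greater-than rule on S.ind", {
  f <- feat_table(c(2.61, 0.27, 0.395, 0.3951, 0))
  calls <- classify_msi(f)
  expect_equal(calls$predicted_status,
               c("MSI-H", "Non-MSI-H", "Non-MSI-H", "MSI-H", "Non-MSI-H"))
  expect_equal(calls$S.ind, f$S.ind)
  # whole-genome regime: strict at 0.909
  g <- classify_msi(feat_table(c(1.0, 0.909)), default_genome_classifier())
  expect_equal(g$predicted_status, c("MSI-H", "Non-MSI-H"))
})

test_that("the POLE flag needs high T.sns and low S.ind, both strict", {
  f <- feat_table(c(0.045, 0.25, 0.045, 0.18), t_sns = c(70, 70, 50, 70))
  expect_equal(pole_flag(f), c(TRUE, FALSE, FALSE, FALSE))
  f2 <- feat_table(0.045, t_sns = 60)      # equality fails the strict rule
  expect_false(pole_flag(f2))
  calls <- classify_msi(feat_table(c(0.045, 2.61), t_sns = c(70, 70)))
  expect_equal(calls$pole_flag, c(TRUE, FALSE))
  # flag never overrides the MSI call
  expect_equal(calls$predicted_status, c("Non-MSI-H", "MSI-H"))
  expect_error(pole_rule(t_sns_cutoff = -1), "positive")
})

test_that("separable 1-D training yields the midpoint stump", {
  f <- feat_table(c(0.1, 0.2, 0.6, 0.7))
  lab <- c("Non-MSI-H", "Non-MSI-H", "MSI-H", "MSI-H")
  fit <- msi_train(f, lab)
  expect_equal(coef(fit), c(S.ind = 0.4))
  expect_equal(predict(fit, f), lab)
})

test_that("degenerate training inputs are handled", {
  f <- feat_table(c(0.1, 0.2, 0.3))
  expect_warning(fit <- msi_train(f, rep("MSS", 3)), "single class")
  expect_equal(summary(fit)$n_leaves, 1L)
  expect_equal(unique(predict(fit, f)), "Non-MSI-H")
  expect_error(msi_train(f[0, ], character()), "empty")
})

test_that("training finds a perfectly separating feature among noise", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 60
    lab <- rep(c("MSI-H", "Non-MSI-H"), each = n / 2)
    f <- feat_table(runif(n))               # S.ind is noise here
    f$T.sns <- ifelse(lab == "MSI-H", runif(n, 2, 3), runif(n, 0, 1))
    fit <- msi_train(f, lab)
    expect_equal(summary(fit)$features, "T.sns")
    expect_equal(summary(fit)$n_leaves, 2L)
    expect_true(coef(fit) > 1 && coef(fit) < 2)
  }
})

test_that("MSI-H calls are monotone in S.ind under a positive threshold", {
  set.seed(78)
  f <- feat_table(runif(40, 0, 1.2))
  base <- classify_msi(f)$predicted_status
  for (k in c(1.5, 3, 10)) {
    f2 <- f
    f2$S.ind <- f$S.ind * k
    up <- classify_msi(f2)$predicted_status
    expect_true(all(!(base == "MSI-H" & up == "Non-MSI-H")))
  }
})

test_that("trained trees route missing values; default trees refuse them", {
  f <- feat_table(c(0.1, 0.15, 0.2, 0.9, 1.0, 1.1))
  lab <- rep(c("Non-MSI-H", "MSI-H"), each = 3)
  f$S.ind[1] <- NA
  fit <- msi_train(f, lab)
  got <- predict(fit, f)
  expect_equal(got[-1], lab[-1])
  expect_true(got[1] %in% c("MSI-H", "Non-MSI-H"))  # NA row routed, not fatal
  fna <- feat_table(0.5)
  fna$S.ind <- NA_real_
  expect_error(classify_msi(fna), "S01")
  expect_error(classify_msi(fna), "S.ind")
  # absent feature column
  expect_error(classify_msi(f[, setdiff(names(f), "S.ind")]), "S.ind")
})

test_that("cross-validation folds partition samples and are seed-determined", {
  f <- feat_table(c(runif(20, 0, 0.2), runif(20, 0.6, 1)))
  lab <- rep(c("Non-MSI-H", "MSI-H"), each = 20)
  cv1 <- cross_validate(f, lab, k = 5, seed = 42)
  cv2 <- cross_validate(f, lab, k = 5, seed = 42)
  expect_equal(cv1$concordance, 100)              # perfectly separable
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(as.integer(table(cv1$predictions$fold)), rep(8L, 5))
  # every sample lands in exactly one test fold
  expect_equal(anyDuplicated(cv1$predictions$sample_id), 0L)
  cv3 <- cross_validate(f, lab, k = 5, seed = 43)
  expect_false(identical(cv1$predictions$fold, cv3$predictions$fold))
  expect_warning(cross_validate(f[c(1:20, 21:23), ], lab[c(1:20, 21:23)],
                                k = 5, seed = 1), "fewer members")
})

test_that("permuted labels drive cross-validated concordance to chance", {
  set.seed(91)
  n <- 400
  f <- feat_table(c(runif(n / 2, 0, 0.2), runif(n / 2, 0.6, 1)))
  lab <- sample(rep(c("Non-MSI-H", "MSI-H"), each = n / 2))  # permuted
  cv <- cross_validate(f, lab, k = 5, seed = 7)
  expect_gt(cv$concordance, 40)
  expect_lt(cv$concordance, 60)
})

test_that("classifier bundles round-trip through JSON", {
  for (b in list(default_exome_classifier(), default_genome_classifier())) {
    j <- msi_classifier_to_json(b)
    b2 <- msi_classifier_from_json(j)
    expect_identical(msi_classifier_to_json(b2), j)
    expect_equal(coef(b2), coef(b))
    expect_equal(b2$regime, b$regime)
    expect_equal(b2$provenance, b$provenance)
  }
})

test_that("a two-level tree with a cancer-type split survives serialization", {
  # MSI-H only for high-S.ind colon tumors: the tree must first split on
  # S.ind, then on cancer_type (one-vs-rest)
  f4 <- feat_table(c(0.1, 0.1, 0.9, 0.9))
  f4$cancer_type <- c("colon", "gastric", "colon", "gastric")
  f <- rbind(f4, f4, f4)
  lab <- rep(c("Non-MSI-H", "Non-MSI-H", "MSI-H", "Non-MSI-H"), 3)
  fit <- msi_train(f, lab)
  expect_setequal(summary(fit)$features, c("S.ind", "cancer_type"))
  expect_equal(summary(fit)$depth, 2L)
  expect_equal(predict(fit, f4),
               c("Non-MSI-H", "Non-MSI-H", "MSI-H", "Non-MSI-H"))
  p <- tempfile(fileext = ".json")
  write_msi_classifier(fit, p)
  back <- read_msi_classifier(p)
  expect_identical(predict(back, f4), predict(fit, f4))
  expect_identical(msi_classifier_to_json(back), msi_classifier_to_json(fit))
})

test_that("malformed classifier documents report the missing field", {
  j <- msi_classifier_to_json(default_exome_classifier())
  expect_error(msi_classifier_from_json(substr(j, 1, nchar(j) %/% 2)),
               "malformed")
  doc <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  doc$tree$threshold <- NULL
  expect_error(
    msi_classifier_from_json(jsonlite::toJSON(doc, auto_unbox = TRUE)),
    "threshold")
  doc2 <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  doc2$tree <- NULL
  expect_error(
    msi_classifier_from_json(jsonlite::toJSON(doc2, auto_unbox = TRUE)),
    "'tree'")
})

test_that("the formula interface matches the default interface", {
  f <- feat_table(c(0.1, 0.2, 0.6, 0.7))
  lab <- c("Non-MSI-H", "Non-MSI-H", "MSI-H", "MSI-H")
  d <- cbind(f, msi_status = lab)
  fit1 <- msi_train(msi_status ~ ., data = d)
  fit2 <- msi_train(f, lab)
  expect_equal(coef(fit1), coef(fit2))
})
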