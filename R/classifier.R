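# Feature columns offered to the tree, in canonical order. Order also serves
# as the deterministic tie-break when two features give equal gain ratio.
MSI_NUMERIC_FEATURES <- c("T.sns", "S.sns", "T.ind", "S.ind", "T", "S",
                          "ratio.sns", "ratio.ind", "ratio")
MSI_CLASSES <- c("Non-MSI-H", "MSI-H")

# MSI-L and MSS laboratory categories are grouped as non-MSI-H throughout
group_non_msih <- function(labels) {
  labels <- as.character(labels)
  labels[labels %in% c("MSI-L", "MSS")] <- "Non-MSI-H"
  bad <- !labels %in% MSI_CLASSES & !is.na(labels)
  if (any(bad))
    stop("unrecognized MSI label(s): ",
         paste(unique(labels[bad]), collapse = ", "))
  labels
}

## ---- tree primitives -------------------------------------------------------

tree_leaf <- function(label, n = NA_real_, n_pos = NA_real_) {
  list(leaf = TRUE, label = label, n = n, n_pos = n_pos)
}

tree_node <- function(feature, type, left, right, threshold = NULL,
                      level = NULL, na_branch = NULL, n = NA_real_,
                      n_pos = NA_real_) {
  list(leaf = FALSE, feature = feature, type = type, threshold = threshold,
       level = level, na_branch = na_branch, left = left, right = right,
       n = n, n_pos = n_pos)
}

stump <- function(feature, threshold, above = "MSI-H", below = "Non-MSI-H") {
  tree_node(feature, "numeric", tree_leaf(below), tree_leaf(above),
            threshold = threshold)
}

tree_features <- function(node) {
  if (node$leaf) return(character())
  unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_leaves <- function(node) {
  if (node$leaf) return(1L)
  tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

# route rows of `data` through the tree; errors name the sample and feature
# when an NA hits a node with no stored NA-routing branch
tree_predict <- function(node, data, sample_id = NULL) {
  n <- nrow(data)
  out <- character(n)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  rec <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) {
      out[idx] <<- node$label
      return()
    }
    v <- data[[node$feature]]
    if (is.null(v))
      stop("classifier requires feature '", node$feature,
           "' absent from the feature table")
    v <- v[idx]
    nas <- is.na(v)
    if (any(nas) && is.null(node$na_branch))
      stop(sprintf("missing value of feature '%s' for sample %s",
                   node$feature, sample_id[idx[which(nas)[1]]]))
    go_left <- if (node$type == "numeric") v <= node$threshold
               else v != node$level
    if (any(nas)) go_left[nas] <- node$na_branch == "left"
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(node, seq_len(n))
  out
}

## ---- classifier bundle -----------------------------------------------------

new_msi_classifier <- function(tree, regime = c("exome", "genome"),
                               provenance = "", version = "1") {
  regime <- match.arg(regime)
  structure(list(tree = tree, regime = regime, provenance = provenance,
                 version = version),
            class = "msi_classifier")
}

#' Packaged default MSI classifier for whole-exome data
#'
#' The default classifier is a single-split decision tree on `S.ind`, the
#' number of microindels in simple repeats per Mb of targeted sequence:
#' tumors with `S.ind > 0.395` are called MSI-H, all others non-MSI-H
#' (equality goes to non-MSI-H; the rule is a strict inequality). No other
#' variable is used.
#'
#' @return An `msi_classifier` with regime `"exome"`.
#' @export
default_exome_classifier <- function() {
  new_msi_classifier(
    stump("S.ind", 0.395),
    regime = "exome",
    provenance = paste("packaged default: single-threshold decision tree on",
                       "S.ind for whole-exome capture; original training",
                       "hyperparameters unknown"))
}

#' Packaged default MSI classifier for whole-genome data
#'
#' Simple repeats are denser genome-wide than in exome target regions, so
#' the whole-genome classifier uses a higher `S.ind` cutoff: tumors with
#' `S.ind > 0.909` are called MSI-H.
#'
#' @return An `msi_classifier` with regime `"genome"`.
#' @export
default_genome_classifier <- function() {
  new_msi_classifier(
    stump("S.ind", 0.909),
    regime = "genome",
    provenance = paste("packaged default: single-threshold decision tree on",
                       "S.ind retrained for whole-genome sequencing"))
}

#' POLE-deficiency flag rule
#'
#' Ultra-hypermutated tumors with defective POLE proofreading show very high
#' substitution burdens but few repeat microindels. Samples with
#' `T.sns > t_sns_cutoff` and `S.ind < s_ind_cutoff` (both strict) are
#' flagged as possible POLE-deficient tumors. The flag is reported alongside
#' the MSI call and never overrides it.
#'
#' @param t_sns_cutoff SNSs/Mb threshold (default 60).
#' @param s_ind_cutoff Repeat-microindels/Mb threshold (default 0.18).
#' @return A `pole_rule` object.
#' @export
pole_rule <- function(t_sns_cutoff = 60, s_ind_cutoff = 0.18) {
  if (!is.numeric(t_sns_cutoff) || t_sns_cutoff <= 0 ||
      !is.numeric(s_ind_cutoff) || s_ind_cutoff <= 0)
    stop("POLE rule cutoffs must be positive")
  structure(list(t_sns_cutoff = t_sns_cutoff, s_ind_cutoff = s_ind_cutoff),
            class = "pole_rule")
}

#' Apply the POLE flag rule to a feature table
#' @param features Feature data frame with `T.sns` and `S.ind` columns.
#' @param rule A [pole_rule()].
#' @return Logical vector.
#' @export
pole_flag <- function(features, rule = pole_rule()) {
  stopifnot(inherits(rule, "pole_rule"))
  for (col in c("T.sns", "S.ind"))
    if (is.null(features[[col]]))
      stop("POLE flagging requires feature '", col, "'")
  features$T.sns > rule$t_sns_cutoff & features$S.ind < rule$s_ind_cutoff
}

#' Classify tumors as MSI-H or non-MSI-H
#'
#' Applies a classifier's decision tree to a feature table and, in the same
#' pass, the POLE-deficiency flag rule. MSI status and the POLE flag are
#' independent outputs.
#'
#' @param features Feature data frame from [compute_features()] (or
#'   [read_features()]).
#' @param classifier An `msi_classifier`; default the packaged exome
#'   classifier.
#' @param rule A [pole_rule()]; `NULL` suppresses flagging.
#' @return A data frame with columns `sample_id`, `predicted_status`,
#'   `pole_flag` and `S.ind` (the value the default tree uses).
#' @export
classify_msi <- function(features, classifier = default_exome_classifier(),
                         rule = pole_rule()) {
  stopifnot(inherits(classifier, "msi_classifier"))
  status <- tree_predict(classifier$tree, features, features$sample_id)
  flag <- if (is.null(rule)) NA else pole_flag(features, rule)
  out <- data.frame(
    sample_id = if (!is.null(features$sample_id)) features$sample_id
                else as.character(seq_len(nrow(features))),
    predicted_status = status,
    pole_flag = flag,
    S.ind = if (!is.null(features$S.ind)) features$S.ind else NA_real_,
    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

## ---- training --------------------------------------------------------------

entropy2 <- function(pos, n) {
  # binary entropy in bits, vectorized; 0*log(0) := 0
  p <- pos / n
  q <- 1 - p
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + q[ok] * log2(q[ok]))
  h
}

best_numeric_split <- function(x, y_pos, min_leaf, n_node) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2 * min_leaf) return(NULL)
  o <- order(x[ok])
  xs <- x[ok][o]
  ys <- y_pos[ok][o]
  bnd <- which(diff(xs) > 0)                 # split after sorted index i
  bnd <- bnd[bnd >= min_leaf & (n - bnd) >= min_leaf]
  if (length(bnd) == 0) return(NULL)
  cpos <- cumsum(ys)
  tot_pos <- cpos[n]
  nl <- bnd
  nr <- n - nl
  pl <- cpos[bnd]
  pr <- tot_pos - pl
  base <- entropy2(tot_pos, n)
  child <- (nl / n) * entropy2(pl, nl) + (nr / n) * entropy2(pr, nr)
  gain <- (n / n_node) * (base - child)      # penalize missing values
  fl <- nl / n
  split_info <- -(fl * log2(fl) + (1 - fl) * log2(1 - fl))
  gr <- gain / split_info
  i <- which.max(gr)                         # first max: smallest threshold
  list(gain = gain[i], gain_ratio = gr[i],
       threshold = (xs[bnd[i]] + xs[bnd[i] + 1]) / 2,
       na_branch = if (nl[i] >= nr[i]) "left" else "right")
}

best_categorical_split <- function(x, y_pos, min_leaf, n_node) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2 * min_leaf) return(NULL)
  xs <- x[ok]
  ys <- y_pos[ok]
  best <- NULL
  for (lv in sort(unique(xs))) {             # one-vs-rest splits
    right <- xs == lv
    nr <- sum(right)
    nl <- n - nr
    if (nr < min_leaf || nl < min_leaf) next
    base <- entropy2(sum(ys), n)
    child <- (nl / n) * entropy2(sum(ys[!right]), nl) +
             (nr / n) * entropy2(sum(ys[right]), nr)
    gain <- (n / n_node) * (base - child)
    fl <- nl / n
    split_info <- -(fl * log2(fl) + (1 - fl) * log2(1 - fl))
    gr <- gain / split_info
    if (is.null(best) || gr > best$gain_ratio + 1e-12)
      best <- list(gain = gain, gain_ratio = gr, level = lv,
                   na_branch = if (nl >= nr) "left" else "right")
  }
  best
}

#' Train an MSI decision-tree classifier
#'
#' Greedy top-down induction of a binary decision tree on the mutation-rate
#' variables (and optionally the cancer-type label), in the C4.5 tradition:
#' splits are scored by information-gain ratio, candidate thresholds are
#' midpoints between consecutive distinct sorted feature values, ties are
#' broken toward the smallest threshold (and toward the earlier feature in
#' the canonical column order), growth stops at `min_leaf`, `max_depth` or
#' zero gain, and the grown tree is post-pruned by collapsing any subtree
#' whose replacement with its majority-class leaf does not increase training
#' error. Rows with a missing feature value are down-weighted in the gain of
#' that feature's splits and routed to the larger child; the routing branch
#' is stored so prediction tolerates missing values.
#'
#' @param features Feature data frame (columns as produced by
#'   [compute_features()]); alternatively a formula `labels ~ .` with `data`.
#' @param labels Character vector of laboratory statuses aligned with the
#'   rows of `features`; `MSI-L` and `MSS` are grouped as `Non-MSI-H`.
#' @param data Data frame when `features` is a formula.
#' @param min_leaf Minimum samples per child (default 2).
#' @param max_depth Maximum tree depth (default 5).
#' @param use_cancer_type Offer `cancer_type` as a one-vs-rest categorical
#'   split candidate (default `TRUE`).
#' @param regime Capture regime recorded in the bundle.
#' @param provenance Free-text training description; a default is composed.
#' @return An `msi_classifier`.
#' @export
msi_train <- function(features, labels = NULL, data = NULL, min_leaf = 2L,
                      max_depth = 5L, use_cancer_type = TRUE,
                      regime = "exome", provenance = NULL) {
  if (inherits(features, "formula")) {
    if (is.null(data)) stop("a formula interface requires `data`")
    resp <- all.vars(features[[2]])
    labels <- data[[resp]]
    features <- data[, setdiff(names(data), resp), drop = FALSE]
  }
  if (nrow(features) == 0 || is.null(labels)) stop("empty training input")
  labels <- group_non_msih(labels)
  if (length(labels) != nrow(features))
    stop("labels must align with feature rows")
  if (anyNA(labels)) stop("training labels must not be NA")
  y_pos <- labels == "MSI-H"

  num_feats <- intersect(MSI_NUMERIC_FEATURES, names(features))
  cat_feats <- if (use_cancer_type && "cancer_type" %in% names(features) &&
                   !all(is.na(features$cancer_type))) "cancer_type"
               else character()
  if (length(num_feats) + length(cat_feats) == 0)
    stop("no usable feature columns found")

  single_class <- length(unique(labels)) == 1
  if (single_class)
    warning("training labels contain a single class; returning a one-leaf tree")
  if (!single_class && min(table(labels)) < 2)
    warning("a class has fewer than 2 training samples")

  majority <- function(idx) {
    np <- sum(y_pos[idx])
    if (np > length(idx) - np) "MSI-H" else "Non-MSI-H"
  }

  grow <- function(idx, depth) {
    np <- sum(y_pos[idx])
    n <- length(idx)
    leaf <- tree_leaf(majority(idx), n = n, n_pos = np)
    if (np == 0 || np == n || depth >= max_depth || n < 2 * min_leaf)
      return(leaf)
    best <- NULL
    for (f in num_feats) {
      cand <- best_numeric_split(features[[f]][idx], y_pos[idx], min_leaf, n)
      if (!is.null(cand) && cand$gain > 1e-12 &&
          (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12)) {
        cand$feature <- f
        cand$type <- "numeric"
        best <- cand
      }
    }
    for (f in cat_feats) {
      cand <- best_categorical_split(features[[f]][idx], y_pos[idx], min_leaf, n)
      if (!is.null(cand) && cand$gain > 1e-12 &&
          (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12)) {
        cand$feature <- f
        cand$type <- "categorical"
        best <- cand
      }
    }
    if (is.null(best)) return(leaf)
    v <- features[[best$feature]][idx]
    nas <- is.na(v)
    go_left <- if (best$type == "numeric") v <= best$threshold else v != best$level
    go_left[nas] <- best$na_branch == "left"
    if (!any(go_left) || all(go_left)) return(leaf)
    tree_node(best$feature, best$type,
              left = grow(idx[go_left], depth + 1L),
              right = grow(idx[!go_left], depth + 1L),
              threshold = best$threshold, level = best$level,
              na_branch = best$na_branch, n = n, n_pos = np)
  }

  # collapse any subtree whose majority-class leaf does not increase
  # training error
  prune <- function(node) {
    if (node$leaf) {
      node$err <- min(node$n_pos, node$n - node$n_pos)
      return(node)
    }
    node$left <- prune(node$left)
    node$right <- prune(node$right)
    sub_err <- node$left$err + node$right$err
    leaf_err <- min(node$n_pos, node$n - node$n_pos)
    if (leaf_err <= sub_err) {
      lab <- if (node$n_pos > node$n - node$n_pos) "MSI-H" else "Non-MSI-H"
      node <- tree_leaf(lab, n = node$n, n_pos = node$n_pos)
      node$err <- leaf_err
    } else {
      node$err <- sub_err
    }
    node
  }
  strip_err <- function(node) {
    node$err <- NULL
    if (!node$leaf) {
      node$left <- strip_err(node$left)
      node$right <- strip_err(node$right)
    }
    node
  }

  tree <- strip_err(prune(grow(seq_len(nrow(features)), 0L)))
  if (is.null(provenance))
    provenance <- sprintf(
      "trained on %d samples (%d MSI-H) by gain-ratio induction, min_leaf=%d, max_depth=%d",
      nrow(features), sum(y_pos), min_leaf, max_depth)
  new_msi_classifier(tree, regime = regime, provenance = provenance)
}

## ---- cross-validation ------------------------------------------------------

#' Stratified k-fold cross-validation of the tree classifier
#'
#' Folds are stratified by class and fully determined by the seed; the
#' pooled concordance is `100 * correct / n` over all held-out predictions.
#'
#' @param features Feature data frame.
#' @param labels Laboratory statuses aligned with rows (`MSI-L`/`MSS`
#'   grouped as `Non-MSI-H`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param ... Passed to [msi_train()].
#' @return An `msi_cv` list: `concordance` (percent), `folds` (per-fold
#'   breakdown), `predictions`.
#' @export
cross_validate <- function(features, labels, k = 5L, seed = 1L, ...) {
  labels <- group_non_msih(labels)
  n <- nrow(features)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  cls_sizes <- table(labels)
  if (any(cls_sizes < k))
    warning("class '", names(cls_sizes)[which.min(cls_sizes)],
            "' has fewer members than k; stratification degrades")
  fold <- integer(n)
  with_seed(seed, {
    for (cl in names(cls_sizes)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pred <- character(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- suppressWarnings(
      msi_train(features[!test, , drop = FALSE], labels[!test], ...))
    pred[test] <- tree_predict(fit$tree, features[test, , drop = FALSE],
                               features$sample_id[test])
  }
  correct <- pred == labels
  folds <- data.frame(
    fold = seq_len(k),
    n = as.integer(tabulate(fold, k)),
    correct = as.integer(vapply(seq_len(k),
                                function(f) sum(correct[fold == f]), 0L)))
  folds$concordance <- 100 * folds$correct / folds$n
  structure(list(concordance = 100 * sum(correct) / n,
                 folds = folds,
                 predictions = data.frame(
                   sample_id = if (!is.null(features$sample_id))
                                 features$sample_id
                               else as.character(seq_len(n)),
                   fold = fold, predicted = pred, label = labels,
                   stringsAsFactors = FALSE)),
            class = "msi_cv")
}

#' @export
print.msi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: %.1f%% concordance (n = %d)\n",
              nrow(x$folds), x$concordance, nrow(x$predictions)))
  print(x$folds, row.names = FALSE)
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

node_to_list <- function(node) {
  if (node$leaf) {
    list(leaf = TRUE, label = node$label, n = node$n, n_pos = node$n_pos)
  } else {
    out <- list(leaf = FALSE, feature = node$feature, type = node$type,
                n = node$n, n_pos = node$n_pos,
                left = node_to_list(node$left),
                right = node_to_list(node$right))
    if (!is.null(node$threshold)) out$threshold <- node$threshold
    if (!is.null(node$level)) out$level <- node$level
    if (!is.null(node$na_branch)) out$na_branch <- node$na_branch
    out
  }
}

node_from_list <- function(x) {
  need <- function(field) {
    if (is.null(x[[field]]))
      stop("classifier document is missing field '", field, "'")
    x[[field]]
  }
  if (isTRUE(need("leaf"))) {
    tree_leaf(need("label"),
              n = if (is.null(x$n)) NA_real_ else as.numeric(x$n),
              n_pos = if (is.null(x$n_pos)) NA_real_ else as.numeric(x$n_pos))
  } else {
    type <- need("type")
    if (type == "numeric") thr <- as.numeric(need("threshold")) else thr <- NULL
    if (type == "categorical") lv <- as.character(need("level")) else lv <- NULL
    tree_node(need("feature"), type,
              left = node_from_list(need("left")),
              right = node_from_list(need("right")),
              threshold = thr, level = lv,
              na_branch = x$na_branch,
              n = if (is.null(x$n)) NA_real_ else as.numeric(x$n),
              n_pos = if (is.null(x$n_pos)) NA_real_ else as.numeric(x$n_pos))
  }
}

#' Serialize a classifier to JSON
#' @param classifier An `msi_classifier`.
#' @return A JSON string.
#' @export
msi_classifier_to_json <- function(classifier) {
  stopifnot(inherits(classifier, "msi_classifier"))
  doc <- list(format = "msicall-classifier",
              version = classifier$version,
              regime = classifier$regime,
              provenance = classifier$provenance,
              tree = node_to_list(classifier$tree))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE))
}

#' Restore a classifier from JSON
#' @param text A JSON string (as from [msi_classifier_to_json()]).
#' @return An `msi_classifier`.
#' @export
msi_classifier_from_json <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("malformed classifier document: ",
                                           conditionMessage(e)))
  for (field in c("regime", "tree"))
    if (is.null(doc[[field]]))
      stop("classifier document is missing field '", field, "'")
  new_msi_classifier(node_from_list(doc$tree),
                     regime = doc$regime,
                     provenance = if (is.null(doc$provenance)) ""
                                  else doc$provenance,
                     version = if (is.null(doc$version)) "1" else doc$version)
}

#' Write a classifier JSON file
#' @param classifier An `msi_classifier`.
#' @param path Output path.
#' @export
write_msi_classifier <- function(classifier, path) {
  writeLines(msi_classifier_to_json(classifier), path)
  invisible(path)
}

#' Read a classifier JSON file
#' @param path Path to a JSON file.
#' @return An `msi_classifier`.
#' @export
read_msi_classifier <- function(path) {
  msi_classifier_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

## ---- methods ---------------------------------------------------------------

format_tree <- function(node, indent = "") {
  if (node$leaf) {
    extra <- if (!is.na(node$n)) sprintf("  (n=%g)", node$n) else ""
    return(paste0(indent, "-> ", node$label, extra))
  }
  cond <- if (node$type == "numeric")
    sprintf("%s <= %g", node$feature, node$threshold)
  else sprintf("%s != '%s'", node$feature, node$level)
  c(paste0(indent, "if ", cond, ":"),
    format_tree(node$left, paste0(indent, "  ")),
    paste0(indent, "else:"),
    format_tree(node$right, paste0(indent, "  ")))
}

#' @export
print.msi_classifier <- function(x, ...) {
  cat("MSI decision-tree classifier (", x$regime, " regime)\n", sep = "")
  cat(format_tree(x$tree), sep = "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.msi_classifier <- function(object, ...) {
  structure(list(regime = object$regime,
                 depth = tree_depth(object$tree),
                 n_leaves = tree_n_leaves(object$tree),
                 features = tree_features(object$tree),
                 provenance = object$provenance),
            class = "summary.msi_classifier")
}

#' @export
print.summary.msi_classifier <- function(x, ...) {
  cat("MSI classifier summary\n")
  cat("  regime:  ", x$regime, "\n")
  cat("  depth:   ", x$depth, "\n")
  cat("  leaves:  ", x$n_leaves, "\n")
  cat("  features:", if (length(x$features)) paste(x$features, collapse = ", ")
                     else "(none; single leaf)", "\n")
  invisible(x)
}

#' Split thresholds of a fitted classifier
#'
#' Returns the numeric thresholds of all internal nodes, named by the split
#' feature (the packaged exome classifier yields `c(S.ind = 0.395)`).
#' @param object An `msi_classifier`.
#' @param ... Unused.
#' @export
coef.msi_classifier <- function(object, ...) {
  collect <- function(node) {
    if (node$leaf) return(numeric())
    own <- if (node$type == "numeric")
      stats::setNames(node$threshold, node$feature) else numeric()
    c(own, collect(node$left), collect(node$right))
  }
  collect(object$tree)
}

#' Predict MSI status for new samples
#'
#' @param object An `msi_classifier`.
#' @param newdata Feature data frame.
#' @param type `"class"` for the status vector, `"table"` for the full
#'   classification table including the POLE flag.
#' @param rule A [pole_rule()] used when `type = "table"`.
#' @param ... Unused.
#' @export
predict.msi_classifier <- function(object, newdata,
                                   type = c("class", "table"),
                                   rule = pole_rule(), ...) {
  type <- match.arg(type)
  if (type == "class")
    tree_predict(object$tree, newdata, newdata$sample_id)
  else
    classify_msi(newdata, object, rule)
}

## ---- internal RNG scoping --------------------------------------------------

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
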