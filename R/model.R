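# Random-forest granule classifier: fitting, cross-validation, proteome
# prediction, tier-wise identification rates, and ranking metrics.

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal integral of the ROC curve with tied scores collapsed to a
#' single operating point, which makes the result identical to the
#' pairwise-concordance (Mann-Whitney) statistic with ties counted 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), same length as `scores`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels); N <- sum(1L - labels)
  if (P == 0L || N == 0L) stop("need both classes to compute AUC")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / P)
  fpr <- c(0, fp[keep] / N)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) integral: the sum over distinct score
#' thresholds of the recall increment times the precision at that
#' threshold.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels)
  if (P == 0L) stop("no positives; PR-AUC undefined")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1L] != s[-length(s)], TRUE)
  prec <- (tp / (tp + fp))[keep]
  rec <- (tp / P)[keep]
  sum(diff(c(0, rec)) * prec)
}

#' Fit the random-forest granule classifier
#'
#' Fits a seeded random forest (default 500 trees, `sqrt(p)` candidate
#' features per split, unlimited depth) on a feature table and binary
#' labels, and packages it with the exact feature-column order and the
#' k-mer vocabulary so that later predictions are guaranteed to see the
#' same representation.
#'
#' @param features Numeric feature matrix (rownames = accessions), e.g.
#'   from [build_feature_table()].
#' @param labels Binary labels (1 = granule protein), aligned with rows.
#' @param vocabulary Optional vocabulary list to persist with the model.
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(ncol))`.
#' @param seed RNG seed; fits are reproducible given the seed.
#' @param threshold High-confidence probability cutoff stored with the
#'   model (default 0.7).
#' @return Object of class `granule_model`.
#' @export
granule_fit <- function(features, labels, vocabulary = NULL,
                        ntree = 500L, mtry = NULL, seed = 1L,
                        threshold = 0.7) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% 0:1))
  if (!all(is.finite(features))) stop("non-finite feature values")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  forest <- with_seed(seed,
    randomForest::randomForest(x = features,
                               y = factor(labels, levels = c(0L, 1L)),
                               ntree = ntree, mtry = mtry))
  structure(list(forest = forest,
                 feature_names = colnames(features),
                 vocabulary = vocabulary,
                 ntree = ntree, mtry = mtry, seed = seed,
                 threshold = threshold,
                 n_train = nrow(features),
                 n_positive = sum(labels)),
            class = "granule_model")
}

#' @export
print.granule_model <- function(x, ...) {
  cat("Granule propensity model (random forest)\n",
      "  trees: ", x$ntree, ", mtry: ", x$mtry, ", seed: ", x$seed, "\n",
      "  training: ", x$n_train, " proteins (", x$n_positive, " positive)\n",
      "  features: ", length(x$feature_names),
      ", high-confidence cutoff: p > ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' @export
summary.granule_model <- function(object, n_top = 10L, ...) {
  imp <- gini_importance(object)
  cat("Top", n_top, "features by normalized Gini importance:\n")
  print(round(utils::head(sort(imp, decreasing = TRUE), n_top), 4))
  invisible(imp)
}

#' Normalized Gini importance of a fitted model
#'
#' Mean decrease in node impurity per feature, normalized to sum to 1.
#'
#' @param model A `granule_model`.
#' @return Named numeric vector over the model's features.
#' @export
gini_importance <- function(model) {
  imp <- model$forest$importance[, "MeanDecreaseGini"]
  imp / sum(imp)
}

#' @export
plot.granule_model <- function(x, n_top = 15L, ...) {
  imp <- sort(gini_importance(x), decreasing = TRUE)[seq_len(n_top)]
  graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                    xlab = "normalized Gini importance", ...)
  invisible(x)
}

#' Predict granule propensities for a proteome
#'
#' Scores each protein with the forest's positive-class vote fraction. The
#' feature columns must match the model's training columns exactly (order
#' included); mismatches raise an error naming the missing/extra columns.
#'
#' @param object A `granule_model`.
#' @param features Feature matrix with rownames = accessions, built with
#'   the model's vocabulary.
#' @param ... Unused.
#' @return Data frame (`accession`, `p`, `high_confidence`), sorted by
#'   decreasing `p`.
#' @export
predict.granule_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (anyDuplicated(rownames(features)))
    stop("duplicate accession rows: ",
         paste(unique(rownames(features)[duplicated(rownames(features))]),
               collapse = ", "))
  missing <- setdiff(object$feature_names, colnames(features))
  extra <- setdiff(colnames(features), object$feature_names)
  if (length(missing) || length(extra))
    stop("feature columns do not match the model",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5L), collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(utils::head(extra, 5L), collapse = ", ")))
  features <- features[, object$feature_names, drop = FALSE]
  p <- stats::predict(object$forest, features, type = "prob")[, "1"]
  out <- data.frame(accession = rownames(features), p = as.numeric(p),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$p, out$accession), ]
  rownames(out) <- NULL
  out$high_confidence <- out$p > object$threshold
  out
}

#' Persist / restore a fitted model bundle
#'
#' The bundle keeps the forest together with the feature order and the
#' k-mer vocabulary; reloading reproduces predictions exactly.
#'
#' @param model A `granule_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "granule_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "granule_model")) stop("not a granule_model bundle")
  model
}

# Stratified k-fold assignment: within each class, a seeded shuffle is
# dealt round-robin into folds, so fold class ratios differ from the global
# ratio by at most one sample.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop("class ", cls, " has fewer members (", length(idx),
             ") than folds (", k, ")")
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the granule classifier
#'
#' Splits the learning set into stratified folds, fits a forest per fold
#' and scores the held-out samples with AUC (trapezoidal ROC) and PR-AUC.
#' In `"strict"` vocabulary mode (the default when sequences are supplied)
#' the k-mer vocabulary is re-selected per fold from that fold's training
#' positives only, and the k-mer feature block is rebuilt for all samples,
#' so no test-fold sequence ever influences feature selection. `"fast"`
#' mode selects the vocabulary once from all positives. When only a
#' prebuilt feature table is given the table is used as-is.
#'
#' Per-fold Gini importances are normalized to sum to 1 and averaged over
#' folds (features absent from a fold's vocabulary contribute 0), so the
#' averaged importance vector also sums to 1.
#'
#' @param features Prebuilt feature matrix (may be `NULL` when `records`
#'   is given).
#' @param labels Binary labels aligned with rows/records.
#' @param records Optional named sequence vector enabling per-fold
#'   featurization.
#' @param k Number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and forest fits.
#' @param vocab_mode `"strict"` or `"fast"` (ignored without `records`).
#' @param top_n Vocabulary size per k-mer length.
#' @param ntree,mtry Forest hyperparameters (see [granule_fit()]).
#' @return Object of class `granule_cv`: per-fold AUC/PR-AUC, their means
#'   and standard errors (sd/sqrt(k)), averaged importances, and the fold
#'   assignment.
#' @export
granule_cv <- function(features = NULL, labels, records = NULL, k = 10L,
                       seed = 1L, vocab_mode = c("strict", "fast"),
                       top_n = 50L, ntree = 500L, mtry = NULL) {
  vocab_mode <- match.arg(vocab_mode)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  n <- length(labels)
  if (n < 20L) stop("need at least 20 samples")
  use_records <- !is.null(records)
  if (use_records) {
    stopifnot(length(records) == n)
  } else {
    if (is.null(features)) stop("supply `features` or `records`")
    features <- as.matrix(features)
    stopifnot(nrow(features) == n)
  }
  if (use_records) {
    base <- t(vapply(records,
                     function(s) c(compute_physchem(s), aa_composition(s)),
                     numeric(39L)))
    rownames(base) <- names(records)
    if (vocab_mode == "fast") {
      vocab <- build_vocabulary(records[labels == 1L], top_n = top_n)
      features <- cbind(base, kmer_block(records, vocab))
    }
  }
  folds <- stratified_folds(labels, k, seed)
  fold_auc <- fold_pr <- numeric(k)
  fold_imp <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(unique(labels[!test])) < 2L || length(unique(labels[test])) < 2L)
      stop("fold ", f, " has a single class")
    if (use_records && vocab_mode == "strict") {
      vocab_f <- build_vocabulary(records[!test & labels == 1L], top_n = top_n)
      X <- cbind(base, kmer_block(records, vocab_f))
    } else {
      X <- features
    }
    fit <- granule_fit(X[!test, , drop = FALSE], labels[!test],
                       ntree = ntree, mtry = mtry, seed = seed + f)
    p <- stats::predict(fit$forest, X[test, , drop = FALSE], type = "prob")[, "1"]
    fold_auc[f] <- roc_auc(p, labels[test])
    fold_pr[f] <- pr_auc(p, labels[test])
    fold_imp[[f]] <- gini_importance(fit)
  }
  all_feats <- unique(unlist(lapply(fold_imp, names)))
  imp_mat <- vapply(fold_imp, function(v) {
    out <- stats::setNames(numeric(length(all_feats)), all_feats)
    out[names(v)] <- v
    out
  }, numeric(length(all_feats)))
  structure(list(fold_auc = fold_auc, fold_pr_auc = fold_pr,
                 mean_auc = mean(fold_auc),
                 sem_auc = stats::sd(fold_auc) / sqrt(k),
                 mean_pr_auc = mean(fold_pr),
                 sem_pr_auc = stats::sd(fold_pr) / sqrt(k),
                 importance = rowMeans(imp_mat),
                 fold_importance = fold_imp,
                 folds = folds, k = k, seed = seed,
                 vocab_mode = if (use_records) vocab_mode else "precomputed"),
            class = "granule_cv")
}

# k-mer feature block for a set of records under a fixed vocabulary
kmer_block <- function(records, vocab) {
  blk <- t(vapply(records, function(s)
    c(kmer_fractions(s, vocab$k2), kmer_fractions(s, vocab$k3)),
    numeric(length(vocab$k2) + length(vocab$k3))))
  colnames(blk) <- c(paste0("k2_", vocab$k2), paste0("k3_", vocab$k3))
  rownames(blk) <- names(records)
  blk
}

#' @export
print.granule_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (", x$vocab_mode, " vocabulary)\n",
      sprintf("  AUC:    %.3f +/- %.3f (mean +/- SEM)\n", x$mean_auc, x$sem_auc),
      sprintf("  PR-AUC: %.3f +/- %.3f\n", x$mean_pr_auc, x$sem_pr_auc),
      sep = "")
  invisible(x)
}

#' @export
summary.granule_cv <- function(object, n_top = 10L, ...) {
  print(object)
  cat("Top features by averaged Gini importance:\n")
  print(round(utils::head(sort(object$importance, decreasing = TRUE), n_top), 4))
  invisible(object)
}

#' Tier-wise identification rates
#'
#' Fraction of catalogued proteins of each evidence tier that the model
#' scores at or above `threshold`, reported as a percentage. Stronger-
#' evidence tiers are expected to be identified at higher rates.
#'
#' @param model A `granule_model`.
#' @param features_by_tier Named list (`"1"` .. `"4"`) of feature matrices.
#' @param threshold Identification cutoff on the predicted probability.
#' @return Named numeric vector of percentages in \[0, 100\].
#' @export
tier_identification_rates <- function(model, features_by_tier, threshold = 0.5) {
  if (length(features_by_tier) == 0L) stop("empty tier table")
  wanted <- as.character(1:4)
  missing <- setdiff(wanted, names(features_by_tier))
  if (length(missing) > 0L)
    warning("missing tier(s): ", paste(missing, collapse = ", "))
  present <- intersect(wanted, names(features_by_tier))
  vapply(features_by_tier[present], function(feat) {
    pred <- stats::predict(model$forest,
                           as.matrix(feat)[, model$feature_names, drop = FALSE],
                           type = "prob")[, "1"]
    100 * mean(pred >= threshold)
  }, numeric(1L))
}
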