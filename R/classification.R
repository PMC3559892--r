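# Balanced random-forest classification with out-of-bag evaluation, mean
# decrease in Gini (MDG) feature importance, and a permutation null for
# importance significance. The forest engine is the randomForest package
# (n_tree bootstrap trees, m_try = floor(sqrt(p)) features per node).

#' Classifier configuration
#'
#' @param n_tree Trees per forest.
#' @param n_balance_repeats Number of balanced down-sampling repeats over
#'   which performance is averaged.
#' @param n_permutations Label permutations for importance significance.
#' @param perm_n_tree Trees per permutation refit (reduced for feasibility;
#'   the add-one permutation p-value calibration is unaffected).
#' @param seed Master seed.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(n_tree = 500L, n_balance_repeats = 10L,
                      n_permutations = 1000L, perm_n_tree = 100L,
                      seed = 1L) {
  cfg <- list(n_tree = as.integer(n_tree),
              n_balance_repeats = as.integer(n_balance_repeats),
              n_permutations = as.integer(n_permutations),
              perm_n_tree = as.integer(perm_n_tree),
              seed = as.integer(seed))
  stopifnot(cfg$n_tree >= 1, cfg$n_balance_repeats >= 1,
            cfg$n_permutations >= 1, cfg$perm_n_tree >= 1)
  class(cfg) <- "rf_config"
  cfg
}

feature_columns <- function(m) setdiff(names(m), c("id", "label"))

check_matrix <- function(m) {
  stopifnot(is.data.frame(m), all(c("id", "label") %in% names(m)))
  if (length(feature_columns(m)) == 0L) stop("feature matrix has no features")
  if (!is.factor(m$label)) stop("label must be a factor")
  invisible(m)
}

#' Down-sample the larger class to balance a feature matrix
#'
#' @param m Feature matrix data frame (`id`, `label`, features).
#' @param seed Integer seed.
#' @return Balanced data frame (both classes at the smaller class's size).
#' @export
balance_downsample <- function(m, seed = 1L) {
  check_matrix(m)
  counts <- table(m$label)
  if (any(counts == 0)) stop("both classes must be non-empty")
  n_min <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(levels(m$label), function(lv) {
    idx <- which(m$label == lv)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  out <- m[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# area under the ROC curve from scores; midrank formula, equivalent to
# trapezoidal interpolation across tied score values
auc_score <- function(scores, labels, positive = levels(labels)[1]) {
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# ROC coordinates (FPR, TPR) from scores, one point per distinct threshold
roc_points <- function(scores, labels, positive = levels(labels)[1]) {
  ord <- order(scores, decreasing = TRUE)
  pos <- labels[ord] == positive
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  uniq <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fpr[uniq]), tpr = c(0, tpr[uniq]))
}

#' Fit one random forest and evaluate it out-of-bag
#'
#' Accuracy is `1 - OOB error`; auROC is computed from OOB class-vote
#' fractions; MDG is the per-feature mean decrease in Gini index.
#'
#' @param m Balanced feature matrix data frame.
#' @param n_tree Number of trees.
#' @param seed Integer seed.
#' @return List: `accuracy`, `auroc`, `mdg` (named), `votes`, `roc`,
#'   `model`.
#' @export
fit_forest <- function(m, n_tree = 500L, seed = 1L) {
  check_matrix(m)
  if (nlevels(droplevels(m$label)) < 2L) stop("constant class labels")
  feats <- feature_columns(m)
  x <- m[, feats, drop = FALSE]
  colnames(x) <- make.names(colnames(x))  # forest engine needs syntactic names
  y <- m$label
  m_try <- max(1L, floor(sqrt(length(feats))))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_tree,
                                   mtry = m_try)
  oob_acc <- 1 - unname(rf$err.rate[n_tree, "OOB"])
  scores <- rf$votes[, levels(y)[1]]
  mdg <- rf$importance[, "MeanDecreaseGini"]
  names(mdg) <- feats
  list(accuracy = oob_acc,
       auroc = auc_score(scores, y),
       mdg = mdg,
       votes = scores,
       roc = roc_points(scores, y),
       model = rf)
}

#' Balanced repeated evaluation
#'
#' Repeats balanced down-sampling plus a forest fit `n_balance_repeats`
#' times with derived seeds, and reports mean and SD of OOB accuracy and
#' auROC, the per-feature MDG averaged across repeats, and each feature's
#' direction: the class in which its mean value is higher, computed on the
#' full input matrix.
#'
#' @param m Feature matrix data frame (possibly unbalanced).
#' @param config An [rf_config()].
#' @return List of class `evaluation_result`.
#' @export
run_balanced_evaluation <- function(m, config = rf_config()) {
  check_matrix(m)
  set.seed(config$seed)
  seeds <- matrix(sample.int(2^31 - 1, 2L * config$n_balance_repeats),
                  ncol = 2L)
  feats <- feature_columns(m)
  acc <- numeric(config$n_balance_repeats)
  auroc <- numeric(config$n_balance_repeats)
  mdg <- matrix(0, nrow = length(feats), ncol = config$n_balance_repeats,
                dimnames = list(feats, NULL))
  for (i in seq_len(config$n_balance_repeats)) {
    bal <- balance_downsample(m, seed = seeds[i, 1L])
    fit <- fit_forest(bal, n_tree = config$n_tree, seed = seeds[i, 2L])
    acc[i] <- fit$accuracy
    auroc[i] <- fit$auroc
    mdg[, i] <- fit$mdg[feats]
  }
  pos_means <- colMeans(m[m$label == levels(m$label)[1], feats, drop = FALSE])
  neg_means <- colMeans(m[m$label == levels(m$label)[2], feats, drop = FALSE])
  res <- list(accuracy = acc, auroc = auroc,
              accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
              auroc_mean = mean(auroc), auroc_sd = stats::sd(auroc),
              mdg_mean = rowMeans(mdg), mdg = mdg,
              direction = ifelse(pos_means >= neg_means,
                                 levels(m$label)[1], levels(m$label)[2]),
              n_repeats = config$n_balance_repeats)
  class(res) <- "evaluation_result"
  res
}

#' Bonferroni adjustment
#'
#' @param p Raw p-values.
#' @param n_features Number of tests.
#' @return `min(1, p * n_features)`, element-wise.
#' @export
bonferroni_adjust <- function(p, n_features) pmin(1, p * n_features)

#' Permutation significance of MDG feature importance
#'
#' Observed MDG scores are compared to the distribution of MDG scores from
#' forests refit on label-permuted data. The add-one estimator
#' `p = (1 + #\{permuted MDG >= observed\}) / (1 + B)` is used, so p-values
#' are never zero; Bonferroni adjustment multiplies by the feature count.
#'
#' @param m Balanced feature matrix data frame.
#' @param config An [rf_config()]; `n_permutations` permutation refits use
#'   `perm_n_tree` trees each, the observed fit uses `n_tree`.
#' @return Data frame: `feature`, `mdg`, `p`, `p_adjusted`, ordered by
#'   decreasing observed MDG.
#' @export
permutation_importance <- function(m, config = rf_config()) {
  check_matrix(m)
  if (config$n_permutations < 1L) stop("n_permutations must be >= 1")
  set.seed(config$seed)
  fit_seed <- sample.int(2^31 - 1, 1L)
  perm_seeds <- sample.int(2^31 - 1, config$n_permutations)
  observed <- fit_forest(m, n_tree = config$n_tree, seed = fit_seed)$mdg
  feats <- names(observed)
  exceed <- integer(length(observed))
  names(exceed) <- feats
  m_perm <- m
  for (b in seq_len(config$n_permutations)) {
    set.seed(perm_seeds[b])
    m_perm$label <- sample(m$label)
    perm_mdg <- fit_forest(m_perm, n_tree = config$perm_n_tree,
                           seed = perm_seeds[b])$mdg
    exceed <- exceed + (perm_mdg[feats] >= observed)
  }
  p <- (1 + exceed) / (1 + config$n_permutations)
  out <- data.frame(feature = feats, mdg = unname(observed),
                    p = unname(p),
                    p_adjusted = unname(bonferroni_adjust(p, length(feats))),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mdg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Column-wise combination of two feature matrices
#'
#' Requires identical row id and label sets; columns are prefixed by source.
#'
#' @param m1,m2 Feature matrix data frames over the same rows.
#' @param prefixes Length-2 character vector of column-name prefixes.
#' @return Combined feature matrix data frame.
#' @export
combine_matrices <- function(m1, m2, prefixes = c("mod", "motif")) {
  check_matrix(m1); check_matrix(m2)
  if (!setequal(m1$id, m2$id)) {
    stop("row id sets differ between matrices")
  }
  m2 <- m2[match(m1$id, m2$id), , drop = FALSE]
  if (!identical(as.character(m1$label), as.character(m2$label))) {
    stop("row labels differ between matrices")
  }
  f1 <- m1[, feature_columns(m1), drop = FALSE]
  f2 <- m2[, feature_columns(m2), drop = FALSE]
  names(f1) <- paste0(prefixes[1], ".", names(f1))
  names(f2) <- paste0(prefixes[2], ".", names(f2))
  out <- cbind(m1[, c("id", "label")], f1, f2)
  rownames(out) <- NULL
  out
}
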