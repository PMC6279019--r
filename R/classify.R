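#' Prepare genus-level features for classification
#'
#' The fixed feature protocol: rarefy to `depth`, collapse to genus (an
#' OTU unclassified at genus keeps its highest classified level in the
#' label), drop taxa detected in fewer than `floor(rarest group size / 2)`
#' samples, convert to relative abundance and arcsin-sqrt transform.
#'
#' @param table a [count_table()].
#' @param groups named group labels (by sample id).
#' @param depth rarefaction depth (default 10,000).
#' @param seed RNG seed for the rarefaction.
#' @return list: `features` (samples x taxa transformed matrix), `groups`
#'   (aligned labels), `presence_threshold`.
#' @export
prepare_rf_features <- function(table, groups, depth = 10000, seed = NULL) {
  rt <- suppressMessages(rarefy(table, depth, seed = seed))
  groups <- groups[rt$sample_ids]
  gt <- collapse_taxonomy(rt, "genus")
  thr <- floor(min(table(as.character(groups))) / 2)
  keep <- colSums(gt$counts > 0) >= thr
  rel <- gt$values[, keep, drop = FALSE]
  list(features = asin(sqrt(pmin(rel, 1))),
       groups = groups, presence_threshold = thr)
}

#' Downsample the majority class to balance a binary training set
#'
#' @param x feature matrix, `y` two-level factor.
#' @param y class labels.
#' @return list `x`, `y` with both classes at the minority size.
#' @export
down_sample <- function(x, y) {
  y <- factor(y)
  sizes <- table(y)
  n_min <- min(sizes)
  keep <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    if (length(idx) > n_min) sample(idx, n_min) else idx
  }))
  list(x = x[keep, , drop = FALSE], y = droplevels(y[keep]))
}

#' SMOTE resampling for a binary training set
#'
#' Synthetic minority oversampling: each synthetic point interpolates
#' between a random minority sample and one of its `k` nearest minority
#' neighbours (Euclidean, in the transformed feature space), combined with
#' downsampling of the majority class.  Both classes end at
#' `min(n_majority, 2 * n_minority)`.
#'
#' @param x feature matrix.
#' @param y two-level factor.
#' @param k neighbours used for interpolation.
#' @return list `x`, `y` (balanced).
#' @export
smote_sample <- function(x, y, k = 5) {
  y <- factor(y)
  sizes <- table(y)
  min_lv <- names(which.min(sizes)); maj_lv <- names(which.max(sizes))
  if (min_lv == maj_lv) maj_lv <- setdiff(levels(y), min_lv)
  n_min <- sum(y == min_lv); n_maj <- sum(y == maj_lv)
  target <- min(n_maj, 2L * n_min)
  xmin <- x[y == min_lv, , drop = FALSE]
  n_new <- target - n_min
  synth <- NULL
  if (n_new > 0) {
    if (n_min == 1L) {
      synth <- xmin[rep(1L, n_new), , drop = FALSE]
    } else {
      kk <- min(k, n_min - 1L)
      dmat <- as.matrix(dist(xmin))
      diag(dmat) <- Inf
      nn <- t(apply(dmat, 1L, function(r) order(r)[seq_len(kk)]))
      base_i <- sample.int(n_min, n_new, replace = TRUE)
      nb_i <- vapply(base_i, function(i) nn[i, sample.int(kk, 1L)], integer(1))
      u <- runif(n_new)
      synth <- xmin[base_i, , drop = FALSE] +
        u * (xmin[nb_i, , drop = FALSE] - xmin[base_i, , drop = FALSE])
    }
    rownames(synth) <- paste0("synth_", seq_len(n_new))
  }
  maj_idx <- which(y == maj_lv)
  if (length(maj_idx) > target) maj_idx <- sample(maj_idx, target)
  xa <- rbind(x[y == min_lv, , drop = FALSE], synth,
              x[maj_idx, , drop = FALSE])
  ya <- factor(c(rep(min_lv, n_min + max(0L, n_new)),
                 rep(maj_lv, length(maj_idx))), levels = levels(y))
  list(x = xa, y = ya)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

roc_interp <- function(roc_obj, fpr_grid) {
  # sensitivity at fixed specificity grid, for fold-averaged ROC curves
  sp <- rev(roc_obj$specificities)
  se <- rev(roc_obj$sensitivities)
  fpr <- 1 - sp
  vapply(fpr_grid, function(f) max(se[fpr <= f + 1e-12], 0), numeric(1))
}

#' One-vs-all random-forest classification with resampling inside CV
#'
#' For each target group, a binary random forest distinguishes that group
#' from the pooled rest under stratified k-fold cross-validation.  Class
#' imbalance is addressed by resampling the TRAINING fold only
#' (downsampling or SMOTE); each held-out fold is evaluated untouched --
#' resampling before the split leaks synthetic neighbours across folds and
#' inflates AUC.  ROC curves are averaged across folds on a fixed
#' false-positive grid; a final model on the (resampled) full data
#' supplies the out-of-bag error and feature importances on a percent
#' scale (100 = most important feature).
#'
#' @param features samples x taxa matrix from [prepare_rf_features()] (or
#'   the list it returns).
#' @param groups named group labels (ignored if `features` is that list).
#' @param sampling `"smote"` or `"down"`.
#' @param k cross-validation folds (reduced with a warning if the target
#'   group is smaller).
#' @param seed RNG seed.
#' @param ntree trees per forest.
#' @return Object of class `rf_report`: per-group list with `auc`
#'   (fold-mean), `auc_folds`, `roc` (fpr, mean tpr), `sensitivity`,
#'   `specificity`, `precision`, `oob_error`, `importance` (percent),
#'   `sampling`, `k`.
#' @export
rf_one_vs_all <- function(features, groups = NULL,
                          sampling = c("smote", "down"), k = 10,
                          seed = NULL, ntree = 500) {
  sampling <- match.arg(sampling)
  if (is.list(features) && !is.null(features$features)) {
    groups <- features$groups
    features <- features$features
  }
  groups <- as.character(groups[rownames(features)])
  fpr_grid <- seq(0, 1, by = 0.02)
  resample <- switch(sampling, down = down_sample,
                     smote = function(x, y) smote_sample(x, y))
  out <- with_seed(seed, {
    res <- list()
    for (target in sort(unique(groups))) {
      y <- factor(ifelse(groups == target, "target", "rest"),
                  levels = c("rest", "target"))
      k_g <- k
      if (sum(y == "target") < k) {
        k_g <- max(2L, sum(y == "target"))
        warning("target group '", target, "' smaller than k; using k = ", k_g)
      }
      fold <- stratified_folds(y, k_g)
      aucs <- numeric(k_g); sens <- spec <- prec <- numeric(k_g)
      tprs <- matrix(NA_real_, k_g, length(fpr_grid))
      for (f in seq_len(k_g)) {
        tr <- fold != f; te <- fold == f
        rs <- resample(features[tr, , drop = FALSE], y[tr])
        fit <- randomForest::randomForest(rs$x, rs$y, ntree = ntree)
        prob <- predict(fit, features[te, , drop = FALSE], type = "prob")[, "target"]
        truth <- y[te]
        r <- pROC::roc(response = truth, predictor = prob, quiet = TRUE,
                       levels = c("rest", "target"), direction = "<")
        aucs[f] <- as.numeric(pROC::auc(r))
        tprs[f, ] <- roc_interp(r, fpr_grid)
        pred <- factor(ifelse(prob >= 0.5, "target", "rest"),
                       levels = c("rest", "target"))
        tp <- sum(pred == "target" & truth == "target")
        fp <- sum(pred == "target" & truth == "rest")
        fn <- sum(pred == "rest" & truth == "target")
        tn <- sum(pred == "rest" & truth == "rest")
        sens[f] <- ifelse(tp + fn > 0, tp / (tp + fn), NA)
        spec[f] <- ifelse(tn + fp > 0, tn / (tn + fp), NA)
        prec[f] <- ifelse(tp + fp > 0, tp / (tp + fp), NA)
      }
      rs_full <- resample(features, y)
      fit_full <- randomForest::randomForest(rs_full$x, rs_full$y,
                                             ntree = ntree)
      oob <- fit_full$err.rate[ntree, "OOB"]
      imp <- randomForest::importance(fit_full)[, 1]
      imp_pct <- if (max(imp) > 0) 100 * imp / max(imp) else imp
      res[[target]] <- list(auc = mean(aucs), auc_folds = aucs,
                            roc = list(fpr = fpr_grid,
                                       tpr = colMeans(tprs, na.rm = TRUE)),
                            sensitivity = mean(sens, na.rm = TRUE),
                            specificity = mean(spec, na.rm = TRUE),
                            precision = mean(prec, na.rm = TRUE),
                            oob_error = unname(oob),
                            importance = sort(imp_pct, decreasing = TRUE),
                            sampling = sampling, k = k_g)
    }
    res
  })
  structure(out, class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  for (g in names(x)) {
    cat(g, ": AUC = ", fmt_num(x[[g]]$auc),
        " (", x[[g]]$sampling, ", ", x[[g]]$k, "-fold), OOB error = ",
        fmt_num(x[[g]]$oob_error), "\n", sep = "")
  }
  invisible(x)
}
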