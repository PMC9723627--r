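#' Balance classes by down-sampling
#'
#' Subsamples the majority class without replacement to the minority class
#' size; deterministic given the seed.
#'
#' @param table feature data.frame with a `label` column.
#' @param seed integer seed.
#' @param label_col name of the label column.
#' @return the balanced data.frame (row order: original order within class).
#' @export
downsampleBalance <- function(table, seed = 1L, label_col = "label") {
  lab <- table[[label_col]]
  classes <- unique(lab)
  if (length(classes) < 2L) {
    stop("both classes must be present for down-sampling", call. = FALSE)
  }
  n_min <- min(table(lab))
  set.seed(.derive_seed(seed, 11L))
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(lab == cl)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  table[sort(keep), , drop = FALSE]
}

# label -> 0/1 with "retained" (or the alphabetically last level) as class 1
.binary_labels <- function(lab) {
  if (is.numeric(lab)) return(as.integer(lab != 0))
  if ("retained" %in% lab) as.integer(lab == "retained")
  else as.integer(lab == sort(unique(lab))[length(unique(lab))])
}

.feature_matrix <- function(table, label_col = "label") {
  drop_cols <- c(label_col, "intron_id", "cell_type", "gene_id", "sample")
  num <- vapply(table, is.numeric, logical(1))
  X <- as.matrix(table[, setdiff(names(table)[num], drop_cols), drop = FALSE])
  list(X = X, y = .binary_labels(table[[label_col]]))
}

.stratified_folds <- function(y, k, seed) {
  set.seed(.derive_seed(seed, 12L))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' ROC / PR evaluation of classifier scores
#'
#' ROC by threshold sweep over the unique scores with trapezoidal AUC
#' (tied scores grouped, equivalent to the rank statistic with averaged
#' ranks); precision-recall curve with step-interpolated area; confusion
#' matrix at a 0.5 score threshold.
#'
#' @param scores numeric class-1 scores.
#' @param labels 0/1 (or `"retained"`/`"non_retained"`) labels.
#' @return list: `roc` (data.frame fpr/tpr/threshold), `auc`, `pr`
#'   (data.frame recall/precision), `pr_auc`, `confusion`. AUCs are `NA` for
#'   single-class inputs.
#' @export
evaluateScores <- function(scores, labels) {
  y <- .binary_labels(labels)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) {
    return(list(roc = NULL, auc = NA_real_, pr = NULL, pr_auc = NA_real_,
                confusion = table(predicted = scores > 0.5, truth = y)))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp_last <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(yy)[grp_last]; fp <- cumsum(1 - yy)[grp_last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp); rec <- tp / P
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[grp_last])),
       auc = auc,
       pr = data.frame(recall = rec, precision = prec),
       pr_auc = pr_auc,
       confusion = table(predicted = factor(scores > 0.5, c(FALSE, TRUE)),
                         truth = y))
}

#' Evaluate a fitted model on a held-out table
#'
#' @param fit an [IRModelFit-class].
#' @param table held-out feature data.frame with labels.
#' @return see [evaluateScores()].
#' @export
evaluateModel <- function(fit, table) {
  fm <- .feature_matrix(table)
  evaluateScores(predictScores(fit, newdata = fm$X), fm$y)
}

#' Fit an elastic-net logistic IR classifier
#'
#' Penalized logistic regression over a grid of mixing values alpha in
#' {0.1, 0.55, 1.0} by 50 lambdas, selected by mean cross-validated ROC AUC
#' over stratified 10-fold CV (equal penalty factor on all features;
#' standardization happens inside each training fold), then refitted on all
#' data at the chosen pair. Constant features are dropped with a warning.
#'
#' @param table balanced feature data.frame with a `label` column.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param alphas mixing grid.
#' @return an [IRModelFit-class] of kind `"EN"`.
#' @export
fitElasticNet <- function(table, folds = 10L, seed = 1L,
                          alphas = c(0.1, 0.55, 1.0)) {
  fm <- .feature_matrix(table)
  X <- fm$X; y <- fm$y
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant features: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  foldid <- .stratified_folds(y, folds, seed)
  best <- NULL
  for (a in alphas) {
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial",
                               type.measure = "auc", foldid = foldid,
                               alpha = a, nlambda = 50, standardize = TRUE)
    i <- which.max(cvfit$cvm)
    if (is.null(best) || cvfit$cvm[i] > best$cvm) {
      best <- list(alpha = a, lambda = cvfit$lambda[i], cvm = cvfit$cvm[i],
                   cvfit = cvfit)
    }
  }
  final <- glmnet::glmnet(X, y, family = "binomial", alpha = best$alpha,
                          standardize = TRUE)
  beta <- as.numeric(glmnet::coef.glmnet(final, s = best$lambda))
  names(beta) <- c("(Intercept)", colnames(X))
  beta_std <- beta[-1] * sds  # coefficients on the standardized scale
  imp <- abs(beta_std)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  new("IRModelFit", kind = "EN",
      fit = list(glmnet = final, lambda = best$lambda,
                 beta = beta, beta_std = beta_std,
                 features = colnames(X)),
      hyperparameters = list(alpha = best$alpha, lambda = best$lambda),
      importance = imp, feature_names = colnames(X),
      training_label = "", cv_auc = best$cvm, seed = as.integer(seed))
}

#' Scaled variable importance of an elastic-net fit
#'
#' Importances are the absolute standardized coefficients scaled to sum to 1
#' (all-zero coefficient vectors give an all-zero, flagged ranking).
#'
#' @param fit an [IRModelFit-class] of kind `"EN"`.
#' @return named numeric vector ordered by decreasing importance (ties kept
#'   in registry order).
#' @export
rankFeaturesEN <- function(fit) {
  stopifnot(modelKind(fit) == "EN")
  imp <- fit@importance
  if (sum(imp) == 0) {
    warning("all coefficients are zero; ranking is uninformative")
    return(imp)
  }
  imp[order(-imp)]
}

# association p-value between a node's labels and one feature
.assoc_pvalue <- function(x, y, is_cat) {
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) return(1)
  if (is_cat) {
    lv <- sort(unique(x))
    if (length(lv) < 2L) return(1)
    tab <- table(factor(x, lv), y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    return(pchisq(stat, df = (nrow(tab) - 1L), lower.tail = FALSE))
  }
  v <- var(x)
  if (!is.finite(v) || v == 0) return(1)
  d <- mean(x[y == 1L]) - mean(x[y == 0L])
  z <- d / sqrt(v * (1 / n1 + 1 / n0))
  2 * pnorm(-abs(z))
}

# best cutpoint of the winning feature: maximal standardized two-sample
# difference in label means, >= 7 observations per side
.best_cut <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (head(ux, -1) + tail(ux, -1)) / 2
  if (length(cuts) > 30L) {
    cuts <- unique(quantile(x, probs = seq(0.03, 0.97, length.out = 30),
                            type = 1))
    cuts <- cuts[cuts < max(x)]
  }
  best <- NULL; best_stat <- -Inf
  for (cu in cuts) {
    l <- x <= cu
    nl <- sum(l); nr <- length(x) - nl
    if (nl < 7L || nr < 7L) next
    stat <- abs(mean(y[l]) - mean(y[!l])) * sqrt(nl * nr)
    if (stat > best_stat) { best_stat <- stat; best <- cu }
  }
  best
}

.grow_tree <- function(X, y, idx, mtry, split_alpha, min_node, is_cat,
                       max_depth = 30L) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = 0L, cut = NA_real_,
                                         left = 0L, right = 0L,
                                         pred = NA_real_)
    length(nodes)
  }
  build <- function(idx, depth) {
    id <- new_node()
    yy <- y[idx]
    leaf <- function() {
      nodes[[id]]$pred <<- mean(yy)
      id
    }
    if (length(idx) < min_node || depth >= max_depth ||
        length(unique(yy)) < 2L) {
      return(leaf())
    }
    cand <- sample.int(ncol(X), mtry)
    pv <- vapply(cand, function(f) {
      .assoc_pvalue(X[idx, f], yy, is_cat[f])
    }, numeric(1))
    if (min(pv) * mtry > split_alpha) return(leaf())
    winner <- cand[which.min(pv)]
    cu <- .best_cut(X[idx, winner], yy)
    if (is.null(cu)) return(leaf())
    l <- X[idx, winner] <= cu
    if (sum(l) < 7L || sum(!l) < 7L) return(leaf())
    nodes[[id]]$feature <<- winner
    nodes[[id]]$cut <<- cu
    nodes[[id]]$left <<- build(idx[l], depth + 1L)
    nodes[[id]]$right <<- build(idx[!l], depth + 1L)
    id
  }
  build(idx, 0L)
  mat <- do.call(rbind, lapply(nodes, function(nd) {
    c(nd$feature, nd$cut, nd$left, nd$right, nd$pred)
  }))
  colnames(mat) <- c("feature", "cut", "left", "right", "pred")
  mat
}

.predict_tree <- function(tree, X) {
  n <- nrow(X)
  pred <- numeric(n)
  node <- rep(1L, n)
  active <- seq_len(n)
  while (length(active)) {
    nd <- node[active]
    leaf <- tree[nd, "feature"] == 0
    if (any(leaf)) {
      pred[active[leaf]] <- tree[nd[leaf], "pred"]
      active <- active[!leaf]
      nd <- nd[!leaf]
    }
    if (length(active)) {
      xv <- X[cbind(active, tree[nd, "feature"])]
      node[active] <- ifelse(xv <= tree[nd, "cut"],
                             tree[nd, "left"], tree[nd, "right"])
    }
  }
  pred
}

#' Fit a conditional-inference random forest
#'
#' Trees are grown on 0.632 subsamples drawn without replacement. At each
#' node, `mtry` candidate features are screened by an association test with
#' the node's labels (standardized mean-difference with a normal
#' approximation for continuous features, chi-square for integer-coded
#' features with few levels); the smallest Bonferroni-adjusted p-value picks
#' the split variable, the cutpoint maximizes the standardized two-sample
#' difference, and the node becomes a leaf when the adjusted p exceeds
#' `split_alpha` or fewer than `min_node` observations remain.
#'
#' @param table balanced feature data.frame with a `label` column.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate features per node (default `ceiling(sqrt(p))`).
#' @param split_alpha stopping threshold on the Bonferroni-adjusted
#'   association p-value (default 0.05).
#' @param min_node minimum node size to attempt a split (default 20).
#' @param seed integer seed; the same seed reproduces the forest exactly.
#' @return an [IRModelFit-class] of kind `"cRF"`; out-of-bag rows per tree
#'   are stored for permutation importance.
#' @export
fitConditionalForest <- function(table, n_trees = 500L, mtry = NULL,
                                 split_alpha = 0.05, min_node = 20L,
                                 seed = 1L) {
  fm <- .feature_matrix(table)
  X <- fm$X; y <- fm$y
  n <- nrow(X); p <- ncol(X)
  if (n < 20L) stop("at least 20 observations are required", call. = FALSE)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  is_cat <- apply(X, 2, function(v) {
    u <- unique(v)
    length(u) <= 4L && all(u == floor(u))
  })
  set.seed(.derive_seed(seed, 13L))
  n_sub <- floor(0.632 * n)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n_sub)
    trees[[b]] <- .grow_tree(X, y, idx, mtry, split_alpha, min_node, is_cat)
    oob[[b]] <- setdiff(seq_len(n), idx)
  }
  oob_score <- numeric(n); oob_cnt <- integer(n)
  for (b in seq_len(n_trees)) {
    o <- oob[[b]]
    oob_score[o] <- oob_score[o] + .predict_tree(trees[[b]], X[o, , drop = FALSE])
    oob_cnt[o] <- oob_cnt[o] + 1L
  }
  has <- oob_cnt > 0L
  oob_auc <- evaluateScores(oob_score[has] / oob_cnt[has], y[has])$auc
  fit <- new("IRModelFit", kind = "cRF",
             fit = list(trees = trees, oob = oob, X = X, y = y,
                        is_cat = is_cat),
             hyperparameters = list(n_trees = as.integer(n_trees),
                                    mtry = as.integer(mtry),
                                    split_alpha = split_alpha,
                                    min_node = as.integer(min_node)),
             importance = numeric(0), feature_names = colnames(X),
             training_label = "", cv_auc = oob_auc,
             seed = as.integer(seed))
  fit@importance <- permutationImportance(fit)
  fit
}

#' @describeIn predictScores average leaf class-1 fraction over trees (cRF)
#'   or the logistic response (EN).
#' @param newdata numeric feature matrix or data.frame with the training
#'   feature columns.
#' @export
setMethod("predictScores", "IRModelFit", function(object, newdata) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object@feature_names, drop = FALSE])
  } else {
    newdata <- newdata[, object@feature_names, drop = FALSE]
  }
  if (object@kind == "EN") {
    as.numeric(stats::predict(object@fit$glmnet, newx = newdata,
                              s = object@fit$lambda, type = "response"))
  } else {
    sc <- numeric(nrow(newdata))
    for (tr in object@fit$trees) sc <- sc + .predict_tree(tr, newdata)
    sc / length(object@fit$trees)
  }
})

#' Permutation variable importance of a conditional forest
#'
#' For each tree, out-of-bag accuracy (at a 0.5 threshold) minus the accuracy
#' after permuting one feature's out-of-bag values, averaged over trees;
#' features a tree never splits on contribute an exact zero for that tree.
#' Negative means are clipped to 0 and the vector is scaled to sum to 1.
#'
#' @param fit an [IRModelFit-class] of kind `"cRF"`.
#' @param seed seed for the permutations (default: the fit's seed).
#' @return named numeric importances summing to 1 (or all zero).
#' @export
permutationImportance <- function(fit, seed = NULL) {
  stopifnot(modelKind(fit) == "cRF")
  f <- fit@fit
  X <- f$X; y <- f$y
  p <- ncol(X)
  n_trees <- length(f$trees)
  if (is.null(seed)) seed <- fit@seed
  set.seed(.derive_seed(seed, 14L))
  drop_sum <- numeric(p)
  for (b in seq_len(n_trees)) {
    tr <- f$trees[[b]]
    o <- f$oob[[b]]
    if (!length(o)) next
    Xo <- X[o, , drop = FALSE]
    base_acc <- mean((.predict_tree(tr, Xo) > 0.5) == y[o])
    used <- unique(tr[tr[, "feature"] > 0, "feature"])
    for (fe in used) {
      Xp <- Xo
      Xp[, fe] <- Xp[sample.int(length(o)), fe]
      acc <- mean((.predict_tree(tr, Xp) > 0.5) == y[o])
      drop_sum[fe] <- drop_sum[fe] + (base_acc - acc)
    }
  }
  imp <- pmax(drop_sum / n_trees, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(X)
  imp
}

#' Cross-cell-type generalization matrix
#'
#' Trains on each cell type's (down-sampled) table and evaluates on every
#' other cell type; the diagonal holds the within-type cross-validated AUC
#' (EN: CV AUC at the selected hyperparameters; cRF: stratified k-fold CV).
#'
#' @param tables named list of feature data.frames, one per cell type.
#' @param kind `"EN"` or `"cRF"`.
#' @param seed integer seed.
#' @param folds folds for the diagonal CV.
#' @param n_trees forest size for `kind = "cRF"`.
#' @return k x k numeric AUC matrix (rows = training cell type).
#' @export
crossCellTypeEval <- function(tables, kind = c("EN", "cRF"), seed = 1L,
                              folds = 10L, n_trees = 200L) {
  kind <- match.arg(kind)
  k <- length(tables)
  cts <- names(tables)
  out <- matrix(NA_real_, k, k, dimnames = list(train = cts, test = cts))
  for (i in seq_len(k)) {
    bal <- downsampleBalance(tables[[i]], seed = seed)
    fit <- if (kind == "EN") fitElasticNet(bal, seed = seed)
           else fitConditionalForest(bal, n_trees = n_trees, seed = seed)
    for (j in seq_len(k)) {
      if (j == i) next
      out[i, j] <- evaluateModel(fit, tables[[j]])$auc
    }
    out[i, i] <- if (kind == "EN") fit@cv_auc
                 else .crf_cv_auc(bal, folds, n_trees, seed)
  }
  out
}

.crf_cv_auc <- function(table, folds, n_trees, seed) {
  fm <- .feature_matrix(table)
  fold <- .stratified_folds(fm$y, folds, .derive_seed(seed, 15L))
  scores <- numeric(length(fm$y))
  for (f in seq_len(folds)) {
    tr_idx <- which(fold != f)
    fit <- fitConditionalForest(table[tr_idx, , drop = FALSE],
                                n_trees = n_trees, seed = seed)
    scores[fold == f] <-
      predictScores(fit, newdata = fm$X[fold == f, , drop = FALSE])
  }
  evaluateScores(scores, fm$y)$auc
}

#' Classify dynamic introns from their two retention states
#'
#' Restricts the pooled feature table to dynamic introns (each contributing
#' its retained-state and non-retained-state rows from the respective cell
#' types), balances the classes, and fits both classifiers with scaled
#' importance rankings.
#'
#' @param feature_tables pooled feature data.frame across cell types.
#' @param dynamic_ids character vector of dynamic intron ids.
#' @param seed integer seed.
#' @param n_trees forest size.
#' @return list: `table` (the dynamic-intron rows), `en`, `crf`
#'   ([IRModelFit-class]), `en_ranking`, `crf_ranking`.
#' @export
dynamicIRExperiment <- function(feature_tables, dynamic_ids, seed = 1L,
                                n_trees = 300L) {
  if (!length(dynamic_ids)) stop("empty dynamic intron set", call. = FALSE)
  tab <- feature_tables[feature_tables$intron_id %in% dynamic_ids, ,
                        drop = FALSE]
  if (nrow(tab) < 50L) {
    stop("fewer than 50 dynamic-intron rows: underpowered", call. = FALSE)
  }
  bal <- downsampleBalance(tab, seed = seed)
  en <- fitElasticNet(bal, seed = seed)
  crf <- fitConditionalForest(bal, n_trees = n_trees, seed = seed)
  list(table = tab, en = en, crf = crf,
       en_ranking = sort(en@importance, decreasing = TRUE),
       crf_ranking = sort(crf@importance, decreasing = TRUE))
}

#' Expression-stratified dynamic-intron experiment
#'
#' Assigns each dynamic intron the host-gene log2 FPKM fold change between a
#' retained-state and a non-retained-state cell type, splits into down
#' (log2FC < -2), stable (|log2FC| <= 2) and up (log2FC > 2) strata, and
#' reruns the conditional-forest experiment on the stable stratum.
#'
#' @param feature_tables pooled feature data.frame across cell types (rows
#'   carry `intron_id`, `cell_type`, `label`).
#' @param expression data.frame gene_id, sample, fpkm.
#' @param intron_genes named character: gene id per intron id.
#' @param seed,n_trees model settings.
#' @return list: `strata` (per intron), `crf`, `crf_ranking` (NULL when the
#'   stable stratum is too small).
#' @export
expressionStratifiedExperiment <- function(feature_tables, expression,
                                           intron_genes, seed = 1L,
                                           n_trees = 300L) {
  ids <- unique(feature_tables$intron_id)
  strat <- setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    rows <- feature_tables[feature_tables$intron_id == id, , drop = FALSE]
    ret_ct <- rows$cell_type[rows$label == "retained"][1]
    non_ct <- rows$cell_type[rows$label == "non_retained"][1]
    if (is.na(ret_ct) || is.na(non_ct)) next
    g <- intron_genes[[id]]
    f_r <- expression$fpkm[expression$gene_id == g &
                             expression$sample == ret_ct][1]
    f_n <- expression$fpkm[expression$gene_id == g &
                             expression$sample == non_ct][1]
    if (is.na(f_r) || is.na(f_n)) next
    lfc <- log2(f_r / f_n)
    strat[id] <- if (abs(lfc) <= 2) "stable" else if (lfc > 2) "up" else "down"
  }
  stable_ids <- names(strat)[!is.na(strat) & strat == "stable"]
  res <- list(strata = strat, crf = NULL, crf_ranking = NULL)
  tab <- feature_tables[feature_tables$intron_id %in% stable_ids, ,
                        drop = FALSE]
  if (nrow(tab) >= 50L && length(unique(tab$label)) == 2L) {
    bal <- downsampleBalance(tab, seed = seed)
    res$crf <- fitConditionalForest(bal, n_trees = n_trees, seed = seed)
    res$crf_ranking <- sort(res$crf@importance, decreasing = TRUE)
  }
  res
}
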