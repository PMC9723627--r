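test_that("down-sampling balances classes deterministically", {
  tab <- data.frame(label = rep(c("retained", "non_retained"), c(100, 900)),
                    x = rnorm(1000))
  bal <- downsampleBalance(tab, seed = 1)
  expect_equal(unname(table(bal$label)), c(100L, 100L), ignore_attr = TRUE)
  expect_identical(bal, downsampleBalance(tab, seed = 1))
  even <- tab[1:200, ]
  expect_equal(nrow(downsampleBalance(even, seed = 1)), 200)
  expect_error(downsampleBalance(tab[1:100, ], seed = 1), "both classes")
})

test_that("ROC/PR evaluation matches pROC and obeys symmetry", {
  set.seed(31)
  y <- rbinom(400, 1, 0.5)
  s <- y * 0.5 + rnorm(400)
  ev <- evaluateScores(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ev$auc, ref, tolerance = 1e-10)
  expect_equal(evaluateScores(-s, y)$auc, 1 - ev$auc, tolerance = 1e-10)
  perfect <- evaluateScores(y + 0.0, y)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$pr_auc, 1)
  # tied scores are handled by rank averaging
  st <- round(s, 1)
  reft <- as.numeric(pROC::auc(pROC::roc(y, st, quiet = TRUE,
                                         direction = "<")))
  expect_equal(evaluateScores(st, y)$auc, reft, tolerance = 1e-10)
  expect_true(is.na(evaluateScores(s, rep(1, 400))$auc))
})

test_that("elastic net selects planted effects and shrinks noise", {
  beta <- c(2, -2, 1.5, rep(0, 17))
  tab <- make_logistic_table(800, 20, beta, seed = 41)
  bal <- downsampleBalance(tab, seed = 1)
  fit <- fitElasticNet(bal, seed = 1)
  top3 <- names(sort(fit@importance, decreasing = TRUE))[1:3]
  expect_setequal(top3, c("f01", "f02", "f03"))
  expect_equal(sign(fit@fit$beta_std[c("f01", "f02", "f03")]),
               c(f01 = 1, f02 = -1, f03 = 1))
  expect_equal(sum(fit@importance), 1, tolerance = 1e-9)
  # a perfectly separable single feature dominates the ranking
  sep <- data.frame(label = rep(c("retained", "non_retained"), each = 100),
                    f1 = rep(c(2, -2), each = 100) + rnorm(200, 0, 0.1),
                    f2 = rnorm(200), f3 = rnorm(200))
  fsep <- fitElasticNet(sep, seed = 1)
  expect_equal(names(which.max(fsep@importance)), "f1")
  expect_gt(fsep@importance["f1"], 0.9)
  # constant features are dropped with a warning
  sep$f4 <- 1
  expect_warning(fitElasticNet(sep, seed = 1), "constant")
})

test_that("elastic-net rankings scale to 1 and are scale-invariant", {
  tab <- make_logistic_table(400, 10, c(2, rep(0, 9)), seed = 42)
  fit <- fitElasticNet(tab, seed = 1)
  r <- rankFeaturesEN(fit)
  expect_equal(sum(r), 1, tolerance = 1e-9)
  expect_true(all(diff(r) <= 1e-12))
  b <- c(2, -1, 0); names(b) <- c("a", "b", "c")
  expect_equal(abs(b) / sum(abs(b)), c(a = 2 / 3, b = 1 / 3, c = 0))
})

test_that("label permutation drives cross-validated AUC to chance", {
  tab <- make_logistic_table(600, 15, c(2, -2, rep(0, 13)), seed = 43)
  set.seed(7)
  tab$label <- sample(tab$label)
  fit <- fitElasticNet(tab, seed = 1)
  expect_gte(fit@cv_auc, 0.44)
  expect_lte(fit@cv_auc, 0.58)
})

test_that("the conditional forest splits on the associated feature first", {
  set.seed(51)
  n <- 400
  y <- rep(0:1, each = n / 2)
  X <- cbind(sep = ifelse(y == 1, 1, 0),
             matrix(rnorm(n * 19), n, 19,
                    dimnames = list(NULL, paste0("z", 1:19))))
  tab <- data.frame(label = ifelse(y == 1, "retained", "non_retained"), X)
  # with all features as candidates the association screen must pick the
  # separator at the root essentially always
  fit <- fitConditionalForest(tab, n_trees = 60, mtry = ncol(X), seed = 3)
  roots <- vapply(fit@fit$trees, function(tr) tr[1, "feature"], numeric(1))
  expect_gte(mean(roots == 1), 0.95)
  # pure node: single-class table refuses informatively (one class only)
  expect_error(fitConditionalForest(tab[y == 1, ][1:30, ], n_trees = 5,
                                    seed = 1), NA)
  # determinism
  fit2 <- fitConditionalForest(tab, n_trees = 60, mtry = ncol(X), seed = 3)
  Xm <- as.matrix(X)
  expect_identical(predictScores(fit, newdata = Xm),
                   predictScores(fit2, newdata = Xm))
})

test_that("permutation importance isolates informative features", {
  tab <- make_logistic_table(600, 10, c(3, rep(0, 9)), seed = 52)
  fit <- fitConditionalForest(tab, n_trees = 100, seed = 2)
  imp <- fit@importance
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_gt(imp["f01"], 0.7)
  expect_true(all(imp[-1] < 0.1))
  expect_true(all(imp >= 0))
})

test_that("cross-cell-type evaluation generalizes under shared effects", {
  beta <- c(2, -2, rep(0, 8))
  tabs <- list(A = make_logistic_table(400, 10, beta, seed = 61),
               B = make_logistic_table(400, 10, beta, seed = 62))
  m <- crossCellTypeEval(tabs, "EN", seed = 1, folds = 5)
  expect_equal(dim(m), c(2, 2))
  expect_true(all(is.finite(m)))
  expect_lt(abs(m["A", "B"] - m["A", "A"]), 0.08)
})

test_that("the dynamic-intron experiment restricts rows and guards power", {
  tab <- make_logistic_table(300, 8, c(2, rep(0, 7)), seed = 71)
  tab$intron_id <- sprintf("i%03d", rep(1:150, 2))
  tab$cell_type <- rep(c("Mo", "Ma"), each = 150)
  res <- dynamicIRExperiment(tab, sprintf("i%03d", 1:150), seed = 1,
                             n_trees = 50)
  expect_s4_class(res$en, "IRModelFit")
  expect_s4_class(res$crf, "IRModelFit")
  expect_true(all(res$table$intron_id %in% sprintf("i%03d", 1:150)))
  expect_error(dynamicIRExperiment(tab, character(0)), "empty")
  expect_error(dynamicIRExperiment(tab, "i001"), "underpowered")
})

test_that("expression stratification splits dynamic hosts by log2 fold change", {
  tab <- data.frame(label = rep(c("retained", "non_retained"), 60),
                    intron_id = rep(sprintf("i%02d", 1:60), each = 2),
                    cell_type = rep(c("Mo", "Ma"), 60),
                    f1 = rnorm(120), f2 = rnorm(120))
  genes <- setNames(rep(c("gS", "gU", "gD"), each = 20)[1:60],
                    sprintf("i%02d", 1:60))
  expr <- data.frame(
    gene_id = rep(c("gS", "gU", "gD"), each = 2),
    sample = rep(c("Mo", "Ma"), 3),
    fpkm = c(10, 10 * 2^2, 10, 10 / 2^3, 10, 10 * 2^3))
  res <- expressionStratifiedExperiment(tab, expr, genes, seed = 1,
                                        n_trees = 30)
  st <- res$strata
  expect_equal(unname(st["i01"]), "stable") # |log2FC| = 2 is stable
  expect_equal(unname(st["i21"]), "up")     # retained state 2^3 higher
  expect_equal(unname(st["i41"]), "down")
})
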