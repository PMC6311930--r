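test_that("stratified folds are balanced, exhaustive and deterministic", {
  y <- rep(c(0L, 1L), each = 5L)
  f <- split_folds(y, k = 5, seed = 42)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.numeric(table(f)), rep(2, 5))
  # every fold carries both classes
  expect_true(all(tapply(y, f, function(v) length(unique(v))) == 2))
  expect_identical(f, split_folds(y, k = 5, seed = 42))
  expect_false(identical(f, split_folds(y, k = 5, seed = 43)))

  # 11 samples in 5 folds -> sizes 3,2,2,2,2
  y11 <- c(rep(1L, 6), rep(0L, 5))
  f11 <- split_folds(y11, k = 5, seed = 1)
  expect_equal(sort(as.numeric(table(f11)), decreasing = TRUE),
               c(3, 2, 2, 2, 2))
  expect_error(split_folds(y11, k = 12, seed = 1), "exceeds")
})

test_that("PCA projection matches an independent eigen-decomposition", {
  set.seed(5)
  X <- matrix(rbinom(50 * 20, 1, 0.3), 50, 20)
  rs <- fit_reduce(X, pcn = 5)
  Z <- predict(rs, X)
  expect_equal(ncol(Z), 5L)
  # retained variance equals the top-5 eigenvalues of the covariance
  ev <- sort(eigen(stats::cov(X), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(as.numeric(apply(Z, 2, stats::var)), ev[1:5],
               tolerance = 1e-8)

  # full-rank projection is lossless
  rsf <- fit_reduce(X, pcn = 20)
  Zf <- predict(rsf, X)
  recon <- Zf %*% t(rsf$rotation) +
    matrix(rs$center, 50, 20, byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fit_reduce(X, pcn = 21), "dimension error")
})

test_that("classifiers separate a separable toy set and are deterministic", {
  set.seed(9)
  n <- 40
  X <- rbind(matrix(rnorm(n, -3, 0.3), n / 2, 2),
             matrix(rnorm(n, 3, 0.3), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  for (algo in c("svm", "logreg", "knn", "rf")) {
    clf <- train_classifier(X, y, algo, seed = 7)
    pr <- predict(clf, X)
    expect_equal(pr$label, y, info = algo)
    # scores orient toward the positive class
    expect_gt(min(pr$score[y == 1]), max(pr$score[y == 0]))
    clf2 <- train_classifier(X, y, algo, seed = 7)
    expect_equal(predict(clf2, X), pr, info = algo)
  }
  expect_error(train_classifier(X, rep(1L, n), "svm"),
               "single class")
})

test_that("logistic regression recovers planted linear signal", {
  fx <- synth_generate(synth_config(seed = 21))
  obj <- fixture_objects(fx)
  ranked <- rank_pairs(obj$network, obj$catalog$drugs)
  rep <- run_pipeline(obj$catalog, obj$network, obj$ddaa,
                      list(pcn = 10, seed = 21, algo = "logreg"), ranked)
  expect_gt(rep$macro[["auc"]], 0.9)
})

test_that("evaluation matches hand-computed confusion arithmetic", {
  # 8 samples: TP=2 FP=1 FN=2 TN=3
  preds <- data.frame(adr_id = "a1",
                      truth = c(1, 1, 1, 1, 0, 0, 0, 0),
                      label = c(1, 1, 0, 0, 1, 0, 0, 0),
                      score = c(0.9, 0.8, 0.4, 0.3, 0.7, 0.2, 0.1, 0.05))
  rep <- evaluate(preds)
  expect_equal(rep$per_adr$precision, 2 / 3)
  expect_equal(rep$per_adr$recall, 2 / 4)
  expect_equal(rep$per_adr$accuracy, 5 / 8)
  expect_equal(rep$per_adr$f1, 2 * (2 / 3) * (1 / 2) / (2 / 3 + 1 / 2))

  perfect <- transform(preds, label = truth, score = truth)
  expect_true(all(evaluate(perfect)$macro == 1))

  flat <- transform(preds, score = 0.5)
  expect_equal(evaluate(flat)$per_adr$auc, 0.5)

  # macro metrics are unweighted means over ADRs
  two <- rbind(preds, transform(perfect, adr_id = "a2"))
  r2 <- evaluate(two)
  expect_equal(r2$macro[["f1"]], mean(r2$per_adr$f1), tolerance = 1e-12)
  expect_equal(r2$macro[["auc"]], mean(r2$per_adr$auc), tolerance = 1e-12)

  # single-class truth: AUC reported missing, excluded from macro
  one_cls <- data.frame(adr_id = "a3", truth = 1, label = 1, score = 1)
  expect_warning(r3 <- evaluate(rbind(preds, one_cls)), "AUC undefined")
  expect_true(is.na(r3$per_adr$auc[r3$per_adr$adr_id == "a3"]))
  expect_equal(r3$macro[["auc"]],
               r3$per_adr$auc[r3$per_adr$adr_id == "a1"])
})

test_that("pipeline honours nsr, min_positives and reruns identically", {
  fx <- synth_generate(synth_config(seed = 13))
  obj <- fixture_objects(fx)
  ranked <- rank_pairs(obj$network, obj$catalog$drugs)
  cfg <- list(pcn = 8, seed = 13, nsr = 1)
  r1 <- run_pipeline(obj$catalog, obj$network, obj$ddaa, cfg, ranked)
  expect_equal(nrow(r1$per_adr), 3L)
  # nsr = 1 -> per-ADR sample count is twice the positive count
  expect_equal(unique(r1$per_adr$n), 20L)
  r2 <- run_pipeline(obj$catalog, obj$network, obj$ddaa, cfg, ranked)
  expect_identical(r1$per_adr, r2$per_adr)
  expect_identical(r1$macro, r2$macro)
  expect_error(
    run_pipeline(obj$catalog, obj$network, obj$ddaa,
                 list(min_positives = 1000), ranked),
    "empty report")
})

test_that("PCA inside the pipeline never sees the test fold", {
  fx <- synth_generate(synth_config(seed = 6))
  obj <- fixture_objects(fx)
  ranked <- rank_pairs(obj$network, obj$catalog$drugs)
  adr <- names(which(table(obj$ddaa$adr_id) >= 10))[1]
  ds <- hcnsadr:::adr_dataset(adr, obj$ddaa, ranked, 1, "hcns", seed = 1)
  X <- build_pair_matrix(obj$catalog, ds$pairs)
  seed <- 31
  folds <- split_folds(ds$labels, 5, seed)
  cv <- hcnsadr:::cv_predict(X, ds$labels, 8, "logreg", 5, seed)
  expect_identical(cv$folds, folds)
  # refitting the space on train-only rows reproduces the fold scores
  f <- 1L
  tr <- folds != f
  rs <- fit_reduce(as.matrix(X[tr, ]), min(8, sum(tr)))
  clf <- train_classifier(predict(rs, as.matrix(X[tr, ])),
                          ds$labels[tr], "logreg",
                          seed = hcnsadr:::derive_seed(seed, "fold1"))
  pr <- predict(clf, predict(rs, as.matrix(X[!tr, ])))
  expect_equal(cv$score[!tr], pr$score, tolerance = 1e-10)
})

test_that("per-pair ADR ranking is ordered and planted signal wins", {
  fx <- synth_generate(synth_config(seed = 17))
  obj <- fixture_objects(fx)
  ranked <- rank_pairs(obj$network, obj$catalog$drugs)
  rep <- run_pipeline(obj$catalog, obj$network, obj$ddaa,
                      list(pcn = 8, seed = 17, algo = "logreg"), ranked,
                      fit_models = TRUE)
  # a pair positive for exactly one ADR ranks that ADR first
  counts <- table(paste(obj$ddaa$drug_a, obj$ddaa$drug_b))
  solo <- names(counts)[counts == 1][1]
  skip_if(is.na(solo), "no single-ADR pair in fixture")
  pr <- strsplit(solo, " ")[[1]]
  truth_adr <- obj$ddaa$adr_id[obj$ddaa$drug_a == pr[1] &
                                 obj$ddaa$drug_b == pr[2]]
  out <- predict_adrs(obj$catalog, rep$models, pr[1], pr[2])
  expect_equal(out$adr_id[1], truth_adr)
  expect_true(all(diff(out$score) <= 0))
  # top-k clips to the model count
  expect_equal(nrow(predict_adrs(obj$catalog, rep$models, pr[1], pr[2],
                                 top = 100)), 3L)
})

test_that("macro-F1 does not degrade with full-rank PCA vs pcn = 2", {
  deltas <- sapply(1:5, function(s) {
    fx <- synth_generate(synth_config(seed = s))
    obj <- fixture_objects(fx)
    ranked <- rank_pairs(obj$network, obj$catalog$drugs)
    lo <- run_pipeline(obj$catalog, obj$network, obj$ddaa,
                       list(pcn = 2, seed = s, algo = "logreg"), ranked)
    hi <- run_pipeline(obj$catalog, obj$network, obj$ddaa,
                       list(pcn = 1000, seed = s, algo = "logreg"),
                       ranked)
    hi$macro[["f1"]] - lo$macro[["f1"]]
  })
  expect_gte(mean(deltas), 0)
})
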