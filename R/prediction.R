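## Per-ADR binary classification on PCA-reduced pair vectors.

## Deterministic fan-out of one top-level seed to named sub-streams
## (folds, ADRs, repeats, classifiers); keeps every derived seed a valid
## 32-bit integer.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

#' Stratified cross-validation fold assignment
#'
#' Splits samples into `k` near-equal folds, stratified by label so that
#' each fold carries both classes whenever possible (small per-ADR
#' datasets would otherwise risk single-class test folds and undefined
#' AUC). Within each class the order is shuffled deterministically from
#' the seed and folds are filled round-robin, continuing the rotation
#' across classes so overall fold sizes differ by at most one.
#'
#' @param labels Vector of 0/1 labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1:k`, one per sample.
#' @export
split_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds sample count ", n, call. = FALSE)
  fold <- integer(n)
  counter <- 0L
  rng <- local({
    set.seed(derive_seed(seed, "folds"))
    function(idx) sample(idx)
  })
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- if (length(idx) > 1L) rng(idx) else idx
    fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' Fit a PCA projection on training pair vectors
#'
#' Centers the training matrix and extracts the leading `pcn` principal
#' directions by singular value decomposition. Only training rows may be
#' used for the fit; test rows are later projected with the stored center
#' and loadings, so no information leaks from the test fold.
#'
#' @param x Numeric matrix (dense or sparse) of training pair vectors.
#' @param pcn Number of components to retain; must not exceed
#'   `min(nrow(x), ncol(x))`.
#' @return Object of class `reduced_space` with `center`, `rotation`
#'   (columns = components) and `pcn`.
#' @export
fit_reduce <- function(x, pcn) {
  x <- as.matrix(x)
  if (pcn > min(dim(x))) {
    stop("dimension error: pcn = ", pcn, " exceeds min(rows, cols) = ",
         min(dim(x)), call. = FALSE)
  }
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc, nu = 0L, nv = pcn)
  structure(list(center = center,
                 rotation = sv$v[, seq_len(pcn), drop = FALSE],
                 sdev = sv$d / sqrt(max(1, nrow(x) - 1L)),
                 pcn = pcn),
            class = "reduced_space")
}

#' Project pair vectors into a fitted reduced space
#'
#' @param object A `reduced_space` from [fit_reduce()].
#' @param newdata Matrix of pair vectors (rows) of the original width.
#' @param ... Unused.
#' @return Numeric matrix with `pcn` columns.
#' @export
predict.reduced_space <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2L, object$center) %*% object$rotation
}

#' Train a per-ADR binary classifier
#'
#' Wraps four standard algorithms behind one interface producing a
#' continuous score (higher = more likely positive) and a hard label.
#' Default hyperparameters of the underlying implementations are used:
#' SVM with RBF kernel (cost 1, gamma 1/ncol), logistic regression,
#' k-nearest neighbours with k = 5, and random forest with 500 trees.
#' Stochastic algorithms are seeded for reproducibility.
#'
#' @param x Numeric matrix of training features (reduced pair vectors).
#' @param y Vector of 0/1 training labels; both classes must be present.
#' @param algo One of `"svm"`, `"logreg"`, `"knn"`, `"rf"`.
#' @param seed Integer seed for stochastic algorithms.
#' @return Object of class `adr_classifier`.
#' @export
train_classifier <- function(x, y, algo = c("svm", "logreg", "knn", "rf"),
                             seed = 1L) {
  algo <- match.arg(algo)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: training set contains a single class",
         call. = FALSE)
  }
  yf <- factor(y, levels = c(0L, 1L))
  model <- switch(algo,
    svm = {
      set.seed(seed)
      e1071::svm(x, yf, kernel = "radial", scale = FALSE)
    },
    logreg = {
      df <- data.frame(x)
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial()))
    },
    knn = list(train = x, cl = yf, k = min(5L, nrow(x))),
    rf = {
      set.seed(seed)
      randomForest::randomForest(x, yf)
    })
  structure(list(algo = algo, model = model, seed = seed,
                 ncol = ncol(x)),
            class = "adr_classifier")
}

#' Score and label new samples with a fitted classifier
#'
#' @param object An `adr_classifier`.
#' @param newdata Feature matrix with the training width.
#' @param ... Unused.
#' @return List with numeric `score` (higher = positive) and integer 0/1
#'   `label` from the algorithm's native decision rule (positive SVM
#'   margin, or probability above 0.5 otherwise).
#' @export
predict.adr_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(object$algo,
    svm = {
      pr <- stats::predict(object$model, newdata, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient the margin so positive values point at class "1"
      if (identical(colnames(attr(pr, "decision.values"))[1L], "0/1")) {
        dv <- -dv
      }
      list(score = as.numeric(dv), label = as.integer(as.character(pr)))
    },
    logreg = {
      p <- suppressWarnings(
        stats::predict(object$model, data.frame(newdata), type = "response"))
      list(score = as.numeric(p), label = as.integer(p > 0.5))
    },
    knn = {
      set.seed(object$seed)
      pr <- class::knn(object$model$train, newdata, object$model$cl,
                       k = object$model$k, prob = TRUE)
      win <- attr(pr, "prob")
      p <- ifelse(pr == "1", win, 1 - win)
      list(score = as.numeric(p), label = as.integer(as.character(pr)))
    },
    rf = {
      p <- stats::predict(object$model, newdata, type = "prob")[, "1"]
      list(score = as.numeric(p), label = as.integer(p > 0.5))
    })
}

## Pooled binary metrics from hard labels; 0-denominator conventions
## give 0, keeping every metric defined on degenerate predictions.
binary_metrics <- function(truth, label) {
  tp <- sum(truth == 1 & label == 1)
  fp <- sum(truth == 0 & label == 1)
  fn <- sum(truth == 1 & label == 0)
  tn <- sum(truth == 0 & label == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- (tp + tn) / max(1, tp + fp + fn + tn)
  c(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
}

auc_score <- function(truth, score) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth, score, levels = c("0", "1"),
                                 direction = "<", quiet = TRUE)))
}

#' Aggregate out-of-fold predictions into an evaluation report
#'
#' Pools every ADR's out-of-fold predictions, computes per-ADR precision,
#' recall, accuracy, F1 (from hard labels) and AUC (from continuous
#' scores), and macro-averages them with equal weight per ADR. An ADR
#' whose pooled truth contains a single class has no defined AUC; it is
#' reported as `NA` and excluded from the macro-AUC with a warning.
#'
#' @param predictions Data.frame with columns `adr_id`, `truth` (0/1),
#'   `score`, `label` (0/1), one row per sample.
#' @param config Optional list echoed into the report.
#' @return Object of class `eval_report`: list with `per_adr` (data.frame)
#'   and `macro` (named numeric vector).
#' @export
evaluate <- function(predictions, config = list()) {
  stopifnot(all(c("adr_id", "truth", "score", "label") %in%
                  names(predictions)))
  adrs <- sort(unique(predictions$adr_id))
  rows <- lapply(adrs, function(a) {
    p <- predictions[predictions$adr_id == a, , drop = FALSE]
    m <- binary_metrics(p$truth, p$label)
    auc <- auc_score(p$truth, p$score)
    data.frame(adr_id = a, n = nrow(p), t(m), auc = auc,
               stringsAsFactors = FALSE)
  })
  per_adr <- do.call(rbind, rows)
  if (anyNA(per_adr$auc)) {
    warning("AUC undefined for ", sum(is.na(per_adr$auc)),
            " ADR(s) with single-class truth; excluded from macro-AUC",
            call. = FALSE)
  }
  macro <- c(precision = mean(per_adr$precision),
             recall = mean(per_adr$recall),
             accuracy = mean(per_adr$accuracy),
             f1 = mean(per_adr$f1),
             auc = mean(per_adr$auc, na.rm = TRUE))
  structure(list(per_adr = per_adr, macro = macro, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", nrow(x$per_adr), "ADR(s)\n")
  print(round(x$macro, 4))
  invisible(x)
}

## Assemble the per-ADR labelled dataset: positives from the DDAA table,
## negatives from the ranked list (hcns) or sampled uniformly (random).
adr_dataset <- function(adr, ddaa, ranked, nsr, negatives = "hcns",
                        seed = 1L, exclude_all_positives = FALSE) {
  pos <- unique(ddaa[ddaa$adr_id == adr, c("drug_a", "drug_b")])
  neg <- if (identical(negatives, "hcns")) {
    exclude <- if (exclude_all_positives) {
      unique(ddaa[, c("drug_a", "drug_b")])
    } else NULL
    select_negatives(ranked, pos, nsr, exclude = exclude)
  } else {
    sample_random_negatives(ranked[, c("drug_a", "drug_b")], pos,
                            round(nsr * nrow(pos)), seed)
  }
  pairs <- rbind(pos, neg)
  rownames(pairs) <- NULL
  list(adr_id = adr, pairs = pairs,
       labels = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))))
}

## Cross-validated out-of-fold predictions for one labelled pair matrix.
## PCA and classifier are fit on the training fold only; pcn is capped at
## the training-fold rank limit and the effective value recorded.
cv_predict <- function(X, labels, pcn, algo, k, seed) {
  folds <- split_folds(labels, k, seed)
  score <- numeric(length(labels))
  label <- integer(length(labels))
  eff_pcn <- pcn
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- as.matrix(X[tr, , drop = FALSE])
    p <- min(pcn, nrow(Xtr), ncol(Xtr))
    eff_pcn <- min(eff_pcn, p)
    rs <- fit_reduce(Xtr, p)
    Ztr <- predict(rs, Xtr)
    Zte <- predict(rs, as.matrix(X[!tr, , drop = FALSE]))
    clf <- train_classifier(Ztr, labels[tr], algo,
                            seed = derive_seed(seed, paste0("fold", f)))
    pr <- predict(clf, Zte)
    score[!tr] <- pr$score
    label[!tr] <- pr$label
  }
  list(score = score, label = label, folds = folds, pcn = eff_pcn)
}

#' Run the full per-ADR prediction pipeline
#'
#' For every ADR with at least `min_positives` known positive pairs:
#' takes those pairs as positive samples, selects negatives from the
#' ascending ranked pair list (or uniformly at random for the
#' random-negative baseline), encodes the pairs as concatenated binary
#' vectors, and evaluates a per-ADR classifier with stratified k-fold
#' cross-validation; PCA is fit inside each training fold. Out-of-fold
#' predictions are pooled into an [evaluate()] report.
#'
#' @param catalog A `drug_catalog`.
#' @param network An `rdg_network` on the same drugs.
#' @param ddaa Drug-drug-ADR table from [ddaa_table()].
#' @param config List of settings: `nsr` (default 1), `pcn` (default 300,
#'   capped per fold at the training rank), `algo` (default `"svm"`),
#'   `folds` (default 5), `seed` (default 1), `min_positives` (default
#'   10), `negatives` (`"hcns"` or `"random"`),
#'   `exclude_all_positives` (default `FALSE`: negatives avoid only the
#'   current ADR's positives; `TRUE` additionally skips every other
#'   ADR's positives).
#' @param ranked Optional precomputed [rank_pairs()] result (reused
#'   across calls to avoid rescoring).
#' @param fit_models If `TRUE`, additionally refit one final model per
#'   ADR on all of its samples, returned in `$models` for
#'   [predict_adrs()].
#' @return An `eval_report`; with `fit_models = TRUE` it carries a
#'   `models` element.
#' @export
run_pipeline <- function(catalog, network, ddaa, config = list(),
                         ranked = NULL, fit_models = FALSE) {
  cfg <- utils::modifyList(list(nsr = 1, pcn = 300, algo = "svm",
                                folds = 5L, seed = 1L, min_positives = 10L,
                                negatives = "hcns",
                                exclude_all_positives = FALSE), config)
  if (is.null(ranked)) ranked <- rank_pairs(network, catalog$drugs)
  counts <- table(ddaa$adr_id)
  adrs <- sort(names(counts)[counts >= cfg$min_positives])
  if (length(adrs) == 0L) {
    stop("empty report: no ADR has >= ", cfg$min_positives,
         " positive pairs", call. = FALSE)
  }
  preds <- list()
  models <- list()
  eff_pcn <- cfg$pcn
  for (adr in adrs) {
    ds <- adr_dataset(adr, ddaa, ranked, cfg$nsr, cfg$negatives,
                      seed = derive_seed(cfg$seed, paste0("neg", adr)),
                      exclude_all_positives = cfg$exclude_all_positives)
    X <- build_pair_matrix(catalog, ds$pairs)
    cv <- cv_predict(X, ds$labels, cfg$pcn, cfg$algo, cfg$folds,
                     seed = derive_seed(cfg$seed, adr))
    eff_pcn <- min(eff_pcn, cv$pcn)
    preds[[adr]] <- data.frame(adr_id = adr, truth = ds$labels,
                               score = cv$score, label = cv$label,
                               fold = cv$folds, stringsAsFactors = FALSE)
    if (fit_models) {
      Xd <- as.matrix(X)
      p <- min(cfg$pcn, dim(Xd))
      rs <- fit_reduce(Xd, p)
      clf <- train_classifier(predict(rs, Xd), ds$labels, cfg$algo,
                              seed = derive_seed(cfg$seed,
                                                 paste0("final", adr)))
      models[[adr]] <- list(space = rs, classifier = clf)
    }
  }
  cfg$pcn_effective <- eff_pcn
  report <- evaluate(do.call(rbind, preds), config = cfg)
  if (fit_models) report$models <- models
  report
}

#' Rank candidate ADRs for one drug pair
#'
#' Scores the pair with every fitted per-ADR model and returns ADRs in
#' descending score order (ties broken by ADR identifier).
#'
#' @param catalog A `drug_catalog` covering both drugs.
#' @param models Named list of per-ADR `list(space, classifier)` fits, as
#'   produced by [run_pipeline()] with `fit_models = TRUE`.
#' @param a,b Drug identifiers.
#' @param top Number of top ADRs to return (clipped to the model count).
#' @return Data.frame with columns `adr_id`, `score`, sorted descending.
#' @export
predict_adrs <- function(catalog, models, a, b, top = Inf) {
  ab <- canonical_pair(a, b)
  v <- matrix(encode_pair(catalog, ab[1L], ab[2L]), nrow = 1L)
  scores <- vapply(models, function(m) {
    predict(m$classifier, predict(m$space, v))$score
  }, numeric(1))
  out <- data.frame(adr_id = names(models), score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$adr_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = min(top, nrow(out)))
}
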