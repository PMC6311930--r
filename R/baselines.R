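## Comparison methods: random negative sampling (RGNS), random label
## assignment, and one-class SVM evaluated on random- and screen-selected
## negative test sets.

#' Sample random negative pairs
#'
#' Uniform sample without replacement from the candidate pairs that are
#' not known positives; the baseline negative generator (RGNS).
#'
#' @param all_pairs Data.frame of candidate pairs (`drug_a`, `drug_b`).
#' @param positives Data.frame of positive pairs to exclude.
#' @param count Number of negatives to draw.
#' @param seed Integer seed.
#' @return Data.frame of `count` sampled pairs.
#' @export
sample_random_negatives <- function(all_pairs, positives, count, seed = 1L) {
  keys <- pair_key(all_pairs$drug_a, all_pairs$drug_b)
  pos_keys <- pair_key(positives$drug_a, positives$drug_b)
  cand <- which(!(keys %in% pos_keys))
  if (count > length(cand)) {
    stop("capacity error: need ", count, " negatives but only ",
         length(cand), " non-positive candidates exist", call. = FALSE)
  }
  set.seed(seed)
  pick <- cand[sample.int(length(cand), count)]
  out <- all_pairs[pick, c("drug_a", "drug_b"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random label assignment baseline
#'
#' Assigns label 1 to exactly `round(prevalence * test_size)` test
#' samples chosen uniformly at random, where the prevalence is the ratio
#' of label 1 in the training set; the remaining samples get 0. A floor
#' on how well chance does on the task.
#'
#' @param train_labels 0/1 training labels defining the prevalence.
#' @param test_size Number of test samples to label.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of length `test_size`.
#' @export
random_assign <- function(train_labels, test_size, seed = 1L) {
  stopifnot(test_size >= 1L)
  prevalence <- mean(train_labels == 1)
  n_one <- round(prevalence * test_size)
  out <- integer(test_size)
  if (n_one > 0L) {
    set.seed(seed)
    out[sample.int(test_size, n_one)] <- 1L
  }
  out
}

## Cross-validated one-class SVM for one ADR: trained on the training
## fold's positives only (after PCA fit on the same rows), scored on the
## held-out positives plus that fold's share of negatives.
ocsvm_cv <- function(X, labels, pcn, k, seed) {
  folds <- split_folds(labels, k, seed)
  score <- numeric(length(labels))
  label <- integer(length(labels))
  for (f in seq_len(k)) {
    tr <- which(folds != f & labels == 1L)
    te <- which(folds == f)
    Xtr <- as.matrix(X[tr, , drop = FALSE])
    p <- min(pcn, nrow(Xtr), ncol(Xtr))
    rs <- fit_reduce(Xtr, p)
    Ztr <- predict(rs, Xtr)
    set.seed(derive_seed(seed, paste0("oc", f)))
    fit <- e1071::svm(Ztr, y = NULL, type = "one-classification",
                      kernel = "radial", scale = FALSE)
    Zte <- predict(rs, as.matrix(X[te, , drop = FALSE]))
    pr <- stats::predict(fit, Zte, decision.values = TRUE)
    score[te] <- as.numeric(attr(pr, "decision.values"))
    label[te] <- as.integer(as.logical(pr))
  }
  list(score = score, label = label, folds = folds)
}

#' One-class SVM baseline over all ADRs
#'
#' Trains a one-class SVM on each ADR's positive pairs only and
#' evaluates it against a test set completed with `nsr = 1` negatives
#' drawn either uniformly at random (`negatives = "random"`) or from the
#' low end of the screen list (`negatives = "screen"`). Metrics use the
#' same suite as the main pipeline.
#'
#' @param catalog,network,ddaa As in [run_pipeline()].
#' @param config Settings list (`nsr`, `pcn`, `folds`, `seed`,
#'   `min_positives`).
#' @param negatives `"random"` or `"screen"` test-negative source.
#' @param ranked Optional precomputed [rank_pairs()] result.
#' @return An `eval_report`.
#' @export
one_class_fit_eval <- function(catalog, network, ddaa, config = list(),
                               negatives = c("random", "screen"),
                               ranked = NULL) {
  negatives <- match.arg(negatives)
  cfg <- utils::modifyList(list(nsr = 1, pcn = 300, folds = 5L, seed = 1L,
                                min_positives = 10L), config)
  if (is.null(ranked)) ranked <- rank_pairs(network, catalog$drugs)
  counts <- table(ddaa$adr_id)
  adrs <- sort(names(counts)[counts >= cfg$min_positives])
  if (length(adrs) == 0L) stop("no ADR passes min_positives", call. = FALSE)
  preds <- lapply(adrs, function(adr) {
    ds <- adr_dataset(adr, ddaa, ranked, cfg$nsr,
                      if (negatives == "screen") "hcns" else "random",
                      seed = derive_seed(cfg$seed, paste0("ocneg", adr)))
    X <- build_pair_matrix(catalog, ds$pairs)
    cv <- ocsvm_cv(X, ds$labels, cfg$pcn, cfg$folds,
                   seed = derive_seed(cfg$seed, adr))
    data.frame(adr_id = adr, truth = ds$labels, score = cv$score,
               label = cv$label, stringsAsFactors = FALSE)
  })
  evaluate(do.call(rbind, preds),
           config = c(cfg, method = paste0("ocsvm_", negatives)))
}

## Random-assignment evaluation reusing the pipeline's per-ADR datasets
## and fold structure.
random_assign_eval <- function(catalog, network, ddaa, cfg, ranked) {
  counts <- table(ddaa$adr_id)
  adrs <- sort(names(counts)[counts >= cfg$min_positives])
  preds <- lapply(adrs, function(adr) {
    ds <- adr_dataset(adr, ddaa, ranked, cfg$nsr, "hcns",
                      seed = derive_seed(cfg$seed, paste0("neg", adr)))
    folds <- split_folds(ds$labels, cfg$folds,
                         seed = derive_seed(cfg$seed, adr))
    label <- integer(length(ds$labels))
    for (f in seq_len(cfg$folds)) {
      te <- folds == f
      label[te] <- random_assign(ds$labels[!te], sum(te),
                                 seed = derive_seed(cfg$seed,
                                                    paste0(adr, "ra", f)))
    }
    data.frame(adr_id = adr, truth = ds$labels, score = as.numeric(label),
               label = label, stringsAsFactors = FALSE)
  })
  evaluate(do.call(rbind, preds), config = c(cfg, method = "random"))
}

## Mean of macro metric vectors over repeated reports.
average_macros <- function(reports) {
  m <- do.call(rbind, lapply(reports, function(r) r$macro))
  colMeans(m)
}

#' Compare the pipeline with its baselines on one dataset
#'
#' Runs any subset of `{hcns, rgns, random, ocsvm_random, ocsvm_screen}`
#' on identical per-ADR positive sets and the shared ranked pair list.
#' Methods with random components (`rgns`, `random`, `ocsvm_random`) are
#' repeated `repeats` times with derived seeds and their macro metrics
#' averaged.
#'
#' @param catalog,network,ddaa As in [run_pipeline()].
#' @param config Settings list as in [run_pipeline()].
#' @param methods Character vector of method names.
#' @param repeats Repetitions for the stochastic methods (default 5).
#' @return Data.frame, one row per method, with macro-averaged AUC, F1,
#'   precision, recall and accuracy columns.
#' @export
run_comparison <- function(catalog, network, ddaa, config = list(),
                           methods = c("hcns", "rgns", "random",
                                       "ocsvm_random", "ocsvm_screen"),
                           repeats = 5L) {
  stopifnot(repeats >= 1L, length(methods) >= 1L)
  cfg <- utils::modifyList(list(nsr = 1, pcn = 300, algo = "svm",
                                folds = 5L, seed = 1L, min_positives = 10L,
                                negatives = "hcns"), config)
  ranked <- rank_pairs(network, catalog$drugs)
  one <- function(method) {
    macro <- switch(method,
      hcns = run_pipeline(catalog, network, ddaa, cfg, ranked)$macro,
      rgns = average_macros(lapply(seq_len(repeats), function(r) {
        c2 <- cfg
        c2$negatives <- "random"
        c2$seed <- derive_seed(cfg$seed, paste0("rgns", r))
        run_pipeline(catalog, network, ddaa, c2, ranked)
      })),
      random = average_macros(lapply(seq_len(repeats), function(r) {
        c2 <- cfg
        c2$seed <- derive_seed(cfg$seed, paste0("rand", r))
        random_assign_eval(catalog, network, ddaa, c2, ranked)
      })),
      ocsvm_random = average_macros(lapply(seq_len(repeats), function(r) {
        c2 <- cfg
        c2$seed <- derive_seed(cfg$seed, paste0("ocr", r))
        one_class_fit_eval(catalog, network, ddaa, c2, "random", ranked)
      })),
      ocsvm_screen = one_class_fit_eval(catalog, network, ddaa, cfg,
                                        "screen", ranked)$macro,
      stop("unknown method: ", method, call. = FALSE))
    data.frame(method = method,
               macro_auc = macro[["auc"]], macro_f1 = macro[["f1"]],
               macro_precision = macro[["precision"]],
               macro_recall = macro[["recall"]],
               macro_accuracy = macro[["accuracy"]],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(methods, one))
  rownames(out) <- NULL
  out
}
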