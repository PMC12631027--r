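#' Antenna-grouped train/test split
#'
#' Assigns whole antennae to the training or test side so a classifier is
#' never tested on an antenna it saw during training. Antennae are shuffled
#' with the seed and the first `round-half-up(train_fraction * n)` go to
#' training (15 antennae at 0.7 give 11 train / 4 test).
#'
#' @param waves Wave tibble (or character vector of antenna ids).
#' @param train_fraction Fraction of antennae assigned to training.
#' @param seed Integer seed.
#' @return A list of class `split_spec` with `train_antennae`,
#'   `test_antennae`, `train_fraction`, `seed`.
#' @export
split_by_antenna <- function(waves, train_fraction = 0.7, seed = 1L) {
  ants <- if (is.character(waves)) unique(waves) else
    unique(waves$antenna_id)
  ants <- sort(ants)
  if (length(ants) < 2) {
    stop("need >= 2 distinct antennae to split", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  shuffled <- sample(ants)
  n_train <- as.integer(floor(train_fraction * length(ants) + 0.5)) # half-up
  n_train <- min(max(n_train, 1L), length(ants) - 1L)
  structure(list(train_antennae = sort(shuffled[seq_len(n_train)]),
                 test_antennae = sort(shuffled[-seq_len(n_train)]),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Balanced accuracy
#'
#' Mean of per-class recalls over the classes present in `truth`; robust to
#' class imbalance. Chance level for k balanced classes is 1/k.
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels, same length.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(c("A", "A", "B", "B", "B"), c("A", "B", "B", "B", "B"))
#' # (0.5 + 1)/2 = 0.75
balanced_accuracy <- function(truth, estimate) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` lengths differ", call. = FALSE)
  }
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(estimate[truth == cl] == cl)
  }, numeric(1)))
}

default_svm_grid <- function() {
  list(cost = 10^seq(-1, 3, by = 1), gamma_scale = 10^seq(-2, 2, by = 1))
}

default_rf_grid <- function() {
  list(ntree = c(100, 300, 500), mtry_frac = c(0.33, 0.6, 1))
}

# antenna-grouped k-fold indices
grouped_folds <- function(antennae, k = 3) {
  ants <- unique(antennae)
  k <- min(k, length(ants))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(ants)),
                             sample(ants))
  unname(fold_of[antennae])
}

search_hyper <- function(fit_predict, grid, X, y, antennae, n_random = 8,
                         k = 3) {
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  # random search over the broad space, then exhaustive search on the
  # neighborhood (+- one grid step per dimension) of the best random draw
  cand_idx <- sample(nrow(combos), min(n_random, nrow(combos)))
  score_one <- function(par) {
    folds <- grouped_folds(antennae, k)
    accs <- vapply(unique(folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      pred <- fit_predict(X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], par)
      balanced_accuracy(y[!tr], pred)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }
  rand_scores <- vapply(cand_idx, function(i) score_one(combos[i, ]),
                        numeric(1))
  best <- combos[cand_idx[which.max(rand_scores)], , drop = FALSE]
  nbhd <- lapply(names(grid), function(g) {
    vals <- sort(unique(grid[[g]]))
    i <- which.min(abs(vals - best[[g]]))
    vals[max(1, i - 1):min(length(vals), i + 1)]
  })
  names(nbhd) <- names(grid)
  fine <- expand.grid(nbhd, KEEP.OUT.ATTRS = FALSE)
  fine_scores <- vapply(seq_len(nrow(fine)), function(i) score_one(fine[i, ]),
                        numeric(1))
  fine[which.max(fine_scores), , drop = FALSE]
}

#' Train the time-series SVM classifier
#'
#' RBF-kernel support vector machine on the full stimulus-aligned voltage
#' time series (5000 features at the default 1 kHz / 5 s window).
#' Hyperparameters (cost and kernel width) are optionally chosen by a random
#' search over a broad grid followed by an exhaustive search of the narrowed
#' neighborhood, scored by antenna-grouped cross-validated balanced accuracy
#' within the training set.
#'
#' @param X Numeric matrix, one row per training wave.
#' @param labels Class labels.
#' @param antennae Antenna id per row (required when `tune = TRUE`).
#' @param tune Run the hyperparameter search? Default uses fixed defaults
#'   (`cost = 10`, `gamma = 1/ncol(X)`).
#' @param hyper Optional list overriding `cost` / `gamma`.
#' @return An object of class `eag_svm`.
#' @export
train_wave_svm <- function(X, labels, antennae = NULL, tune = FALSE,
                           hyper = NULL) {
  X <- wave_matrix(X)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop("training set has a single class", call. = FALSE)
  gamma0 <- 1 / ncol(X)
  par <- list(cost = 10, gamma = gamma0)
  if (isTRUE(tune)) {
    if (is.null(antennae)) stop("`antennae` required for tuning", call. = FALSE)
    grid <- default_svm_grid()
    best <- search_hyper(function(Xtr, ytr, Xte, p) {
      m <- e1071::svm(Xtr, factor(ytr), cost = p$cost,
                      gamma = p$gamma_scale * gamma0, kernel = "radial",
                      scale = FALSE)
      as.character(stats::predict(m, Xte))
    }, grid, X, as.character(labels), antennae)
    par <- list(cost = best$cost, gamma = best$gamma_scale * gamma0)
  }
  if (!is.null(hyper)) par[names(hyper)] <- hyper
  fit <- e1071::svm(X, labels, cost = par$cost, gamma = par$gamma,
                    kernel = "radial", scale = FALSE)
  structure(list(fit = fit, hyper = par, n_features = ncol(X),
                 classes = levels(labels)),
            class = "eag_svm")
}

#' Train the principal-component random-forest classifier
#'
#' Random forest on the first few PC scores (the analysis default is 5
#' components covering at least 90% of the variance).
#'
#' @inheritParams train_wave_svm
#' @return An object of class `eag_rf`.
#' @export
train_wave_rf <- function(X, labels, antennae = NULL, tune = FALSE,
                          hyper = NULL) {
  X <- wave_matrix(X)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop("training set has a single class", call. = FALSE)
  par <- list(ntree = 300, mtry = max(1, floor(sqrt(ncol(X)))))
  if (isTRUE(tune)) {
    if (is.null(antennae)) stop("`antennae` required for tuning", call. = FALSE)
    grid <- default_rf_grid()
    best <- search_hyper(function(Xtr, ytr, Xte, p) {
      m <- randomForest::randomForest(
        Xtr, factor(ytr), ntree = p$ntree,
        mtry = max(1, round(p$mtry_frac * ncol(Xtr))))
      as.character(stats::predict(m, Xte))
    }, grid, X, as.character(labels), antennae)
    par <- list(ntree = best$ntree,
                mtry = max(1, round(best$mtry_frac * ncol(X))))
  }
  if (!is.null(hyper)) par[names(hyper)] <- hyper
  fit <- randomForest::randomForest(X, labels, ntree = par$ntree,
                                    mtry = par$mtry)
  structure(list(fit = fit, hyper = par, n_features = ncol(X),
                 classes = levels(labels)),
            class = "eag_rf")
}

#' @export
predict.eag_svm <- function(object, newdata, ...) {
  X <- wave_matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("wave length ", ncol(X), " does not match the trained model (",
         object$n_features, " features)", call. = FALSE)
  }
  as.character(stats::predict(object$fit, X))
}

#' @export
predict.eag_rf <- function(object, newdata, ...) {
  X <- wave_matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("score length ", ncol(X), " does not match the trained model (",
         object$n_features, " features)", call. = FALSE)
  }
  as.character(stats::predict(object$fit, X))
}

#' Exact McNemar test for paired classifiers
#'
#' Two-sided exact binomial test on the discordant outcomes of two
#' classifiers evaluated on identical test waves:
#' `p = min(1, 2 * P(X <= min(n01, n10)))` with
#' `X ~ Binomial(n01 + n10, 1/2)`; `p = 1` when there are no discordant
#' pairs. A chi-square variant with continuity correction is available.
#'
#' @param n00 Both models incorrect.
#' @param n01 Model A incorrect, model B correct.
#' @param n10 Model A correct, model B incorrect.
#' @param n11 Both correct.
#' @param method `"exact"` (default) or `"chisq"` (continuity-corrected).
#' @return The p-value.
#' @export
#' @examples
#' mcnemar_exact(11, 7, 6, 59) # 1.0
mcnemar_exact <- function(n00, n01, n10, n11 = 0,
                          method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n00, n01, n10, n11)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  nd <- n01 + n10
  if (nd == 0) return(1)
  if (method == "exact") {
    k <- min(n01, n10)
    # odd nd with k = (nd-1)/2: the lower tail is exactly 1/2 by symmetry
    if (k >= (nd - 1) / 2) return(1)
    min(1, 2 * stats::pbinom(k, nd, 0.5))
  } else {
    stat <- (abs(n01 - n10) - 1)^2 / nd
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Paired-correctness table for two prediction vectors
#'
#' @param truth True labels.
#' @param pred_a,pred_b Predictions of models A and B on the same waves.
#' @return A list with `n00`, `n01`, `n10`, `n11` (A incorrect/correct by
#'   B incorrect/correct).
#' @export
paired_outcomes <- function(truth, pred_a, pred_b) {
  a <- pred_a == truth; b <- pred_b == truth
  list(n00 = sum(!a & !b), n01 = sum(!a & b),
       n10 = sum(a & !b), n11 = sum(a & b))
}

#' Repeated antenna-grouped evaluation of SVM and RF classifiers
#'
#' For each of `n_splits` seeded antenna-grouped 70/30 splits: fits the PCA
#' basis on the training waves only, trains the time-series SVM and the
#' first-`n_pcs` RF, predicts the held-out antennae, and records balanced
#' accuracies and confusion counts. Confusion matrices are pooled over
#' splits and row-normalized to percentages; the paired-correctness table
#' pooled over splits feeds an exact McNemar comparison of the two models.
#'
#' @param waves Normalized, filtered wave tibble.
#' @param labels Class labels (default `waves$odor`).
#' @param n_splits Number of repeated splits (the study design uses 100).
#' @param train_fraction Fraction of antennae in training.
#' @param n_pcs Principal components for the RF features.
#' @param seed Base seed; split s uses seed + s - 1.
#' @param tune `"none"` (fixed defaults), `"once"` (random-then-grid search
#'   on the first split's training antennae, then frozen), or
#'   `"per_split"`.
#' @param models Character subset of `c("svm", "rf")`.
#' @return An object of class `eag_eval`; see [tidy.eag_eval()] and
#'   [glance.eag_eval()].
#' @export
evaluate_repeated <- function(waves, labels = NULL, n_splits = 100,
                              train_fraction = 0.7, n_pcs = 5, seed = 1L,
                              tune = c("none", "once", "per_split"),
                              models = c("svm", "rf")) {
  tune <- match.arg(tune)
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(labels)) labels <- waves$odor
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  k <- length(classes)
  X_all <- wave_matrix(waves)
  ants <- waves$antenna_id

  hyper <- list(svm = NULL, rf = NULL)
  conf <- lapply(models, function(m) {
    matrix(0, k, k, dimnames = list(truth = classes, predicted = classes))
  })
  names(conf) <- models
  per_split <- list()
  paired <- c(n00 = 0, n01 = 0, n10 = 0, n11 = 0)
  seeds <- seed + seq_len(n_splits) - 1L

  for (s in seq_len(n_splits)) {
    sp <- split_by_antenna(ants, train_fraction, seed = seeds[[s]])
    tr <- ants %in% sp$train_antennae
    te <- !tr
    stopifnot(!any(sp$train_antennae %in% sp$test_antennae))
    if (length(unique(labels[tr])) < 2) {
      stop("split with seed ", seeds[[s]], " left a single-class training set",
           call. = FALSE)
    }
    preds <- list()
    do_tune <- tune == "per_split" || (tune == "once" && s == 1L)
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seeds[[s]] + 10000L)
    if ("svm" %in% models) {
      m <- train_wave_svm(X_all[tr, , drop = FALSE], labels[tr],
                          antennae = ants[tr], tune = do_tune,
                          hyper = if (!do_tune) hyper$svm)
      if (do_tune) hyper$svm <- m$hyper
      preds$svm <- predict(m, X_all[te, , drop = FALSE])
    }
    if ("rf" %in% models) {
      pca <- fit_wave_pca(X_all[tr, , drop = FALSE])
      npc <- min(n_pcs, ncol(pca$components))
      Str <- pca$scores[, seq_len(npc), drop = FALSE]
      Ste <- project_waves(pca, X_all[te, , drop = FALSE], n_pcs = npc)
      m <- train_wave_rf(Str, labels[tr], antennae = ants[tr],
                         tune = do_tune, hyper = if (!do_tune) hyper$rf)
      if (do_tune) hyper$rf <- m$hyper
      preds$rf <- predict(m, Ste)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

    truth_te <- labels[te]
    for (m in models) {
      per_split[[length(per_split) + 1L]] <- tibble::tibble(
        model = m, split = s, seed = seeds[[s]],
        balanced_accuracy = balanced_accuracy(truth_te, preds[[m]]))
      tab <- table(factor(truth_te, classes), factor(preds[[m]], classes))
      conf[[m]] <- conf[[m]] + unclass(tab)
    }
    if (all(c("svm", "rf") %in% models)) {
      po <- paired_outcomes(truth_te, preds$svm, preds$rf)
      paired <- paired + unlist(po)
    }
  }

  per_split <- dplyr::bind_rows(per_split)
  confusion_percent <- lapply(conf, function(M) {
    rs <- rowSums(M)
    rs[rs == 0] <- 1
    100 * M / rs
  })
  mcnemar_p <- if (all(c("svm", "rf") %in% models)) {
    mcnemar_exact(paired[["n00"]], paired[["n01"]], paired[["n10"]],
                  paired[["n11"]])
  } else NA_real_

  structure(
    list(per_split = per_split,
         mean_balanced_accuracy = vapply(
           split(per_split$balanced_accuracy, per_split$model), mean,
           numeric(1)),
         confusion_counts = conf,
         confusion_percent = confusion_percent,
         paired = as.list(paired),
         mcnemar_p = mcnemar_p,
         chance_level = 1 / k,
         classes = classes,
         n_splits = n_splits,
         seeds = seeds,
         hyper = hyper),
    class = "eag_eval")
}

#' @export
print.eag_eval <- function(x, ...) {
  cat(sprintf("<eag_eval> %d antenna-grouped splits, %d classes (chance %.2f)\n",
              x$n_splits, length(x$classes), x$chance_level))
  for (m in names(x$mean_balanced_accuracy)) {
    cat(sprintf("  %s: mean balanced accuracy %.3f\n", m,
                x$mean_balanced_accuracy[[m]]))
  }
  if (!is.na(x$mcnemar_p)) {
    cat(sprintf("  McNemar (pooled discordants %d vs %d): p = %.4g\n",
                x$paired$n01, x$paired$n10, x$mcnemar_p))
  }
  invisible(x)
}

#' Per-split balanced accuracies of a repeated evaluation
#'
#' @param x An `eag_eval`.
#' @param ... Unused.
#' @return Tibble with `model`, `split`, `seed`, `balanced_accuracy` — the
#'   source data of the accuracy violin plot.
#' @method tidy eag_eval
#' @export
tidy.eag_eval <- function(x, ...) x$per_split

#' One-row summary of a repeated evaluation
#'
#' @param x An `eag_eval`.
#' @param ... Unused.
#' @return One-row tibble with the mean balanced accuracy per model, chance
#'   level, number of splits and pooled McNemar p-value.
#' @method glance eag_eval
#' @export
glance.eag_eval <- function(x, ...) {
  out <- tibble::tibble(n_splits = x$n_splits, n_classes = length(x$classes),
                        chance_level = x$chance_level,
                        mcnemar_p = x$mcnemar_p)
  for (m in names(x$mean_balanced_accuracy)) {
    out[[paste0("mean_balanced_accuracy_", m)]] <-
      x$mean_balanced_accuracy[[m]]
  }
  out
}
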