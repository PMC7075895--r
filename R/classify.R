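# Nested leave-one-participant-out classification of paired contrasts.
#
# Outer loop: hold out both antisymmetric samples of one subject. Inner
# loop: leave-one-subject-out over the remaining subjects selects the
# feature count and classifier/hyperparameter maximizing inner accuracy;
# the winner is refit on all outer-training samples and scored on the
# held-out pair. Standardization and t-test feature ranking are refit
# inside every fold — no information from held-out subjects ever reaches
# the transform, the ranking, or the model.

#' Default classifier and feature-count grids
#'
#' Three classifier families: linear support vector machine (margin
#' penalty C grid), nearest neighbours (k grid), and a random forest.
#' The forest size default favours the small training sets this design
#' produces (two samples per subject); votes stabilize well below this
#' count there.
#'
#' @param svm_cost SVM penalty grid.
#' @param knn_k neighbour-count grid.
#' @param rf_trees trees in the forest.
#' @return data.frame with columns `classifier`, `param`.
#' @export
classifier_grid <- function(svm_cost = c(0.01, 0.1, 1, 10),
                            knn_k = c(1, 3, 5), rf_trees = 50) {
  data.frame(
    classifier = c(rep("svm", length(svm_cost)),
                   rep("knn", length(knn_k)), "rf"),
    param = c(svm_cost, knn_k, rf_trees),
    stringsAsFactors = FALSE)
}

#' @rdname classifier_grid
#' @param p number of available features.
#' @export
feature_count_grid <- function(p) {
  g <- c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 126)
  g <- g[g <= p]
  if (length(g) == 0) g <- p
  unique(c(g, if (p < 126) p))
}

#' Fit an intercept-free linear SVM
#'
#' L1-loss linear support vector machine without a bias term, solved by
#' dual coordinate descent; the contrast construction makes the problem
#' exactly origin-symmetric, so an intercept could only add noise.
#'
#' @param X training matrix.
#' @param y +1/-1 labels.
#' @param cost margin penalty C.
#' @return numeric weight vector (named by column).
#' @export
fit_linear_svm <- function(X, y, cost = 1) {
  w <- .linear_svm_fit(X, as.numeric(y), cost)
  names(w) <- colnames(X)
  w
}

# majority-vote kNN from a precomputed test-by-train distance matrix
knn_vote <- function(D2, ytr, k) {
  apply(D2, 1, function(d) {
    nb <- order(d)[seq_len(k)]
    if (sum(ytr[nb]) >= 0) 1L else -1L
  })
}

# The training set always contains both members of every antisymmetric
# pair (d, +1) and (-d, -1), whose hinge losses are identical for any w.
# Fitting on the positive half with doubled cost therefore yields exactly
# the same intercept-free SVM solution at half the problem size.
svm_fit_pairs <- function(X, y, cost, ...) {
  pos <- y > 0
  .linear_svm_fit(X[pos, , drop = FALSE], rep(1, sum(pos)), 2 * cost, ...)
}

# Evaluate every (config, feature count) cell by leave-one-subject-out CV
# within the training partition. Returns correct-count matrix and the
# selected cell under the tie-break (max accuracy; smallest feature count;
# classifier order svm < knn < rf; parameter order as listed).
select_config <- function(X, y, subject, configs, k_grid, seed) {
  subs <- unique(subject)
  n_cfg <- nrow(configs)
  correct <- matrix(0, n_cfg, length(k_grid))
  total <- 0
  rf_rows <- which(configs$classifier == "rf")
  for (s in subs) {
    tr <- subject != s
    te <- !tr
    prm <- standardize_fit(X[tr, , drop = FALSE])
    Xi <- standardize_apply(prm, X[tr, , drop = FALSE])
    Xt <- standardize_apply(prm, X[te, , drop = FALSE])
    total <- total + sum(te)
    if (ncol(Xi) == 0) {   # all features degenerate: chance by construction
      correct <- correct + sum(y[te] == 1L)
      next
    }
    ytr <- y[tr]
    yte <- y[te]
    ord <- rank_features(Xi, ytr)
    Xi <- Xi[, ord, drop = FALSE]
    Xt <- Xt[, ord, drop = FALSE]
    ks <- sort(k_grid[k_grid <= ncol(Xi)])
    # squared test-to-train distances grow incrementally with the ranked
    # feature prefix, so every feature count shares one running matrix
    D2 <- matrix(0, nrow(Xt), nrow(Xi))
    prev <- 0
    for (ki in seq_along(ks)) {
      kk <- ks[ki]
      block <- (prev + 1):kk
      prev <- kk
      Xb <- Xi[, block, drop = FALSE]
      Tb <- Xt[, block, drop = FALSE]
      D2 <- D2 + outer(rowSums(Tb^2), rowSums(Xb^2), "+") -
        2 * tcrossprod(Tb, Xb)
      Xik <- Xi[, seq_len(kk), drop = FALSE]
      Xtk <- Xt[, seq_len(kk), drop = FALSE]
      for (ci in seq_len(n_cfg)) {
        cl <- configs$classifier[ci]
        par <- configs$param[ci]
        pred <- switch(cl,
          svm = {
            w <- svm_fit_pairs(Xik, ytr, par)
            ifelse(as.numeric(Xtk %*% w) >= 0, 1L, -1L)
          },
          knn = knn_vote(D2, ytr, min(par, nrow(Xik))),
          rf = {
            fit <- ranger::ranger(x = Xik, y = as.numeric(ytr),
                                  classification = TRUE,
                                  num.trees = par, num.threads = 1,
                                  verbose = FALSE,
                                  seed = derive_seed(seed, "rf", s, kk))
            pr <- stats::predict(fit, data = Xtk, num.threads = 1,
                                 verbose = FALSE)
            as.integer(pr$predictions)
          })
        correct[ci, ki] <- correct[ci, ki] + sum(pred == yte)
      }
    }
  }
  acc <- correct / total
  # tie-break: accuracy desc, then feature count asc, then config order
  cells <- expand.grid(cfg = seq_len(n_cfg), ki = seq_along(k_grid))
  cells$acc <- acc[cbind(cells$cfg, cells$ki)]
  cells$k <- k_grid[cells$ki]
  cells <- cells[order(-cells$acc, cells$k, cells$cfg), ]
  best <- cells[1, ]
  list(accuracy = acc, best_config = configs[best$cfg, ],
       best_k = best$k, inner_accuracy = best$acc)
}

# Refit the selected configuration on the full training partition and
# return predictions for the test rows plus the frozen model pieces.
refit_predict <- function(config, n_feat, X, y, Xte, seed) {
  prm <- standardize_fit(X)
  Xi <- standardize_apply(prm, X)
  Xt <- standardize_apply(prm, Xte)
  if (ncol(Xi) == 0)
    return(list(pred = rep(1L, nrow(Xte)), features = character(0),
                params = prm, fit = NULL))
  ord <- rank_features(Xi, y)
  kk <- min(n_feat, ncol(Xi))
  sel <- ord[seq_len(kk)]
  Xik <- Xi[, sel, drop = FALSE]
  Xtk <- Xt[, sel, drop = FALSE]
  fit <- NULL
  w <- NULL
  if (identical(config$classifier, "svm")) {
    w <- svm_fit_pairs(Xik, y, config$param)
    names(w) <- colnames(Xik)
  } else if (identical(config$classifier, "rf")) {
    fit <- ranger::ranger(x = Xik, y = as.numeric(y),
                          classification = TRUE,
                          num.trees = config$param, num.threads = 1,
                          verbose = FALSE,
                          seed = derive_seed(seed, "rf-final"))
  }
  pred <- if (nrow(Xtk) == 0) integer(0) else switch(config$classifier,
    svm = ifelse(as.numeric(Xtk %*% w) >= 0, 1L, -1L),
    knn = {
      D2 <- vapply(seq_len(nrow(Xtk)), function(i)
        colSums((t(Xik) - Xtk[i, ])^2), numeric(nrow(Xik)))
      knn_vote(t(matrix(D2, nrow(Xik))), y, min(config$param, nrow(Xik)))
    },
    rf = {
      pr <- stats::predict(fit, data = Xtk, num.threads = 1,
                           verbose = FALSE)
      as.integer(pr$predictions)
    })
  list(pred = pred, features = colnames(Xik), params = prm, fit = fit,
       weights = w, train_X = Xik, train_y = y)
}

#' Nested leave-one-participant-out cross-validation
#'
#' @param contrasts an `sc_contrasts` from [make_contrasts()] (or any list
#'   with `X`, `y`, `subject`).
#' @param classifiers from [classifier_grid()].
#' @param feature_counts feature-count grid (default
#'   [feature_count_grid()] of the available features).
#' @param seed integer seed for the stochastic classifier.
#' @return list of class `sc_cv_result`: `folds` (per-subject data.frame
#'   with selected classifier, parameter, feature count, correct count),
#'   `accuracy`, `n_correct`, `n_total`, `p_value` (one-sided binomial
#'   against chance 0.5), `fold_weights` (standardized-scale linear
#'   weights for folds won by the linear model).
#' @export
nested_lopo_cv <- function(contrasts, classifiers = classifier_grid(),
                           feature_counts = NULL, seed = 1) {
  X <- contrasts$X
  y <- contrasts$y
  subject <- contrasts$subject
  subs <- unique(subject)
  if (length(subs) < 3)
    stop("nested cross-validation needs at least 3 subjects", call. = FALSE)
  if (is.null(feature_counts)) feature_counts <- feature_count_grid(ncol(X))
  folds <- list()
  fold_weights <- list()
  n_correct <- 0
  n_total <- 0
  for (s in subs) {
    tr <- subject != s
    sel <- select_config(X[tr, , drop = FALSE], y[tr], subject[tr],
                         classifiers, feature_counts,
                         seed = derive_seed(seed, "outer", s))
    rf <- refit_predict(sel$best_config, sel$best_k,
                        X[tr, , drop = FALSE], y[tr],
                        X[!tr, , drop = FALSE],
                        seed = derive_seed(seed, "outer", s))
    corr <- sum(rf$pred == y[!tr])
    n_correct <- n_correct + corr
    n_total <- n_total + sum(!tr)
    folds[[length(folds) + 1]] <- data.frame(
      subject = s, classifier = sel$best_config$classifier,
      param = sel$best_config$param, n_features = sel$best_k,
      inner_accuracy = sel$inner_accuracy, correct = corr,
      stringsAsFactors = FALSE)
    if (identical(sel$best_config$classifier, "svm"))
      fold_weights[[s]] <- rf$weights
  }
  accuracy <- n_correct / n_total
  structure(list(folds = do.call(rbind, folds), accuracy = accuracy,
                 n_correct = n_correct, n_total = n_total,
                 p_value = binomial_significance(n_correct, n_total),
                 fold_weights = fold_weights),
            class = "sc_cv_result")
}

#' Exact one-sided binomial significance of a classification accuracy
#'
#' Tail probability P(X >= n_correct) for X ~ Binomial(n_total, 1/2): the
#' paired-contrast construction makes 50% the exact chance level.
#'
#' @param n_correct correctly classified samples.
#' @param n_total total samples.
#' @return p-value.
#' @export
binomial_significance <- function(n_correct, n_total) {
  stopifnot(n_correct >= 0, n_correct <= n_total)
  stats::pbinom(n_correct - 1, n_total, 0.5, lower.tail = FALSE)
}

#' Relative feature contributions of a linear model
#'
#' Rescales linear weights to relative contributions: absolute values
#' divided by their sum. The conventional 10% display threshold is
#' attached as an attribute and applied only in reports, never in
#' computation.
#'
#' @param weights named numeric weights.
#' @return named contributions summing to 1, class `sc_weight_profile`.
#' @export
weight_profile <- function(weights) {
  a <- abs(weights)
  if (sum(a) == 0) stop("all weights are zero", call. = FALSE)
  structure(a / sum(a), display_threshold = 0.10,
            class = "sc_weight_profile")
}

#' Train a frozen contrast model on a full training cohort
#'
#' Runs the same leave-one-subject-out selection as the inner loop of
#' [nested_lopo_cv()] over the whole training set, then refits the winning
#' configuration on all samples. The returned model freezes the
#' standardization parameters, the selected feature names, and the fitted
#' classifier for external validation.
#'
#' @inheritParams nested_lopo_cv
#' @return list of class `sc_contrast_model`.
#' @export
train_contrast_model <- function(contrasts, classifiers = classifier_grid(),
                                 feature_counts = NULL, seed = 1) {
  X <- contrasts$X
  if (is.null(feature_counts)) feature_counts <- feature_count_grid(ncol(X))
  sel <- select_config(X, contrasts$y, contrasts$subject, classifiers,
                       feature_counts, seed = derive_seed(seed, "final"))
  rf <- refit_predict(sel$best_config, sel$best_k, X, contrasts$y,
                      X[0, , drop = FALSE], seed = derive_seed(seed, "final"))
  structure(list(config = sel$best_config, n_features = sel$best_k,
                 features = rf$features, params = rf$params,
                 fit = rf$fit, weights = rf$weights,
                 train_X = rf$train_X, train_y = rf$train_y,
                 contrasts = contrasts, classifiers = classifiers,
                 feature_counts = feature_counts, seed = seed,
                 condition_a = contrasts$condition_a,
                 condition_b = contrasts$condition_b,
                 task = contrasts$task),
            class = "sc_contrast_model")
}

predict_contrast_model <- function(model, Xnew) {
  Z <- standardize_apply(model$params, Xnew[, names(model$params$mean),
                                            drop = FALSE])
  Zk <- Z[, model$features, drop = FALSE]
  switch(model$config$classifier,
    svm = ifelse(as.numeric(Zk %*% model$weights) >= 0, 1L, -1L),
    knn = {
      D2 <- t(vapply(seq_len(nrow(Zk)), function(i)
        colSums((t(model$train_X) - Zk[i, ])^2),
        numeric(nrow(model$train_X))))
      knn_vote(D2, model$train_y, min(model$config$param,
                                      nrow(model$train_X)))
    },
    rf = {
      pr <- stats::predict(model$fit, data = Zk, num.threads = 1,
                           verbose = FALSE)
      as.integer(pr$predictions)
    })
}

#' Validate a frozen model on an external cohort
#'
#' Builds the same condition contrast in the external feature table and
#' scores it with the frozen model and frozen standardization. A feature
#' mask (names to exclude, e.g. all acoustic features when no audio is
#' available externally) triggers a refit of the model on its own training
#' contrasts restricted to the unmasked features, using the identical
#' selection procedure.
#'
#' @param model an `sc_contrast_model`.
#' @param external_table feature table of the external cohort.
#' @param mask character vector of feature names to exclude (NULL for
#'   none).
#' @return list: `accuracy`, `n_correct`, `n_total`, `p_value`, `model`
#'   (the possibly refit model).
#' @export
transfer_evaluate <- function(model, external_table, mask = NULL) {
  if (!is.null(mask) && length(mask) > 0) {
    ctr <- model$contrasts
    keep <- setdiff(colnames(ctr$X), mask)
    if (length(keep) == 0) stop("mask removes every feature", call. = FALSE)
    ctr$X <- ctr$X[, keep, drop = FALSE]
    ctr$features <- keep
    model <- train_contrast_model(ctr, model$classifiers,
                                  feature_count_grid(length(keep)),
                                  seed = model$seed)
  }
  needed <- names(model$params$mean)
  missing <- setdiff(needed, feature_columns(external_table))
  if (length(missing) > 0)
    stop("external table lacks model features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ext <- make_contrasts(external_table, model$condition_a,
                        model$condition_b, model$task)
  pred <- predict_contrast_model(model, ext$X)
  n_correct <- sum(pred == ext$y)
  list(accuracy = n_correct / length(ext$y), n_correct = n_correct,
       n_total = length(ext$y),
       p_value = binomial_significance(n_correct, length(ext$y)),
       model = model)
}
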