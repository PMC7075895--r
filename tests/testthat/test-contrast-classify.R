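# Paired-contrast construction, standardization, ranking, the classifier
# stack, and nested cross-validation.

test_that("standardization uses training parameters only and drops constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  p <- standardize_fit(X)
  Z <- standardize_apply(p, X)
  expect_equal(colnames(Z), "a")              # constant column dropped
  expect_equal(mean(Z[, "a"]), 0)
  expect_equal(sd(Z[, "a"]), 1)
  # leakage contract: test rows transformed with training parameters
  Xte <- cbind(a = 10, b = 0)
  Zte <- standardize_apply(p, Xte)
  expect_equal(unname(Zte[1, "a"]), (10 - 2) / 1)
})

test_that("make_contrasts builds exact antisymmetric pairs", {
  tab <- data.frame(subject_id = rep(c("S1", "S2"), each = 2),
                    session = 1, condition = rep(c("A", "B"), 2),
                    task = "Monologue",
                    `A-f1` = c(1, 0, 4, 1), `A-f2` = c(2, 0, 6, 1),
                    check.names = FALSE)
  ctr <- make_contrasts(tab, "A", "B", "Monologue")
  expect_equal(nrow(ctr$X), 4)                 # 2 samples per subject
  expect_equal(ctr$y, c(1L, -1L, 1L, -1L))
  expect_equal(unname(ctr$X[1, ]), c(1, 2))    # x_A - x_B for S1
  expect_equal(ctr$X[2, ], -ctr$X[1, ])        # exact negation
  expect_equal(ctr$subject, c("S1", "S1", "S2", "S2"))
  # missing condition: subject excluded with a warning, not an error
  expect_warning(
    ctr2 <- make_contrasts(tab[-2, ], "A", "B", "Monologue"), "S1")
  expect_equal(unique(ctr2$subject), "S2")
  expect_equal(ctr2$excluded, "S1")
})

test_that("rank_features puts a planted signal first and is exact under antisymmetry", {
  set.seed(11)
  hits <- 0
  for (r in 1:100) {
    d <- cbind(matrix(rnorm(10 * 2), 10, 2), rnorm(10, mean = 2),
               matrix(rnorm(10 * 2), 10, 2))
    X <- rbind(d, -d)
    colnames(X) <- paste0("f", 1:5)
    y <- rep(c(1L, -1L), each = 10)
    ord <- rank_features(X, y)
    if (ord[1] == 3) hits <- hits + 1
    # construction property: class means are exact negations
    expect_equal(colMeans(X[y > 0, ]), -colMeans(X[y < 0, ]))
  }
  expect_gte(hits, 95)
})

test_that("the intercept-free linear SVM agrees with a reference implementation", {
  set.seed(21)
  d <- matrix(rnorm(20 * 3), 20, 3) + rep(c(1.5, 0, -0.5), each = 20)
  X <- rbind(d, -d)
  y <- rep(c(1, -1), each = 20)
  for (C in c(0.1, 1)) {
    w <- speechcontrast:::.linear_svm_fit(X, y, C, max_epochs = 5000,
                                          tol = 1e-8)
    ref <- e1071::svm(X, factor(y), kernel = "linear", cost = C,
                      scale = FALSE)
    wref <- as.numeric(t(ref$coefs) %*% ref$SV)
    # the reference encodes an arbitrary class-order sign; align it
    if (sum(w * wref) < 0) wref <- -wref
    # origin symmetry forces the reference intercept to ~0 (up to the
    # reference solver's own stopping tolerance), so the weight vectors
    # of the two solvers should coincide
    expect_lt(abs(ref$rho), 1e-3)
    expect_equal(w, wref, tolerance = 1e-3)
  }
})

test_that("the half-pair SVM shortcut reproduces the full symmetric fit", {
  set.seed(22)
  d <- matrix(rnorm(15 * 4), 15, 4)
  X <- rbind(d, -d)
  y <- rep(c(1, -1), each = 15)
  w_full <- speechcontrast:::.linear_svm_fit(X, y, 1, max_epochs = 5000,
                                             tol = 1e-10)
  w_half <- speechcontrast:::svm_fit_pairs(X, y, 1, max_epochs = 5000,
                                           tol = 1e-10)
  expect_equal(w_half, w_full, tolerance = 1e-4)
})

test_that("knn_vote matches the reference nearest-neighbour classifier", {
  set.seed(23)
  Xtr <- matrix(rnorm(40 * 4), 40, 4)
  ytr <- rep(c(1L, -1L), 20)
  Xte <- matrix(rnorm(15 * 4), 15, 4)
  D2 <- t(vapply(seq_len(nrow(Xte)), function(i)
    colSums((t(Xtr) - Xte[i, ])^2), numeric(nrow(Xtr))))
  for (k in c(1, 3, 5)) {
    mine <- speechcontrast:::knn_vote(D2, ytr, k)
    ref <- as.integer(as.character(class::knn(Xtr, Xte, factor(ytr), k = k)))
    expect_equal(mine, ref)
  }
})

test_that("binomial significance is the exact tail sum", {
  expect_equal(binomial_significance(27, 31), 36457 / 2^31,
               tolerance = 1e-12)
  expect_gt(binomial_significance(10, 20), 0.5)
  expect_equal(binomial_significance(5, 5), 1 / 32)
  expect_equal(binomial_significance(0, 10), 1)
})

test_that("weight_profile normalizes absolute weights", {
  wp <- weight_profile(c(a = 2, b = -1, c = 1))
  expect_equal(unname(as.numeric(wp)), c(0.5, 0.25, 0.25))
  expect_equal(sum(wp), 1)
  expect_equal(attr(wp, "display_threshold"), 0.10)
  wp1 <- weight_profile(c(a = 0, b = 3))
  expect_equal(unname(as.numeric(wp1)), c(0, 1))
  expect_error(weight_profile(c(0, 0)), "zero")
})

test_that("feature_count_grid caps at the available feature count", {
  expect_equal(feature_count_grid(126), c(1, 2, 3, 5, 8, 13, 21, 34, 55,
                                          89, 126))
  expect_equal(feature_count_grid(10), c(1, 2, 3, 5, 8, 10))
  expect_equal(feature_count_grid(1), 1)
})

test_that("nested CV is perfect on a separable toy set and refuses n < 3", {
  set.seed(31)
  n <- 8
  d <- cbind(1 + 0.1 * rnorm(n), matrix(rnorm(n * 3), n, 3))
  X <- matrix(0, 2 * n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[seq(1, 2 * n, 2), ] <- d
  X[seq(2, 2 * n, 2), ] <- -d
  y <- rep(c(1L, -1L), n)
  subject <- rep(sprintf("S%02d", 1:n), each = 2)
  ctr <- list(X = X, y = y, subject = subject)
  res <- nested_lopo_cv(ctr, classifiers = classifier_grid(svm_cost = 1,
                                                           knn_k = 1),
                        seed = 1)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_total, 2 * n)
  expect_equal(nrow(res$folds), n)             # one fold per subject
  expect_error(nested_lopo_cv(list(X = X[1:4, ], y = y[1:4],
                                   subject = subject[1:4])),
               "3 subjects")
})

test_that("nested CV is deterministic, including the stochastic forest", {
  tab <- simulate_feature_table(n_subjects = 6, n_acoustic = 6,
                                n_semantic = 0, n_psycholinguistic = 0,
                                effect_size = 1, n_effect_features = 2,
                                seed = 5)
  ctr <- make_contrasts(tab, "DRUG", "PBO", "Monologue")
  r1 <- nested_lopo_cv(ctr, seed = 9)
  r2 <- nested_lopo_cv(ctr, seed = 9)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$folds, r2$folds)
})

test_that("transfer evaluation scores external cohorts and honours masks", {
  # one instrument, two disjoint subject samples: the planted effect sits
  # on the same features internally and externally, as it would for two
  # cohorts measured with the same protocol
  full <- simulate_feature_table(n_subjects = 24, effect_size = 2, seed = 41)
  subs <- unique(full$subject_id)
  tr_tab <- full[full$subject_id %in% subs[1:12], ]
  ext <- full[full$subject_id %in% subs[13:24], ]
  ctr <- make_contrasts(tr_tab, "DRUG", "PBO", "Monologue")
  grids <- classifier_grid(svm_cost = c(0.1, 1), knn_k = 3)
  model <- train_contrast_model(ctr, classifiers = grids,
                                feature_counts = c(1, 5, 21), seed = 2)
  out <- transfer_evaluate(model, ext)
  expect_gte(out$accuracy, 0.75)
  # null external cohort stays near chance
  ext0 <- simulate_feature_table(n_subjects = 12, effect_size = 0, seed = 43)
  out0 <- transfer_evaluate(model, ext0)
  expect_lt(out0$accuracy, 0.8)
  # masking every acoustic feature refits on the 38 text features
  mask <- domain_columns(tr_tab, "acoustic")
  outm <- transfer_evaluate(model, ext, mask = mask)
  expect_false(any(outm$model$features %in% mask))
  # a missing unmasked feature is a named error
  ext_broken <- ext
  gone <- model$features[1]
  ext_broken[[gone]] <- NULL
  expect_error(transfer_evaluate(model, ext_broken), gone, fixed = TRUE)
})
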