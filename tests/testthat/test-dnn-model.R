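test_that("splitting is a seed-reproducible 64/16/20 partition", {
  sp <- split_data(1000, seed = 3)
  expect_length(sp$train, 640)
  expect_length(sp$validation, 160)
  expect_length(sp$test, 200)
  expect_identical(sort(c(sp$train, sp$validation, sp$test)), 1:1000)
  expect_identical(sp, split_data(1000, seed = 3))
  expect_false(identical(sp$train, split_data(1000, seed = 4)$train))
  expect_error(split_data(5), "at least 10")
  expect_error(split_data(1000, ratios = c(0.5, 0.3, 0.3)), "summing to 1")
})

test_that("validation and test keep the natural prevalence; only training is rebalanced", {
  ch <- big_default_cohort()
  sp <- split_data(ch, seed = 5)
  prev <- mean(ch$y)
  expect_lt(abs(mean(ch$y[sp$validation]) - prev), 0.01)
  expect_lt(abs(mean(ch$y[sp$test]) - prev), 0.01)
  rus <- undersample(ch$y, sp$train, seed = 6)
  expect_equal(mean(ch$y[rus]), 0.5)
})

test_that("random under-sampling keeps all minority cases and balances exactly", {
  labels <- c(rep(1L, 100), rep(0L, 1000))
  idx <- seq_along(labels)
  rus <- undersample(labels, idx, seed = 1)
  expect_length(rus, 200)
  expect_equal(sum(labels[rus]), 100)
  expect_true(all(which(labels == 1L) %in% rus))
  expect_identical(rus, undersample(labels, idx, seed = 1))
  balanced <- c(rep(1L, 50), rep(0L, 50))
  expect_identical(undersample(balanced, 1:100, seed = 2), 1:100)
  expect_error(undersample(rep(1L, 10), 1:10, seed = 1), "both classes")
})

test_that("parameter count matches the layer-by-layer formula", {
  d <- 20L; h <- 32L
  net <- build_network(net_config(d, hidden_width = h, n_residual_blocks = 2L))
  expected <- (d * h + h) + 2 * (2 * (h^2 + h) + 2 * 2 * h) + (h + 1)
  expect_equal(n_parameters(net), expected)
})

test_that("the network is a deterministic sigmoid-bounded map outside training", {
  net <- build_network(net_config(5, hidden_width = 8), seed = 11)
  X <- withr::with_seed(1, matrix(rnorm(40), 8, 5))
  p1 <- predict_proba(net, X)
  expect_identical(p1, predict_proba(net, X))
  expect_true(all(p1 > 0 & p1 < 1))
  # same init seed, same predictions; different seed, different
  expect_identical(p1, predict_proba(build_network(net_config(5, hidden_width = 8),
                                                   seed = 11), X))
  expect_false(identical(p1, predict_proba(build_network(net_config(5, hidden_width = 8),
                                                         seed = 12), X)))
  # all-zero weights: sigma(0) = 0.5 for every input
  zero <- net
  zero$params <- rapply(zero$params, function(x) x * 0, how = "replace")
  expect_equal(predict_proba(zero, X), rep(0.5, 8))
})

test_that("a zero-block network computes an exact logistic model", {
  beta <- c(1.5, -2, 0.7)
  net <- linear_resnet(beta, intercept = 0.3)
  X <- withr::with_seed(2, matrix(rnorm(30), 10, 3))
  expect_equal(predict_proba(net, X), plogis(drop(X %*% beta) + 0.3),
               tolerance = 1e-12)
})

test_that("training separates two Gaussian clouds as well as the logistic oracle", {
  ch <- toy_cloud_cohort(2000)
  sp <- split_data(ch, seed = 1)
  net <- build_network(net_config(2, hidden_width = 16), seed = 1)
  net <- train_network(net, ch,
                       list(train = sp$train, validation = sp$validation),
                       train_config(max_epochs = 60, seed = 1))
  ev <- evaluate(net, ch, sp$validation, split_name = "Validation")
  # logistic regression oracle on the same split
  df <- data.frame(ch$features, y = ch$y)
  lr <- suppressWarnings(glm(y ~ ., data = df[sp$train, ], family = binomial))
  p_lr <- predict(lr, df[sp$validation, ], type = "response")
  f1_lr <- ehrimpact:::.threshold_metrics(ch$y[sp$validation], p_lr, 0.5)$f1
  expect_gte(f1_lr, 0.99)
  expect_gte(ev$f1, 0.95)
})

test_that("early stopping halts after `patience` non-improving epochs and restores the best weights", {
  ch <- toy_cloud_cohort(400, gap = 0.3, seed = 9)
  sp <- split_data(ch, seed = 2)
  net <- build_network(net_config(2, hidden_width = 4), seed = 3)
  # a vanishing learning rate freezes the weights, so validation F1 never
  # improves after epoch 1: patience 1 must stop at epoch 2
  frozen <- train_network(net, ch,
                          list(train = sp$train, validation = sp$validation),
                          train_config(learning_rate = 1e-12, patience = 1,
                                       max_epochs = 50, seed = 4))
  expect_equal(nrow(frozen$history), 2)
  expect_equal(frozen$best_epoch, 1)

  trained <- train_network(build_network(net_config(2, hidden_width = 8), seed = 5),
                           ch, list(train = sp$train, validation = sp$validation),
                           train_config(max_epochs = 30, patience = 5, seed = 6))
  # returned weights reproduce the recorded best validation F1
  p_val <- predict_proba(trained, ch$features[sp$validation, ])
  f1 <- ehrimpact:::.threshold_metrics(ch$y[sp$validation], p_val, 0.5)$f1
  expect_equal(f1, max(trained$history$val_f1))
  expect_equal(f1, trained$history$val_f1[trained$best_epoch])
})

test_that("an informative extra feature never hurts achievable validation F1", {
  f1_for <- function(d_extra, seed) {
    withr::with_seed(seed, {
      n <- 1200
      y <- rbinom(n, 1L, 0.5)
      feats <- data.frame(f1 = rnorm(n, ifelse(y == 1, 1, -1)))
      if (d_extra) feats$f2 <- rnorm(n, ifelse(y == 1, 1, -1))
      specs <- lapply(names(feats), feature_spec, kind = "continuous")
      ch <- new_cohort(feats, y_documented = y, y_coded = integer(n),
                       specs = specs)
      sp <- split_data(ch, seed = seed)
      net <- build_network(net_config(ncol(feats), hidden_width = 8),
                           seed = seed)
      net <- train_network(net, ch,
                           list(train = sp$train, validation = sp$validation),
                           train_config(max_epochs = 40, seed = seed))
      max(net$history$val_f1)
    })
  }
  seeds <- 1:5
  base <- vapply(seeds, function(s) f1_for(FALSE, s), 0)
  extra <- vapply(seeds, function(s) f1_for(TRUE, s), 0)
  expect_gte(mean(extra) - mean(base), -0.01)
})

test_that("evaluation metrics match a hand-computed confusion table and pairwise AUC", {
  ch <- new_cohort(data.frame(x = numeric(6)),
                   y_documented = c(1L, 1L, 0L, 1L, 0L, 0L),
                   y_coded = integer(6),
                   specs = list(feature_spec("x", "continuous")))
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  model <- function(features) scores[seq_len(nrow(features))]
  ev <- evaluate(model, ch, 1:6)
  # threshold 0.5 -> predictions 1,1,1,0,0,0: tp=2 fp=1 fn=1 tn=2
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$f1, 2 / 3)
  expect_equal(ev$accuracy, 4 / 6)
  expect_equal(ev$auc, 8 / 9)

  # degenerate cases
  perfect <- function(features) ch$y[seq_len(nrow(features))] * 0.98 + 0.01
  evp <- evaluate(perfect, ch, 1:6)
  expect_equal(unlist(evp[c("f1", "accuracy", "precision", "recall", "auc")]),
               c(f1 = 1, accuracy = 1, precision = 1, recall = 1, auc = 1))
  flat <- function(features) rep(0.5, nrow(features))
  expect_equal(evaluate(flat, ch, 1:6)$auc, 0.5)

  one_class <- new_cohort(data.frame(x = numeric(4)),
                          y_documented = rep(1L, 4), y_coded = integer(4),
                          specs = list(feature_spec("x", "continuous")))
  ev1 <- evaluate(flat, one_class, 1:4)
  expect_true(is.na(ev1$auc))
  expect_equal(ev1$recall, 1)
})

test_that("rank AUC equals brute-force pairwise comparison, ties mid-ranked", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(20:300, 1)
      y <- rbinom(n, 1L, 0.4)
      if (length(unique(y)) < 2) next
      p <- round(runif(n), 1)  # coarse grid forces ties
      expect_equal(ehrimpact:::.rank_auc(y, p), pairwise_auc(y, p))
    }
  })
})

test_that("the analytic AUC interval reproduces the published bounds and limits", {
  ci <- auc_confidence_interval(0.782, 29338, 141922, 0.95)
  expect_equal(round(ci, 3), c(0.779, 0.785))
  # symmetry at AUC = 0.5
  ci5 <- auc_confidence_interval(0.5, 500, 500, 0.95)
  expect_equal(ci5[1] - 0.5, -(ci5[2] - 0.5))
  # width shrinks toward 0 with the sample counts
  w <- function(n) diff(auc_confidence_interval(0.8, n, n, 0.95))
  expect_gt(w(100), w(10000))
  expect_lt(w(1e8), 1e-3)
  expect_error(auc_confidence_interval(0.8, 10, 10, level = 1.2), "level")
  expect_error(auc_confidence_interval(1, 10, 10), "strictly inside")
})
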