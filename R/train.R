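# Training protocol: 64/16/20 split, random under-sampling of the majority
# class on the training part only, mini-batch SGD on binary cross-entropy,
# early stopping on validation F1, and rank-based AUC with the analytic
# (Hanley-McNeil) confidence interval.

#' Split instances into training / validation / test parts
#'
#' Simple random split (seed-reproducible) into disjoint, exhaustive index
#' sets. Validation and test are left at the natural outcome prevalence; any
#' class rebalancing happens afterwards on the training part only.
#'
#' @param n number of instances, or an `ehr_cohort`.
#' @param ratios length-3 proportions summing to 1 (default
#'   `c(0.64, 0.16, 0.20)`).
#' @param seed integer seed.
#' @return a list with sorted integer vectors `train`, `validation`, `test`.
#' @export
split_data <- function(n, ratios = c(0.64, 0.16, 0.20), seed = 1L) {
  if (inherits(n, "ehr_cohort")) n <- cohort_size(n)
  .assert(n >= 10, "need at least 10 instances to split")
  .assert(length(ratios) == 3 && all(ratios > 0) &&
            abs(sum(ratios) - 1) < 1e-8, "ratios must be 3 positives summing to 1")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(ratios[1] * n)
  n_val <- round(ratios[2] * n)
  .assert(n_train >= 1 && n_val >= 1 && n - n_train - n_val >= 1,
          "degenerate split: one part is empty")
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1):n]))
}

#' Random under-sampling to exact class balance
#'
#' Keeps every minority-class index and a uniform random subset of the
#' majority class of the same size. Intended for the training part only.
#'
#' @param labels full binary label vector.
#' @param indices index subset to balance.
#' @param seed integer seed.
#' @return sorted integer vector of balanced indices.
#' @export
undersample <- function(labels, indices, seed = 1L) {
  lab <- labels[indices]
  .assert(length(unique(lab)) == 2, "both classes must be present")
  tab <- table(lab)
  minority <- names(tab)[which.min(tab)]
  keep_min <- indices[lab == minority]
  maj <- indices[lab != minority]
  keep_maj <- withr::with_seed(seed, sample(maj, length(keep_min)))
  sort(c(keep_min, keep_maj))
}

#' Training hyper-parameters
#'
#' @param learning_rate SGD step size (default 0.01).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param batch_size mini-batch size (default 256).
#' @param max_epochs epoch cap (default 200).
#' @param patience early-stopping patience: training halts once validation F1
#'   has not improved its running maximum for this many consecutive epochs
#'   (default 10).
#' @param classification_threshold probability threshold for the F1 /
#'   accuracy / precision / recall metrics (default 0.5, the natural
#'   operating point after class-balanced training).
#' @param seed integer seed for shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 256L, max_epochs = 200L,
                         patience = 10L, classification_threshold = 0.5,
                         seed = 1L) {
  .assert(learning_rate > 0, "learning_rate must be > 0")
  .assert(patience >= 1, "patience must be >= 1")
  .assert(classification_threshold > 0 && classification_threshold < 1,
          "classification_threshold must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 classification_threshold = classification_threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the residual network
#'
#' Optimizes mean binary cross-entropy by mini-batch SGD with momentum.
#' After every epoch the validation F1 (at the classification threshold,
#' dropout disabled) is recorded; training stops when the F1 running maximum
#' has not strictly improved for `patience` consecutive epochs, or at
#' `max_epochs`, and the weights of the best-F1 epoch are restored.
#' Continuous design columns are standardized internally using training-set
#' statistics; the standardization travels with the model so predictions and
#' perturbations stay in raw units.
#'
#' @param net an untrained `resnet_classifier` (see [build_network()]).
#' @param cohort an `ehr_cohort`.
#' @param splits list with `train` (under-sampled already, see
#'   [undersample()]) and `validation` index vectors.
#' @param cfg a [train_config()].
#' @param outcome label column used as the target (default `"y"`).
#' @return the trained `resnet_classifier`, with `history` (per-epoch data
#'   frame of training loss and validation F1) and `best_epoch`.
#' @export
train_network <- function(net, cohort, splits, cfg = train_config(),
                          outcome = "y") {
  .assert(inherits(net, "resnet_classifier"), "net must be a resnet_classifier")
  D <- build_design_matrix(cohort$specs, cohort$features)
  .assert(ncol(D) == net$config$input_dim,
          "network input_dim does not match the cohort design matrix")
  net$specs <- cohort$specs
  net$feature_names <- colnames(D)
  is_cont <- vapply(cohort$specs, function(sp) sp$kind == "continuous", TRUE)
  cont_cols <- .spec_names(cohort$specs)[is_cont]
  center <- stats::setNames(rep(0, ncol(D)), colnames(D))
  scale <- stats::setNames(rep(1, ncol(D)), colnames(D))
  for (cc in cont_cols) {
    center[cc] <- mean(D[splits$train, cc])
    s <- stats::sd(D[splits$train, cc])
    scale[cc] <- if (is.finite(s) && s > 0) s else 1
  }
  net$center <- center
  net$scale <- scale

  X <- sweep(sweep(D, 2, center, "-"), 2, scale, "/")
  y <- cohort[[outcome]]
  Xtr <- X[splits$train, , drop = FALSE]
  ytr <- y[splits$train]
  Xval <- X[splits$validation, , drop = FALSE]
  yval <- y[splits$validation]

  params <- net$params
  vel <- .map_params(function(a, b) a * 0, params, params)
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  history <- list()
  n_tr <- nrow(Xtr)
  dr <- net$config$dropout_rate

  withr::with_seed(cfg$seed, {
    bad_epochs <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      loss_sum <- 0
      starts <- seq(1L, n_tr, by = cfg$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + cfg$batch_size - 1L, n_tr)]
        Xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        fw <- .net_forward(params, Xb, dropout_rate = dr, keep_cache = TRUE)
        p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        }
        loss_sum <- loss_sum + loss * length(idx)
        grads <- .net_backward(params, Xb, fw, (fw$p - yb) / length(idx))
        vel <- .map_params(function(v, g) cfg$momentum * v - cfg$learning_rate * g,
                           vel, grads)
        params <- .map_params(`+`, params, vel)
      }
      p_val <- .net_forward(params, Xval)$p
      val_f1 <- .threshold_metrics(yval, p_val, cfg$classification_threshold)$f1
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = loss_sum / n_tr,
                                     val_f1 = val_f1)
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= cfg$patience) break
      }
    }
  })
  net$params <- best$params
  net$best_epoch <- best$epoch
  net$history <- do.call(rbind, history)
  net$trained <- TRUE
  net
}

# Confusion-matrix metrics at a probability threshold. Empty denominators
# (no predicted or no true positives) yield 0 rather than NaN.
.threshold_metrics <- function(y, p, threshold) {
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, accuracy = (tp + tn) / length(y),
       precision = precision, recall = recall)
}

# Rank-statistic AUC with mid-rank tie handling; NA when one class is absent.
.rank_auc <- function(y, p) {
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Analytic AUC confidence interval
#'
#' The Hanley-McNeil interval: with `A` the AUC, `Q1 = A/(2-A)` and
#' `Q2 = 2A^2/(1+A)`,
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg))`,
#' and the interval is `A +/- z * SE` clipped to `[0, 1]`.
#'
#' @param auc AUC estimate, strictly inside (0, 1).
#' @param n_pos,n_neg positive and negative sample counts (>= 1).
#' @param level confidence level in (0, 1) (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
auc_confidence_interval <- function(auc, n_pos, n_neg, level = 0.95) {
  .assert(level > 0 && level < 1, "level must lie in (0, 1)")
  .assert(auc > 0 && auc < 1, "auc must lie strictly inside (0, 1)")
  .assert(n_pos >= 1 && n_neg >= 1, "sample counts must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Evaluate a classifier on a cohort subset
#'
#' Threshold metrics (F1, accuracy, precision, recall) plus rank-based AUC
#' with its analytic confidence interval. With only one outcome class the
#' AUC (and its interval) are reported as not available while the threshold
#' metrics are still computed.
#'
#' @param model object with a [predict_proba()] method.
#' @param cohort an `ehr_cohort`.
#' @param indices evaluation index vector.
#' @param threshold classification threshold (default 0.5).
#' @param level AUC confidence level (default 0.95).
#' @param split_name label stored in the report (e.g. "Test").
#' @param outcome label column (default `"y"`).
#' @return a `metrics_report` list: `f1`, `accuracy`, `precision`, `recall`,
#'   `auc`, `auc_ci`, `n_pos`, `n_neg`, `split_name`.
#' @export
evaluate <- function(model, cohort, indices, threshold = 0.5, level = 0.95,
                     split_name = "", outcome = "y") {
  .assert(length(indices) > 0, "indices must be non-empty")
  y <- cohort[[outcome]][indices]
  p <- predict_proba(model, cohort$features[indices, , drop = FALSE])
  tm <- .threshold_metrics(y, p, threshold)
  auc <- .rank_auc(y, p)
  ci <- if (is.na(auc)) {
    c(NA_real_, NA_real_)
  } else if (auc <= 0 || auc >= 1) {
    c(auc, auc)  # degenerate separation; the analytic SE is 0 at the boundary
  } else {
    auc_confidence_interval(auc, sum(y == 1L), sum(y == 0L), level)
  }
  structure(c(tm, list(auc = auc, auc_ci = ci,
                       n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                       split_name = split_name)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%-12s F1 %.3f  acc %.3f  prec %.3f  rec %.3f  AUC %s\n",
    x$split_name, x$f1, x$accuracy, x$precision, x$recall,
    if (is.na(x$auc)) "n/a"
    else sprintf("%.3f (%.3f-%.3f)", x$auc, x$auc_ci[1], x$auc_ci[2])))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(split = x$split_name, f1 = x$f1, accuracy = x$accuracy,
             precision = x$precision, recall = x$recall, auc = x$auc,
             auc_ci_low = x$auc_ci[1], auc_ci_high = x$auc_ci[2],
             n_pos = x$n_pos, n_neg = x$n_neg, stringsAsFactors = FALSE)
}
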