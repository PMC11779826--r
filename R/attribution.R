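# Finite-difference attribution of a black-box probability model: impact
# scores (first differences under a feature perturbation, averaged over the
# cohort) and pairwise interaction scores (second differences beyond the sum
# of the individual impacts). Both feature states are imposed on every
# instance, so the population score reads like a regression coefficient.

.new_score_result <- function(target, scale, per_instance,
                              ci = NULL, n_bootstrap = NULL) {
  structure(
    list(target = target, scale = scale,
         per_instance = per_instance,
         population = mean(per_instance),
         ci = ci, n_bootstrap = n_bootstrap),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  ci <- if (is.null(x$ci)) "" else sprintf(" [%.4f, %.4f]", x$ci[1], x$ci[2])
  cat(sprintf("<score_result> %s (%s scale): %.5f%s\n",
              x$target, x$scale, x$population, ci))
  invisible(x)
}

.resolve_spec <- function(cohort, feature) {
  sp <- cohort$specs[[feature]]
  .assert(!is.null(sp), "feature '", feature, "' not declared in the cohort")
  sp
}

#' Impact score of a feature on a probability model
#'
#' For each instance the feature is set to both of its states and the change
#' in model output recorded: binary features are toggled 0 to 1; continuous
#' features are increased by one perturbation unit from their observed value;
#' categorical features are moved from the reference level to each other
#' level in turn. On the `"probability"` scale the output is used directly;
#' on the `"logit"` scale its log-odds (clipped near 0/1 with a warning).
#' The population score is the mean of the per-instance scores.
#'
#' @param model object with a [predict_proba()] method (dropout-free at
#'   prediction time).
#' @param cohort an `ehr_cohort`.
#' @param feature feature name.
#' @param scale `"probability"` (default) or `"logit"`.
#' @param unit override of the continuous perturbation unit.
#' @return a `score_result`; for a categorical feature, a list of
#'   `score_result`s, one per non-reference level (targets `"feature=level"`).
#' @export
impact_score <- function(model, cohort, feature,
                         scale = c("probability", "logit"), unit = NULL) {
  scale <- match.arg(scale)
  g <- .score_transform(scale)
  sp <- .resolve_spec(cohort, feature)
  X <- cohort$features
  if (sp$kind == "binary") {
    X1 <- X; X1[[feature]] <- 1
    X0 <- X; X0[[feature]] <- 0
    s <- g(predict_proba(model, X1)) - g(predict_proba(model, X0))
    .new_score_result(feature, scale, s)
  } else if (sp$kind == "continuous") {
    u <- unit %||% sp$perturbation_unit
    Xu <- X; Xu[[feature]] <- Xu[[feature]] + u
    s <- g(predict_proba(model, Xu)) - g(predict_proba(model, X))
    .new_score_result(feature, scale, s)
  } else {
    .assert(!is.null(sp$reference_level),
            "categorical feature '", feature, "' lacks a reference level")
    Xref <- X; Xref[[feature]] <- sp$reference_level
    base <- g(predict_proba(model, Xref))
    lapply(setdiff(sp$categories, sp$reference_level), function(lev) {
      Xl <- X; Xl[[feature]] <- lev
      .new_score_result(paste0(feature, "=", lev), scale,
                        g(predict_proba(model, Xl)) - base)
    })
  }
}

#' Pairwise interaction score of two features
#'
#' The second finite difference of the (transformed) model output over
#' simultaneous changes in features `j` and `k`:
#' `g(f(both changed)) - g(f(only j)) - g(f(only k)) + g(f(neither))`,
#' averaged over all instances. "Changed" means 1 for a binary feature and
#' observed value + one perturbation unit for a continuous one; "neither"
#' means 0 for binary and the observed value for continuous. The score is
#' exactly symmetric in `(j, k)`, and vanishes for any model additive on the
#' chosen scale.
#'
#' @inheritParams impact_score
#' @param feature_j,feature_k distinct binary or continuous feature names.
#' @return a `score_result` with target `"j:k"` (alphabetical).
#' @export
interaction_score <- function(model, cohort, feature_j, feature_k,
                              scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  g <- .score_transform(scale)
  .assert(feature_j != feature_k, "interaction requires two distinct features")
  spj <- .resolve_spec(cohort, feature_j)
  spk <- .resolve_spec(cohort, feature_k)
  for (sp in list(spj, spk)) {
    .assert(sp$kind %in% c("binary", "continuous"),
            "interaction scores support binary and continuous features; '",
            sp$name, "' is ", sp$kind)
  }
  set_state <- function(X, sp, changed) {
    if (sp$kind == "binary") {
      X[[sp$name]] <- if (changed) 1 else 0
    } else if (changed) {
      X[[sp$name]] <- X[[sp$name]] + sp$perturbation_unit
    }
    X
  }
  X <- cohort$features
  f <- function(cj, ck) {
    g(predict_proba(model, set_state(set_state(X, spj, cj), spk, ck)))
  }
  s <- f(TRUE, TRUE) - f(TRUE, FALSE) - f(FALSE, TRUE) + f(FALSE, FALSE)
  .new_score_result(.pair_key(feature_j, feature_k), scale, s)
}

#' Impact scores for all features and interactions with an anchor
#'
#' Computes the impact score of every declared feature and the interaction
#' score of every other (binary/continuous) feature with the anchor
#' exposure. Results are sorted by descending population score, ties broken
#' by target name.
#'
#' @inheritParams impact_score
#' @param anchor anchor feature name (e.g. the exposure).
#' @return a list of class `score_set` with elements `impact` and
#'   `interaction`, each a list of `score_result`s.
#' @export
score_all <- function(model, cohort, anchor,
                      scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  .resolve_spec(cohort, anchor)
  impacts <- list()
  for (nm in .spec_names(cohort$specs)) {
    res <- impact_score(model, cohort, nm, scale)
    if (inherits(res, "score_result")) res <- list(res)
    impacts <- c(impacts, res)
  }
  partners <- setdiff(.spec_names(cohort$specs), anchor)
  partners <- partners[vapply(partners, function(nm)
    cohort$specs[[nm]]$kind %in% c("binary", "continuous"), TRUE)]
  interactions <- lapply(partners, function(nm)
    interaction_score(model, cohort, nm, anchor, scale))
  structure(list(impact = .sort_scores(impacts),
                 interaction = .sort_scores(interactions),
                 anchor = anchor, scale = scale),
            class = "score_set")
}

.sort_scores <- function(scores) {
  pop <- vapply(scores, `[[`, 0, "population")
  tgt <- vapply(scores, `[[`, "", "target")
  scores[order(-pop, tgt)]
}

#' Tabulate a score set (or list of score results)
#'
#' @param scores a `score_set` or list of `score_result`s.
#' @return data frame with columns `target`, `scale`, `population`,
#'   `ci_low`, `ci_high`, `n_bootstrap`.
#' @export
scores_to_df <- function(scores) {
  if (inherits(scores, "score_set")) {
    return(rbind(
      cbind(component = "impact", scores_to_df(scores$impact)),
      cbind(component = "interaction", scores_to_df(scores$interaction))))
  }
  do.call(rbind, lapply(scores, function(s) {
    data.frame(target = s$target, scale = s$scale, population = s$population,
               ci_low = if (is.null(s$ci)) NA_real_ else s$ci[1],
               ci_high = if (is.null(s$ci)) NA_real_ else s$ci[2],
               n_bootstrap = s$n_bootstrap %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> anchor '%s', %s scale\n", x$anchor, x$scale))
  print(scores_to_df(x), digits = 4)
  invisible(x)
}

# One full modelling pass: split -> RUS -> train -> score. Returns the score
# set and a flat named vector of population scores (used by the bootstrap).
.fit_and_score <- function(cohort, config, seed) {
  splits <- split_data(cohort, config$ratios, seed = derive_seed(seed, "split"))
  rus <- undersample(cohort$y, splits$train, seed = derive_seed(seed, "rus"))
  d <- ncol(build_design_matrix(cohort$specs, cohort$features))
  net <- build_network(
    net_config(input_dim = d,
               hidden_width = config$hidden_width %||% 64L,
               n_residual_blocks = config$n_residual_blocks %||% 2L,
               dropout_rate = config$dropout_rate %||% 0.25),
    seed = derive_seed(seed, "init"))
  cfg <- config$train_cfg %||% train_config()
  cfg$seed <- derive_seed(seed, "sgd")
  net <- train_network(net, cohort,
                       list(train = rus, validation = splits$validation), cfg)
  set <- score_all(net, cohort, config$anchor, config$scale %||% "probability")
  flat <- c(
    stats::setNames(vapply(set$impact, `[[`, 0, "population"),
                    paste0("impact:", vapply(set$impact, `[[`, "", "target"))),
    stats::setNames(vapply(set$interaction, `[[`, 0, "population"),
                    paste0("interaction:",
                           vapply(set$interaction, `[[`, "", "target"))))
  list(set = set, flat = flat, net = net, splits = splits, rus = rus)
}

#' Bootstrap confidence intervals for impact and interaction scores
#'
#' Percentile bootstrap over the full training pipeline: the cohort is
#' resampled with replacement `B` times; for each replicate the
#' split / under-sampling / training / scoring pipeline is re-run from
#' scratch and the population scores recorded. The confidence interval of
#' each score is the (1-level)/2 and 1-(1-level)/2 empirical percentile
#' (inverse-ECDF quantiles, so B = 2 gives the min/max) of the replicate
#' values; point estimates come from the un-resampled pipeline. A replicate
#' whose resample contains a single outcome class is redrawn (bounded
#' retries, event logged via `message()`).
#'
#' @param cohort an `ehr_cohort`.
#' @param config pipeline configuration list: `anchor`, `scale`, `ratios`,
#'   `hidden_width`, `n_residual_blocks`, `dropout_rate`, `train_cfg`.
#' @param B number of bootstrap replicates (default 200, >= 2).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; each replicate derives its own child seed, so
#'   results do not depend on execution order.
#' @param max_retries redraw cap per replicate (default 10).
#' @param point optional precomputed `score_set` from the un-resampled
#'   pipeline (e.g. the one already fitted by [run_pipeline()]); when `NULL`
#'   it is computed here with a child seed of `seed`. Supplying it decouples
#'   the point estimates from the bootstrap seed.
#' @return a `score_set` whose `score_result`s carry `ci` and `n_bootstrap`,
#'   plus an attribute `"replicates"` (B x n_targets matrix).
#' @export
bootstrap_scores <- function(cohort, config, B = 200L, level = 0.95,
                             seed = 1L, max_retries = 10L, point = NULL) {
  .assert(B >= 2, "B must be at least 2")
  .assert(level > 0 && level < 1, "level must lie in (0, 1)")
  point <- if (is.null(point)) {
    .fit_and_score(cohort, config, seed = derive_seed(seed, "point"))$set
  } else {
    .assert(inherits(point, "score_set"), "point must be a score_set")
    point
  }
  targets <- c(
    paste0("impact:", vapply(point$impact, `[[`, "", "target")),
    paste0("interaction:", vapply(point$interaction, `[[`, "", "target")))
  n <- cohort_size(cohort)
  reps <- matrix(NA_real_, nrow = B, ncol = length(targets),
                 dimnames = list(NULL, targets))
  for (b in seq_len(B)) {
    for (attempt in seq_len(max_retries)) {
      idx <- withr::with_seed(derive_seed(seed, "resample", b, attempt),
                              sample.int(n, n, replace = TRUE))
      if (length(unique(cohort$y[idx])) == 2) break
      message("bootstrap replicate ", b, ": single-class resample, redrawn")
      if (attempt == max_retries) {
        stop("bootstrap replicate ", b, " single-class after ",
             max_retries, " retries", call. = FALSE)
      }
    }
    boot <- new_cohort(
      features = cohort$features[idx, , drop = FALSE],
      y_documented = cohort$y_documented[idx],
      y_coded = cohort$y_coded[idx],
      y_true = cohort$y_true[idx],
      specs = cohort$specs, seed = NA_integer_)
    flat <- .fit_and_score(boot, config,
                           seed = derive_seed(seed, "boot", b))$flat
    reps[b, ] <- flat[targets]
  }
  alpha <- (1 - level) / 2
  fill_ci <- function(scores, prefix) {
    lapply(scores, function(s) {
      v <- reps[, paste0(prefix, s$target)]
      s$ci <- unname(stats::quantile(v, c(alpha, 1 - alpha), type = 1))
      s$n_bootstrap <- B
      s
    })
  }
  set <- point
  set$impact <- fill_ci(set$impact, "impact:")
  set$interaction <- fill_ci(set$interaction, "interaction:")
  attr(set, "replicates") <- reps
  set
}
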