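test_that("a constant model has zero impact everywhere", {
  ch <- binary_cohort(50, 3, seed = 1)
  const <- function(features) rep(0.37, nrow(features))
  for (f in c("x1", "x2", "x3")) {
    s <- impact_score(const, ch, f)
    expect_equal(s$population, 0)
    expect_equal(s$per_instance, rep(0, 50))
  }
})

test_that("closed-form impacts of simple sigmoid models are recovered exactly", {
  ch <- binary_cohort(80, 2, seed = 2)
  # f(x) = sigma(x1): probability-scale impact is sigma(1) - sigma(0)
  f1 <- function(features) plogis(features$x1)
  s <- impact_score(f1, ch, "x1", "probability")
  expect_equal(s$population, plogis(1) - plogis(0), tolerance = 1e-12)
  expect_equal(s$population, 0.2310586, tolerance = 1e-6)

  # hand-weighted 2-feature linear-sigmoid model: logit impacts equal weights
  f2 <- function(features) plogis(2 * features$x1 - 1.5 * features$x2 + 0.3)
  expect_equal(impact_score(f2, ch, "x1", "logit")$population, 2,
               tolerance = 1e-9)
  expect_equal(impact_score(f2, ch, "x2", "logit")$population, -1.5,
               tolerance = 1e-9)
  # ... and match the exhaustive enumeration oracle on both scales
  for (sc in c("probability", "logit")) {
    expect_equal(impact_score(f2, ch, "x1", sc)$population,
                 enum_impact_oracle(f2, ch, "x1", sc), tolerance = 1e-12)
  }
})

test_that("interaction scores annihilate additive models and recover bilinear terms", {
  ch <- binary_cohort(60, 2, seed = 3)
  additive <- function(features) plogis(0.8 * features$x1 + 1.1 * features$x2 - 0.2)
  expect_lt(abs(interaction_score(additive, ch, "x1", "x2", "logit")$population),
            1e-9)
  gam <- 0.6
  bilinear <- function(features) plogis(gam * features$x1 * features$x2)
  expect_equal(interaction_score(bilinear, ch, "x1", "x2", "logit")$population,
               gam, tolerance = 1e-9)
  expect_equal(interaction_score(bilinear, ch, "x1", "x2", "probability")$population,
               enum_interaction_oracle(bilinear, ch, "x1", "x2", "probability"),
               tolerance = 1e-12)
  expect_error(interaction_score(bilinear, ch, "x1", "x1"), "distinct")
})

test_that("a zero-cross-term residual network has vanishing logit interactions", {
  beta <- c(0.9, -0.6, 0.4)
  net <- linear_resnet(beta, intercept = -0.5)
  ch <- binary_cohort(40, 3, seed = 4)
  for (f in seq_along(beta)) {
    expect_equal(impact_score(net, ch, paste0("x", f), "logit")$population,
                 beta[f], tolerance = 1e-8)
  }
  expect_lt(abs(interaction_score(net, ch, "x1", "x2", "logit")$population),
            1e-9)
  expect_lt(abs(interaction_score(net, ch, "x1", "x3", "logit")$population),
            1e-9)
})

test_that("population scores equal enumeration oracles for a fixed-weight network", {
  d <- 10L
  ch <- binary_cohort(300, d, seed = 5)
  net <- build_network(net_config(d, hidden_width = 16), seed = 6)
  net$specs <- ch$specs
  net$feature_names <- paste0("x", 1:d)
  for (f in c("x1", "x5", "x10")) {
    expect_equal(impact_score(net, ch, f, "probability")$population,
                 enum_impact_oracle(net, ch, f, "probability"),
                 tolerance = 1e-12)
  }
  for (pair in list(c("x1", "x2"), c("x3", "x9"))) {
    expect_equal(
      interaction_score(net, ch, pair[1], pair[2], "probability")$population,
      enum_interaction_oracle(net, ch, pair[1], pair[2], "probability"),
      tolerance = 1e-12)
  }
})

test_that("interaction scores are exactly symmetric and population = mean(per-instance)", {
  d <- 4L
  ch <- binary_cohort(120, d, seed = 7)
  net <- build_network(net_config(d, hidden_width = 8), seed = 8)
  net$specs <- ch$specs
  net$feature_names <- paste0("x", 1:d)
  s_jk <- interaction_score(net, ch, "x2", "x3", "probability")
  s_kj <- interaction_score(net, ch, "x3", "x2", "probability")
  expect_identical(s_jk$per_instance, s_kj$per_instance)
  expect_identical(s_jk$target, s_kj$target)
  expect_identical(s_jk$population, mean(s_jk$per_instance))
  imp <- impact_score(net, ch, "x1", "probability")
  expect_identical(imp$population, mean(imp$per_instance))
})

test_that("probability- and logit-scale impacts agree in sign for a monotone model", {
  net <- linear_resnet(c(1.2, -0.7), intercept = 0.1)
  ch <- binary_cohort(100, 2, seed = 9)
  for (f in c("x1", "x2")) {
    sp <- impact_score(net, ch, f, "probability")$population
    sl <- impact_score(net, ch, f, "logit")$population
    expect_equal(sign(sp), sign(sl))
  }
})

test_that("categorical impacts are reported per non-reference level", {
  withr::with_seed(10, {
    n <- 60
    feats <- data.frame(
      race = sample(c("white", "black", "other"), n, replace = TRUE),
      x = rbinom(n, 1, 0.5))
    specs <- list(
      feature_spec("race", "categorical",
                   categories = c("white", "black", "other"),
                   reference_level = "white"),
      feature_spec("x", "binary"))
    ch <- new_cohort(feats, y_documented = rbinom(n, 1, 0.4),
                     y_coded = integer(n), specs = specs)
    model <- function(features) {
      plogis(0.5 * (features$race == "black") -
               0.25 * (features$race == "other") + 0.3 * features$x)
    }
    res <- impact_score(model, ch, "race", "logit")
    expect_length(res, 2)
    targets <- vapply(res, `[[`, "", "target")
    pops <- vapply(res, `[[`, 0, "population")
    expect_setequal(targets, c("race=black", "race=other"))
    expect_equal(unname(pops[match("race=black", targets)]), 0.5,
                 tolerance = 1e-9)
    expect_equal(unname(pops[match("race=other", targets)]), -0.25,
                 tolerance = 1e-9)
    expect_error(interaction_score(model, ch, "race", "x"), "categorical")
  })
})

test_that("saturated model outputs are clipped with a warning on the logit scale", {
  ch <- binary_cohort(10, 2, seed = 11)
  hard <- function(features) as.numeric(features$x1 >= 0.5)
  w <- capture_warnings(s <- impact_score(hard, ch, "x1", "logit"))
  expect_true(any(grepl("clipped", w)))
  expect_true(all(is.finite(s$per_instance)))
})

test_that("score_all covers every feature, interactions with the anchor, sorted", {
  d <- 5L
  ch <- binary_cohort(80, d, seed = 12)
  net <- build_network(net_config(d, hidden_width = 8), seed = 13)
  net$specs <- ch$specs
  net$feature_names <- paste0("x", 1:d)
  set <- score_all(net, ch, anchor = "x3")
  expect_length(set$impact, d)
  expect_length(set$interaction, d - 1L)
  expect_true("x3" %in% vapply(set$impact, `[[`, "", "target"))
  expect_false(any(grepl("x3:x3", vapply(set$interaction, `[[`, "", "target"))))
  pops <- vapply(set$impact, `[[`, 0, "population")
  expect_true(all(diff(pops) <= 0))
  df <- scores_to_df(set)
  expect_setequal(unique(df$component), c("impact", "interaction"))
})

test_that("bootstrap CIs are the replicate percentiles, with B = 2 the min/max", {
  ch <- generate_cohort(big_default_model(), 1200, seed = 30)
  config <- list(anchor = "dual_use", scale = "probability",
                 ratios = c(0.64, 0.16, 0.20), hidden_width = 8L,
                 train_cfg = train_config(max_epochs = 6, patience = 3,
                                          seed = 1))
  set <- bootstrap_scores(ch, config, B = 2, seed = 5)
  reps <- attr(set, "replicates")
  expect_equal(dim(reps), c(2L, length(set$impact) + length(set$interaction)))
  for (s in c(set$impact, set$interaction)) {
    v <- reps[, paste0(if (s$target %in% names(ch$specs)) "impact:"
                       else "interaction:", s$target)]
    expect_equal(s$ci, c(min(v), max(v)))
    expect_equal(s$n_bootstrap, 2L)
  }
  # defaults follow the standard protocol: 200 replicates at the 95% level
  expect_equal(eval(formals(bootstrap_scores)$B), 200L)
  expect_equal(eval(formals(bootstrap_scores)$level), 0.95)
})

test_that("a null feature's bootstrap interval straddles zero", {
  m <- big_default_model()
  ch <- generate_cohort(m, 1500, seed = 31)
  # replace a planted feature with pure noise, independent of the outcome
  ch$features$female <- withr::with_seed(32, rbinom(1500, 1L, 0.5))
  config <- list(anchor = "dual_use", scale = "probability",
                 ratios = c(0.64, 0.16, 0.20), hidden_width = 8L,
                 train_cfg = train_config(max_epochs = 8, patience = 4,
                                          seed = 2))
  set <- bootstrap_scores(ch, config, B = 8, seed = 6)
  fem <- Filter(function(s) s$target == "female", set$impact)[[1]]
  expect_lt(fem$ci[1], 0)
  expect_gt(fem$ci[2], 0)
})
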