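# Shared fixtures and independent oracles, all built in code.

# Memoized large default-scenario cohort (used by several Monte-Carlo checks).
.fixture_env <- new.env(parent = emptyenv())

big_default_cohort <- function() {
  if (is.null(.fixture_env$big)) {
    m <- calibrate_model(default_scenario(), seed = 7)
    .fixture_env$big_model <- m
    .fixture_env$big <- generate_cohort(m, 100000, seed = 8)
  }
  .fixture_env$big
}

big_default_model <- function() {
  invisible(big_default_cohort())
  .fixture_env$big_model
}

# Small all-binary cohort with d features, uniform random values.
binary_cohort <- function(n, d, seed = 1, prevalence = 0.4) {
  withr::with_seed(seed, {
    feats <- as.data.frame(stats::setNames(
      lapply(seq_len(d), function(j) stats::rbinom(n, 1L, 0.5)),
      paste0("x", seq_len(d))))
    y <- stats::rbinom(n, 1L, prevalence)
    new_cohort(feats, y_documented = y, y_coded = integer(n),
               specs = lapply(paste0("x", seq_len(d)), feature_spec,
                              kind = "binary"))
  })
}

# A residual network that computes an exact logistic model sigma(b + x'beta):
# the stem embeds the inputs shifted by a large constant so every hidden unit
# stays positive, all block weights are zeroed (each block reduces to
# relu(identity)), and the head undoes the shift.
linear_resnet <- function(beta, intercept = 0, hidden_width = NULL) {
  d <- length(beta)
  h <- hidden_width %||% max(d, 2L)
  shift <- 1000
  net <- build_network(net_config(d, hidden_width = h,
                                  n_residual_blocks = 2L, dropout_rate = 0),
                       seed = 1)
  zero <- function(x) x * 0
  net$params <- rapply(net$params, zero, how = "replace")
  W0 <- matrix(0, d, h)
  for (j in seq_len(d)) W0[j, j] <- 1
  net$params$W0 <- W0
  net$params$b0 <- rep(shift, h)
  w <- numeric(h)
  w[seq_len(d)] <- beta
  net$params$w <- w
  net$params$b <- intercept - shift * sum(beta)
  net
}

# Exhaustive-enumeration oracle for population scores on all-binary cohorts:
# enumerate the distinct observed feature patterns with their frequencies and
# recompute the finite differences per pattern.
enum_impact_oracle <- function(model, cohort, feature, scale) {
  g <- if (scale == "logit") stats::qlogis else identity
  feats <- cohort$features
  pat <- do.call(paste, c(feats, sep = "|"))
  tab <- table(pat)
  levels_df <- unique(feats)
  key <- do.call(paste, c(levels_df, sep = "|"))
  total <- 0
  for (i in seq_len(nrow(levels_df))) {
    row <- levels_df[i, , drop = FALSE]
    r1 <- row; r1[[feature]] <- 1
    r0 <- row; r0[[feature]] <- 0
    s <- g(predict_proba(model, r1)) - g(predict_proba(model, r0))
    total <- total + s * tab[[key[i]]]
  }
  total / nrow(feats)
}

enum_interaction_oracle <- function(model, cohort, fj, fk, scale) {
  g <- if (scale == "logit") stats::qlogis else identity
  feats <- cohort$features
  pat <- do.call(paste, c(feats, sep = "|"))
  tab <- table(pat)
  levels_df <- unique(feats)
  key <- do.call(paste, c(levels_df, sep = "|"))
  total <- 0
  for (i in seq_len(nrow(levels_df))) {
    corner <- function(vj, vk) {
      row <- levels_df[i, , drop = FALSE]
      row[[fj]] <- vj; row[[fk]] <- vk
      g(predict_proba(model, row))
    }
    s <- corner(1, 1) - corner(1, 0) - corner(0, 1) + corner(0, 0)
    total <- total + s * tab[[key[i]]]
  }
  total / nrow(feats)
}

# Brute-force pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie).
pairwise_auc <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Separable two-cloud toy cohort for training checks.
toy_cloud_cohort <- function(n = 2000, gap = 2, seed = 42) {
  withr::with_seed(seed, {
    y <- stats::rbinom(n, 1L, 0.5)
    f1 <- stats::rnorm(n, mean = ifelse(y == 1, gap, -gap))
    f2 <- stats::rnorm(n, mean = ifelse(y == 1, gap, -gap))
    new_cohort(data.frame(f1 = f1, f2 = f2),
               y_documented = y, y_coded = integer(n),
               specs = list(feature_spec("f1", "continuous"),
                            feature_spec("f2", "continuous")))
  })
}
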