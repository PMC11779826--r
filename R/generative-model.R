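# Synthetic EHR cohort model: a logistic outcome over typed features with
# planted pairwise interactions, an exposure sub-model, a shared latent
# comorbidity liability, and a two-source measurement-error process for the
# outcome label (note-derived and code-derived).

# Logistic-normal marginalization constant: E[sigma(a + Z)], Z ~ N(0, s^2),
# is well approximated by sigma(a / sqrt(1 + c^2 s^2)) with c = 16*sqrt(3)/(15*pi).
.ln_c2 <- (16 * sqrt(3) / (15 * pi))^2

#' Specify a generative cohort model
#'
#' Defines the joint distribution of an EHR-like cohort: marginal feature
#' distributions, an exposure logistic sub-model (so the exposed are e.g.
#' younger and more comorbid), a shared latent liability inducing comorbidity
#' co-occurrence, a logistic outcome model with main effects `beta` and
#' pairwise interactions `gamma` on the log-odds scale, and label-noise
#' parameters producing two imperfect outcome labels from the latent truth.
#'
#' @param feature_specs list of [feature_spec()] objects.
#' @param marginal_params named list, one entry per feature:
#'   `list(prevalence=)` for binary, `list(mean=, sd=, lower=, upper=)` for
#'   continuous (truncated normal), `list(proportions=)` (named vector) for
#'   categorical.
#' @param dependence_params list with elements `exposure_feature` (name of the
#'   binary exposure), `exposure_coef` (named log-odds coefficients of other
#'   features in the exposure sub-model; continuous features enter
#'   standardized), `exposure_latent_coef` (log-odds per unit latent
#'   liability), and `latent_loadings` (named log-odds loadings of binary
#'   features on the shared liability).
#' @param beta named numeric of main-effect log-odds; names must be design
#'   columns (feature names, or `"feature=level"` for categorical levels).
#' @param gamma named numeric of interaction log-odds; names are unordered
#'   design-column pairs written `"a:b"` (alphabetical).
#' @param target_prevalence latent outcome prevalence in (0, 1) that
#'   [calibrate_intercept()] hits by tuning `beta0`.
#' @param label_noise list with `documented_sensitivity`,
#'   `documented_specificity` (operating characteristics of the note-derived
#'   label against the latent truth) and `coded_given_true` (probability a
#'   true case carries the code-derived label).
#' @param beta0 logistic intercept; `NA` until calibrated.
#' @param exclude_prior_outcome fraction in `[0, 1)` of true cases dropped
#'   after generation, mimicking a sensitivity analysis that removes
#'   prevalent cases.
#' @return an object of class `generative_model`.
#' @export
generative_model <- function(feature_specs, marginal_params,
                             dependence_params = list(),
                             beta, gamma = numeric(),
                             target_prevalence,
                             label_noise = list(documented_sensitivity = 1,
                                                documented_specificity = 1,
                                                coded_given_true = 1),
                             beta0 = NA_real_,
                             exclude_prior_outcome = 0) {
  specs <- .validate_specs(feature_specs)
  nms <- .spec_names(specs)
  .assert(all(nms %in% names(marginal_params)),
          "marginal_params must cover every feature")
  .assert(is.numeric(target_prevalence) &&
            target_prevalence > 0 && target_prevalence < 1,
          "target_prevalence must lie in (0, 1)")
  .assert(label_noise$documented_sensitivity > 0 &&
            label_noise$documented_sensitivity <= 1 &&
            label_noise$documented_specificity > 0 &&
            label_noise$documented_specificity <= 1,
          "sensitivity/specificity must lie in (0, 1]")
  .assert(label_noise$coded_given_true >= 0 && label_noise$coded_given_true <= 1,
          "coded_given_true must lie in [0, 1]")
  design_names <- colnames(build_design_matrix(specs, .probe_row(specs)))
  .assert(all(names(beta) %in% design_names),
          "beta names must be design columns")
  if (length(gamma)) {
    parts <- strsplit(names(gamma), ":", fixed = TRUE)
    for (p in parts) {
      .assert(length(p) == 2 && all(p %in% design_names),
              "gamma keys must pair two declared design columns")
    }
    canon <- vapply(parts, function(p) .pair_key(p[1], p[2]), "")
    names(gamma) <- canon
    .assert(!anyDuplicated(canon), "duplicate gamma pair")
  }
  if (length(dependence_params)) {
    ef <- dependence_params$exposure_feature
    if (!is.null(ef)) .assert(ef %in% nms && specs[[ef]]$kind == "binary",
                              "exposure_feature must be a declared binary feature")
  }
  .assert(exclude_prior_outcome >= 0 && exclude_prior_outcome < 1,
          "exclude_prior_outcome must lie in [0, 1)")
  structure(
    list(feature_specs = specs, marginal_params = marginal_params,
         dependence_params = dependence_params,
         beta0 = beta0, beta = beta, gamma = gamma,
         target_prevalence = target_prevalence,
         label_noise = label_noise,
         exclude_prior_outcome = exclude_prior_outcome),
    class = "generative_model"
  )
}

# A single syntactically valid feature row, used to learn design column names.
.probe_row <- function(specs) {
  row <- lapply(specs, function(sp) {
    switch(sp$kind, binary = 0, continuous = 0,
           categorical = sp$reference_level)
  })
  as.data.frame(stats::setNames(row, .spec_names(specs)),
                stringsAsFactors = FALSE)
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(
    "<generative_model> %d features, %d interactions, target prevalence %.3f, beta0 %s\n",
    length(x$feature_specs), length(x$gamma), x$target_prevalence,
    if (is.na(x$beta0)) "uncalibrated" else sprintf("%.4f", x$beta0)
  ))
  invisible(x)
}

#' Default EHR-like scenario
#'
#' A ready-made generative model emulating a veteran outpatient cohort with a
#' rare-ish substance-use outcome: a continuous age (mean 61, SD 16, truncated
#' to 18-100 years, negatively associated with the outcome), a binary
#' dual-system-use exposure near 9% prevalence concentrated among younger,
#' female and more comorbid patients, correlated binary substance-use and
#' mental-health comorbidities at realistic prevalences with positive main
#' effects, a planted positive age-by-exposure interaction and negative
#' PTSD-by-exposure and other-drug-by-exposure interactions, a latent outcome
#' prevalence of 17%, and two noisy outcome labels: a note-derived label with
#' 88.4% sensitivity / 96.6% specificity and a code-derived label carried by
#' 11.3% of true cases (so the coded label badly under-counts the outcome).
#'
#' The intercept `beta0` is left uncalibrated; call [calibrate_model()] (or
#' [calibrate_intercept()]) before generating cohorts.
#'
#' @param gamma_scale multiplier on all planted interaction coefficients;
#'   set to 0 for a purely additive scenario.
#' @return a `generative_model`.
#' @export
default_scenario <- function(gamma_scale = 1) {
  specs <- list(
    feature_spec("age", "continuous", perturbation_unit = 1),
    feature_spec("dual_use", "binary"),
    feature_spec("female", "binary"),
    feature_spec("prior_opioid", "binary"),
    feature_spec("alcohol_disorder", "binary"),
    feature_spec("other_drug_disorder", "binary"),
    feature_spec("ptsd", "binary"),
    feature_spec("tobacco_disorder", "binary")
  )
  marginals <- list(
    age = list(mean = 61, sd = 16, lower = 18, upper = 100),
    dual_use = list(prevalence = 0.09),
    female = list(prevalence = 0.143),
    prior_opioid = list(prevalence = 0.509),
    alcohol_disorder = list(prevalence = 0.185),
    other_drug_disorder = list(prevalence = 0.140),
    ptsd = list(prevalence = 0.204),
    tobacco_disorder = list(prevalence = 0.268)
  )
  dependence <- list(
    exposure_feature = "dual_use",
    exposure_coef = c(age = -0.35, female = 0.30),
    exposure_latent_coef = 0.30,
    latent_loadings = c(prior_opioid = 0.40, alcohol_disorder = 0.80,
                        other_drug_disorder = 0.80, ptsd = 0.60,
                        tobacco_disorder = 0.80)
  )
  beta <- c(age = -0.035, dual_use = 0.74, female = 0.10,
            prior_opioid = 0.80, alcohol_disorder = 1.20,
            other_drug_disorder = 1.60, ptsd = 0.60,
            tobacco_disorder = 0.90)
  gamma <- gamma_scale * c("age:dual_use" = 0.03,
                           "dual_use:ptsd" = -0.80,
                           "dual_use:other_drug_disorder" = -0.80)
  generative_model(
    feature_specs = specs, marginal_params = marginals,
    dependence_params = dependence,
    beta = beta, gamma = gamma,
    target_prevalence = 0.17,
    label_noise = list(documented_sensitivity = 0.884,
                       documented_specificity = 0.966,
                       coded_given_true = 0.113)
  )
}

# Sample the feature table (no labels). Order of draws is fixed so that a
# given seed always yields the same table: latent liability, continuous
# features, plain binaries, exposure, liability-loaded binaries.
.sample_features <- function(model, n) {
  specs <- model$feature_specs
  dep <- model$dependence_params
  loadings <- dep$latent_loadings %||% numeric()
  exposure <- dep$exposure_feature
  L <- stats::rnorm(n)
  out <- vector("list", length(specs))
  names(out) <- .spec_names(specs)

  cont_std <- list()  # standardized continuous columns for the exposure model
  for (sp in specs) {
    mp <- model$marginal_params[[sp$name]]
    if (sp$kind == "continuous") {
      lo <- stats::pnorm(mp$lower %||% -Inf, mp$mean, mp$sd)
      hi <- stats::pnorm(mp$upper %||% Inf, mp$mean, mp$sd)
      u <- stats::runif(n, lo, hi)
      out[[sp$name]] <- stats::qnorm(u, mp$mean, mp$sd)
      cont_std[[sp$name]] <- (out[[sp$name]] - mp$mean) / mp$sd
    } else if (sp$kind == "categorical") {
      out[[sp$name]] <- sample(names(mp$proportions), n, replace = TRUE,
                               prob = mp$proportions)
    } else if (!identical(sp$name, exposure) &&
               !(sp$name %in% names(loadings))) {
      out[[sp$name]] <- stats::rbinom(n, 1L, mp$prevalence)
    }
  }
  if (!is.null(exposure)) {
    mp <- model$marginal_params[[exposure]]
    co <- dep$exposure_coef %||% numeric()
    lc <- dep$exposure_latent_coef %||% 0
    lp <- rep(0, n); s2 <- lc^2
    for (nm in names(co)) {
      sp <- specs[[nm]]
      if (sp$kind == "continuous") {
        lp <- lp + co[[nm]] * cont_std[[nm]]
        s2 <- s2 + co[[nm]]^2
      } else {
        p <- model$marginal_params[[nm]]$prevalence
        lp <- lp + co[[nm]] * out[[nm]]
        s2 <- s2 + co[[nm]]^2 * p * (1 - p)
      }
    }
    a0 <- stats::qlogis(mp$prevalence) * sqrt(1 + .ln_c2 * s2)
    out[[exposure]] <- stats::rbinom(n, 1L, .sigmoid(a0 + lp + lc * L))
  }
  for (nm in names(loadings)) {
    mp <- model$marginal_params[[nm]]
    a0 <- stats::qlogis(mp$prevalence) * sqrt(1 + .ln_c2 * loadings[[nm]]^2)
    out[[nm]] <- stats::rbinom(n, 1L, .sigmoid(a0 + loadings[[nm]] * L))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Linear predictor of the latent outcome, excluding the intercept.
# Interaction products use mean-centered continuous columns so that main
# effects keep their interpretation at the cohort average (the second
# difference of the logit over any pair still equals gamma exactly).
.outcome_eta <- function(model, features) {
  D <- build_design_matrix(model$feature_specs, features)
  eta <- drop(D[, names(model$beta), drop = FALSE] %*% model$beta)
  centered <- function(col) {
    sp <- model$feature_specs[[col]]
    if (!is.null(sp) && sp$kind == "continuous") {
      D[, col] - model$marginal_params[[col]]$mean
    } else {
      D[, col]
    }
  }
  for (key in names(model$gamma)) {
    p <- strsplit(key, ":", fixed = TRUE)[[1]]
    eta <- eta + model$gamma[[key]] * centered(p[1]) * centered(p[2])
  }
  eta
}

#' Calibrate the outcome intercept to the target prevalence
#'
#' Finds `beta0` such that the expected latent outcome prevalence over a probe
#' sample of features equals `target_prevalence`, by bisection on the mean of
#' the logistic response. Deterministic given the seed.
#'
#' @param model a `generative_model`.
#' @param n_probe probe sample size (at least 10,000).
#' @param seed integer seed for the probe features.
#' @param tol prevalence tolerance (default 1e-4, i.e. 0.01 percentage point).
#' @param max_iter bisection iteration cap.
#' @return the calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(model, n_probe = 50000L, seed = 1L,
                                tol = 1e-4, max_iter = 200L) {
  .assert(inherits(model, "generative_model"), "model must be a generative_model")
  .assert(n_probe >= 10000, "n_probe must be at least 10,000")
  eta <- withr::with_seed(seed, .sample_features(model, n_probe))
  eta <- .outcome_eta(model, eta)
  f <- function(b0) mean(.sigmoid(b0 + eta)) - model$target_prevalence
  lo <- -30; hi <- 30
  .assert(f(lo) < 0 && f(hi) > 0, "calibration error: target not bracketed")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  stop("calibration error: bisection did not converge within ", max_iter,
       " iterations", call. = FALSE)
}

#' @rdname calibrate_intercept
#' @return `calibrate_model()` returns the model with `beta0` set.
#' @export
calibrate_model <- function(model, n_probe = 50000L, seed = 1L, ...) {
  model$beta0 <- calibrate_intercept(model, n_probe = n_probe, seed = seed, ...)
  model
}

#' Read or write a generative model configuration file
#'
#' The model is serialized as a structured JSON or YAML document (chosen by
#' file extension) holding the feature specs, marginal and dependence
#' parameters, effect sizes, interaction terms, prevalence target and label
#' noise. Files are validated on read through [generative_model()].
#'
#' @param model a `generative_model`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_model_config()` returns a `generative_model`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  dep <- model$dependence_params
  for (nm in c("exposure_coef", "latent_loadings")) {
    if (!is.null(dep[[nm]])) dep[[nm]] <- as.list(dep[[nm]])
  }
  obj <- list(
    feature_specs = .specs_to_list(model$feature_specs),
    marginal_params = model$marginal_params,
    dependence_params = dep,
    beta0 = if (is.na(model$beta0)) NULL else model$beta0,
    beta = as.list(model$beta),
    gamma = as.list(model$gamma),
    target_prevalence = model$target_prevalence,
    label_noise = model$label_noise,
    exclude_prior_outcome = model$exclude_prior_outcome
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  dep <- obj$dependence_params %||% list()
  for (nm in c("exposure_coef", "latent_loadings")) {
    if (!is.null(dep[[nm]])) dep[[nm]] <- unlist(dep[[nm]])
  }
  generative_model(
    feature_specs = .specs_from_list(obj$feature_specs),
    marginal_params = obj$marginal_params,
    dependence_params = dep,
    beta = unlist(obj$beta),
    gamma = if (length(obj$gamma)) unlist(obj$gamma) else numeric(),
    target_prevalence = obj$target_prevalence,
    label_noise = obj$label_noise,
    beta0 = obj$beta0 %||% NA_real_,
    exclude_prior_outcome = obj$exclude_prior_outcome %||% 0
  )
}
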