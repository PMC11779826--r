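#' Generate a synthetic cohort
#'
#' Draws `n` instances from a calibrated generative model: features with the
#' configured marginals and dependence structure, a latent true outcome
#' `y_true ~ Bernoulli(sigma(beta0 + sum(beta x) + sum(gamma x x)))`, a
#' note-derived label `y_documented` obtained from `y_true` through the
#' configured sensitivity/specificity, a code-derived label `y_coded` drawn
#' among true cases only, and the analysis outcome `y = y_documented | y_coded`.
#'
#' @param model a calibrated `generative_model` (see [calibrate_model()]).
#' @param n number of instances (>= 1).
#' @param seed integer seed; identical `(model, n, seed)` gives an identical
#'   cohort.
#' @return an object of class `ehr_cohort`: a list with `features` (data
#'   frame), label vectors `y`, `y_documented`, `y_coded`, `y_true`, the
#'   feature `specs` and the `seed`.
#' @export
generate_cohort <- function(model, n, seed) {
  .assert(inherits(model, "generative_model"), "model must be a generative_model")
  .assert(!is.na(model$beta0),
          "model is uncalibrated: set beta0 via calibrate_model() first")
  .assert(is.numeric(n) && n >= 1, "n must be a positive count")
  n <- as.integer(n)
  noise <- model$label_noise
  res <- withr::with_seed(seed, {
    features <- .sample_features(model, n)
    p_true <- .sigmoid(model$beta0 + .outcome_eta(model, features))
    y_true <- stats::rbinom(n, 1L, p_true)
    p_doc <- ifelse(y_true == 1L, noise$documented_sensitivity,
                    1 - noise$documented_specificity)
    y_documented <- stats::rbinom(n, 1L, p_doc)
    y_coded <- integer(n)
    pos <- which(y_true == 1L)
    if (length(pos)) {
      y_coded[pos] <- stats::rbinom(length(pos), 1L, noise$coded_given_true)
    }
    keep <- seq_len(n)
    if (model$exclude_prior_outcome > 0 && length(pos)) {
      drop_n <- floor(model$exclude_prior_outcome * length(pos))
      if (drop_n > 0) keep <- setdiff(keep, sample(pos, drop_n))
    }
    list(features = features[keep, , drop = FALSE],
         y_true = y_true[keep], y_documented = y_documented[keep],
         y_coded = y_coded[keep])
  })
  rownames(res$features) <- NULL
  new_cohort(features = res$features,
             y_documented = res$y_documented,
             y_coded = res$y_coded,
             y_true = res$y_true,
             specs = model$feature_specs,
             seed = seed)
}

#' Construct a cohort object
#'
#' @param features data frame of raw feature columns matching `specs`.
#' @param y_documented,y_coded binary label vectors; the analysis outcome is
#'   their element-wise OR.
#' @param y_true optional latent truth (synthetic cohorts only).
#' @param specs list of [feature_spec()] objects.
#' @param seed optional integer provenance seed.
#' @return an `ehr_cohort`.
#' @export
new_cohort <- function(features, y_documented, y_coded, y_true = NULL,
                       specs, seed = NA_integer_) {
  specs <- .validate_specs(specs)
  n <- nrow(features)
  for (nm in c("y_documented", "y_coded")) {
    v <- get(nm)
    .assert(length(v) == n && all(v %in% c(0L, 1L)),
            nm, " must be a binary vector of length n")
  }
  if (!is.null(y_true)) {
    .assert(length(y_true) == n && all(y_true %in% c(0L, 1L)),
            "y_true must be a binary vector of length n")
  }
  .assert(!anyNA(features), "features must have no missing values")
  for (sp in specs) {
    x <- features[[sp$name]]
    .assert(!is.null(x), "feature column '", sp$name, "' missing")
    if (sp$kind == "binary") {
      .assert(all(x %in% c(0, 1)),
              "binary feature '", sp$name, "' has values outside {0,1}")
    }
    if (sp$kind == "categorical") {
      .assert(all(x %in% sp$categories),
              "categorical feature '", sp$name, "' has undeclared levels")
    }
  }
  structure(
    list(features = features,
         y = as.integer(y_documented | y_coded),
         y_documented = as.integer(y_documented),
         y_coded = as.integer(y_coded),
         y_true = if (is.null(y_true)) NULL else as.integer(y_true),
         specs = specs, seed = seed),
    class = "ehr_cohort"
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf(
    "<ehr_cohort> %d instances, %d features; outcome prevalence %.1f%% (documented %.1f%%, coded %.1f%%)\n",
    nrow(x$features), length(x$specs), 100 * mean(x$y),
    100 * mean(x$y_documented), 100 * mean(x$y_coded)))
  invisible(x)
}

#' Number of instances in a cohort
#' @param cohort an `ehr_cohort`.
#' @return integer count.
#' @export
cohort_size <- function(cohort) nrow(cohort$features)

.label_cols <- c("y", "y_documented", "y_coded")

#' Write / read a cohort as CSV plus a JSON side-car
#'
#' The CSV holds one instance per row with the feature columns followed by
#' the label columns (`y_true` if present, `y_documented`, `y_coded`, `y`),
#' UTF-8, `"."` decimal separator, no index column. Feature metadata (the
#' specs) and the provenance seed go to a JSON side-car named
#' `<path-sans-ext>_specs.json`. Reading validates the file: unknown columns,
#' missing cells (reported with row and column) and non-binary label values
#' are errors.
#'
#' @param cohort an `ehr_cohort`.
#' @param path CSV file path.
#' @param specs optional list of [feature_spec()]; when `NULL`, read from the
#'   side-car.
#' @return `read_cohort()` returns an `ehr_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$features
  if (!is.null(cohort$y_true)) df$y_true <- cohort$y_true
  df$y_documented <- cohort$y_documented
  df$y_coded <- cohort$y_coded
  df$y <- cohort$y
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- .sidecar_path(path)
  jsonlite::write_json(
    list(feature_specs = .specs_to_list(cohort$specs),
         seed = if (is.na(cohort$seed)) NULL else cohort$seed),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_specs.json")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, specs = NULL) {
  if (is.null(specs)) {
    sidecar <- .sidecar_path(path)
    .assert(file.exists(sidecar),
            "no specs given and side-car not found: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    specs <- .specs_from_list(meta$feature_specs)
    seed <- meta$seed %||% NA_integer_
  } else {
    specs <- .validate_specs(specs)
    seed <- NA_integer_
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  expected <- c(.spec_names(specs), "y_true", .label_cols)
  unknown <- setdiff(names(df), expected)
  .assert(length(unknown) == 0,
          "format error: unknown column(s) ", paste(unknown, collapse = ", "))
  missing <- setdiff(c(.spec_names(specs), "y_documented", "y_coded"), names(df))
  .assert(length(missing) == 0,
          "format error: missing column(s) ", paste(missing, collapse = ", "))
  na_idx <- which(is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(na_idx)) {
    stop(sprintf("format error: missing cell at row %d, column '%s'",
                 na_idx[1, 1], names(df)[na_idx[1, 2]]), call. = FALSE)
  }
  for (lc in intersect(c("y_true", .label_cols), names(df))) {
    bad <- which(!(df[[lc]] %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf(
        "format error: non-binary outcome value %s at row %d, column '%s'",
        df[[lc]][bad[1]], bad[1], lc), call. = FALSE)
    }
  }
  cohort <- new_cohort(
    features = df[, .spec_names(specs), drop = FALSE],
    y_documented = df$y_documented, y_coded = df$y_coded,
    y_true = df[["y_true"]], specs = specs, seed = seed)
  if ("y" %in% names(df)) {
    .assert(all(cohort$y == df$y),
            "format error: y column inconsistent with y_documented | y_coded")
  }
  cohort
}
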