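#' Declare a cohort feature
#'
#' A feature specification records the name and kind of a predictor together
#' with the information needed to perturb it during attribution: the category
#' levels and reference level for categorical features, and the perturbation
#' unit (the "one-unit increase" used by impact scoring) for continuous ones.
#'
#' @param name feature name, unique within a cohort.
#' @param kind one of `"binary"`, `"continuous"`, `"categorical"`.
#' @param categories character vector of level names (categorical only,
#'   at least two).
#' @param reference_level the baseline level (categorical only); must be one
#'   of `categories`.
#' @param perturbation_unit positive step used for continuous perturbations
#'   (e.g. 1 year for age). Ignored for other kinds.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name,
                         kind = c("binary", "continuous", "categorical"),
                         categories = NULL,
                         reference_level = NULL,
                         perturbation_unit = NULL) {
  kind <- match.arg(kind)
  .assert(is.character(name) && length(name) == 1 && nzchar(name),
          "feature name must be a non-empty string")
  if (kind == "categorical") {
    .assert(length(categories) >= 2,
            "categorical feature '", name, "' needs at least 2 categories")
    .assert(!is.null(reference_level) && reference_level %in% categories,
            "reference_level of '", name, "' must be one of its categories")
  }
  if (kind == "continuous") {
    perturbation_unit <- perturbation_unit %||% 1
    .assert(is.numeric(perturbation_unit) && perturbation_unit > 0,
            "perturbation_unit of '", name, "' must be > 0")
  }
  structure(
    list(name = name, kind = kind,
         categories = categories, reference_level = reference_level,
         perturbation_unit = perturbation_unit),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  extra <- switch(x$kind,
    continuous = sprintf(" (unit %g)", x$perturbation_unit),
    categorical = sprintf(" (%s; ref %s)",
                          paste(x$categories, collapse = "/"),
                          x$reference_level),
    "")
  cat(sprintf("<feature_spec> %s: %s%s\n", x$name, x$kind, extra))
  invisible(x)
}

.validate_specs <- function(specs) {
  .assert(length(specs) >= 1, "at least one feature spec is required")
  for (sp in specs) .assert(inherits(sp, "feature_spec"),
                            "all elements must be feature_spec objects")
  nms <- vapply(specs, `[[`, "", "name")
  .assert(!anyDuplicated(nms), "feature names must be unique")
  stats::setNames(specs, nms)
}

.spec_names <- function(specs) vapply(specs, `[[`, "", "name")

# Expand a feature table into a numeric design matrix. Binary and continuous
# features map to one column under their own name; categorical features map
# to one indicator column per non-reference level, named "feature=level".
#' Build the numeric design matrix for a set of feature specs
#'
#' @param specs list of [feature_spec()] objects.
#' @param features data frame of raw feature columns.
#' @return numeric matrix with one column per design term.
#' @export
build_design_matrix <- function(specs, features) {
  specs <- .validate_specs(specs)
  cols <- list()
  for (sp in specs) {
    x <- features[[sp$name]]
    .assert(!is.null(x), "feature '", sp$name, "' missing from table")
    if (sp$kind == "categorical") {
      for (lev in setdiff(sp$categories, sp$reference_level)) {
        cols[[paste0(sp$name, "=", lev)]] <- as.numeric(x == lev)
      }
    } else {
      cols[[sp$name]] <- as.numeric(x)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  mat
}

.specs_to_list <- function(specs) {
  lapply(unname(specs), function(sp) {
    sp[!vapply(sp, is.null, TRUE)]
  })
}

.specs_from_list <- function(lst) {
  .validate_specs(lapply(lst, function(el) {
    feature_spec(
      name = el$name, kind = el$kind,
      categories = if (!is.null(el$categories)) unlist(el$categories),
      reference_level = el$reference_level,
      perturbation_unit = el$perturbation_unit
    )
  }))
}
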