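# Internal numeric helpers shared across modules.

.sigmoid <- function(x) stats::plogis(x)

# Log-odds with clipping at a documented epsilon: probabilities at exactly 0
# or 1 have no finite logit, so they are pulled inside (eps, 1 - eps) with a
# warning rather than propagating +/-Inf into population averages.
.logit_eps <- 1e-12

.safe_logit <- function(p, eps = .logit_eps) {
  out_of_range <- p <= 0 | p >= 1
  if (any(out_of_range)) {
    warning(sprintf(
      "%d probability value(s) at 0 or 1 clipped to epsilon %g before logit",
      sum(out_of_range), eps
    ), call. = FALSE)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  stats::qlogis(p)
}

.score_transform <- function(scale) {
  switch(scale,
    probability = identity,
    logit = .safe_logit,
    stop("unknown scale: ", scale)
  )
}

#' Derive a reproducible child seed from a parent seed and a stage label
#'
#' One global seed fans out deterministically to every stage of the pipeline
#' (cohort generation, splitting, under-sampling, weight initialization,
#' bootstrap replicates). The derivation hashes the parent seed together with
#' arbitrary string/integer tags into a 31-bit integer, so changing e.g. only
#' the bootstrap tag leaves all other stage seeds unchanged.
#'
#' @param seed integer parent seed.
#' @param ... stage tags (strings or integers) identifying the consumer.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Canonical unordered key for a feature pair, e.g. "age:dual_use".
.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

# non-standard-evaluation columns used in ggplot2 calls
utils::globalVariables(c("population", "target", "ci_low", "ci_high"))
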