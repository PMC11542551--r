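#' Log-odds and logistic helpers
#'
#' `logit()` maps probabilities to log-odds, `logistic()` is its inverse.
#' Latent susceptibility is modelled on the log-odds scale throughout so that
#' heritable and technical variance components are additive while well-level
#' infection probabilities stay inside (0, 1).
#'
#' @param p probability in (0, 1).
#' @param x log-odds.
#' @return numeric vector.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
logistic <- function(x) stats::plogis(x)

# Deterministic 31-bit polynomial string hash. Used to expand one global seed
# into independent per-well substreams keyed by (population, week, replicate,
# ...), so enlarging a design never perturbs the draws of wells that were
# already present. The multiplier keeps intermediate products below 2^53, so
# the arithmetic is exact in doubles.
.hash31 <- function(key) {
  h <- 113
  for (cp in utf8ToInt(key)) {
    h <- (h * 69069 + cp + 1) %% 2147483647
  }
  as.integer(h %% 2147483646)
}

#' Derive a reproducible substream seed
#'
#' Combines a global seed with an arbitrary set of keys (population id, week,
#' replicate index, ...) into a 31-bit seed for `set.seed()`. The mapping is a
#' pure function of its arguments, so the same global seed always yields the
#' same substream for the same well regardless of how many other wells the
#' design contains.
#'
#' @param seed integer global seed.
#' @param ... keys identifying the substream; coerced to character.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(as.character(as.integer(seed)), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  .hash31(key)
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
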