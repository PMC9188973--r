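#' @importFrom rlang %||% abort warn
#' @importFrom stats coef cor dgamma lm median model.matrix qnorm qt quantile
#'   rbinom rnorm runif sd setNames var vcov complete.cases na.omit
#' @importFrom utils head tail
NULL

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive a child seed from a parent seed and an index, staying inside 32-bit range
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 9973) %% 2147483629L) + 1L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
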