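# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a component seed from a global seed
#'
#' Expands one user-facing seed into independent per-component seeds by
#' hashing the component name, so adding a pipeline stage never perturbs the
#' random stream of earlier stages. Results are kept below 2^31.
#'
#' @param seed Integer global seed.
#' @param name Character tag naming the consumer (e.g. `"simulate"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435) %% 2147483647L + 1L)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
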