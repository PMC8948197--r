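# Internal helpers: error conditions and seed splitting.

stop_validation <- function(msg, ...) {
  abort(msg, class = "imflux_validation_error", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "imflux_format_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "imflux_io_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "imflux_config_error", ...)
}

#' Derive a child seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed. Each consumer
#' (network generation, cohort generation, each bootstrap) gets its own child
#' stream via a fixed multiplicative-congruential step, so adding one consumer
#' never perturbs another's stream. Children stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param purpose One of the documented purpose labels.
#' @return An integer seed.
#' @export
child_seed <- function(seed, purpose = c("network", "cohort", "roc",
                                         "compare", "pipeline")) {
  purpose <- match.arg(purpose)
  offset <- c(network = 101L, cohort = 211L, roc = 307L,
              compare = 401L, pipeline = 503L)[[purpose]]
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# A NULL seed leaves the RNG alone (still reproducible if the caller seeded).
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Collect validation problems; abort once with the full list.
check_all <- function(problems, context) {
  problems <- problems[!vapply(problems, is.null, logical(1))]
  problems <- unlist(problems, use.names = FALSE)
  if (length(problems) > 0) {
    stop_validation(c(paste0("invalid ", context, ":"),
                      stats::setNames(problems, rep("x", length(problems)))))
  }
  invisible(TRUE)
}
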