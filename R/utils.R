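#' otukit: integrated analysis of microbiome census data
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured logging to stderr. Levels: debug < info < warn.
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

otk_log <- function(msg, level = "info") {
  min_level <- getOption("otukit.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[min_level]]) {
    message(sprintf("[otukit %s] %s", level, msg))
  }
  invisible(NULL)
}

otk_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic integer sub-seed derivation, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
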