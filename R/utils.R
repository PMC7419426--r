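# Internal helpers: classed conditions and seeded evaluation.

sr_stop <- function(msg, class = "invalid_input", call. = FALSE) {
  stop(errorCondition(msg,
    class = c(paste0("silicarisk_", class), "silicarisk_error")
  ))
}

sr_warn <- function(msg) {
  warning(warningCondition(msg, class = "silicarisk_warning"))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    sr_stop("`seed` must be a single non-missing integer")
  }
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
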