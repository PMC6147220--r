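# Shared internal helpers.

#' @importFrom withr with_seed
NULL

rms <- function(x) sqrt(mean(x^2))

db_ratio <- function(p_num, p_den) 10 * log10(p_num / p_den)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# Derive a stream of sub-seeds from one master seed, staying inside the
# 32-bit integer range R uses for set.seed().
derive_seeds <- function(seed, n, salt = 0L) {
  base <- (as.numeric(seed) * 7919 + salt * 104729) %% 2147480000
  as.integer((base + seq_len(n) * 9973) %% 2147480000)
}
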