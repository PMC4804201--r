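# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a base seed
#'
#' Expands one user-facing seed into independent per-stage streams so that
#' toggling one pipeline stage does not shift the draws of another. The
#' result always fits in a 32-bit integer.
#'
#' @param seed integer base seed.
#' @param offset integer stage offset (0, 1, 2, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 1000003 * (offset + 1)) %% 2147483629)
}

stop_undefined <- function(msg) {
  stop(structure(class = c("epihost_undefined_statistic", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
}
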