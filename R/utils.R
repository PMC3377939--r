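# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible 32-bit sub-seed from a master seed
#'
#' All randomized operations in the package accept an explicit integer seed.
#' Batch drivers derive per-task seeds from one master seed with this helper so
#' that results are reproducible and seeds stay below 2^31.
#'
#' @param master integer master seed
#' @param k integer task index (>= 0)
#' @return an integer seed in \[0, 2^31 - 2\]
#' @export
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 7919 + as.double(k) * 104729) %% 2147483646)
}

# Evaluate a right-continuous step function with value v0 before the first
# jump; values[k] is the value on [jump_times[k], jump_times[k+1]).
# left = TRUE evaluates the left limit f(t-).
step_eval <- function(jump_times, values, t, v0 = 1, left = FALSE) {
  if (length(jump_times) == 0L) return(rep(v0, length(t)))
  idx <- findInterval(t, jump_times, left.open = left)
  c(v0, values)[idx + 1L]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# settings merged over defaults; unknown names rejected to catch typos
merge_config <- function(defaults, config) {
  if (is.null(config)) return(defaults)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(config)] <- config
  defaults
}
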