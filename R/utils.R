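`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Counter-based scheme: a master seed plus a stream of integer/character
#' labels is folded into a 31-bit integer, so per-subject randomness is
#' reproducible independently of cohort size or evaluation order.
#'
#' @param seed master integer seed.
#' @param ... integer or character labels identifying the stream
#'   (e.g. `"subject", 7`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  labels <- unlist(list(...), use.names = FALSE)
  h <- (abs(as.numeric(seed)) %% 2147483629) + 1
  for (lab in labels) {
    if (is.character(lab)) {
      for (k in utf8ToInt(lab)) h <- (h * 31 + k) %% 2147483629
    } else {
      h <- (h * 69069 + abs(as.numeric(lab)) + 1) %% 2147483629
    }
  }
  as.integer(h + 1)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
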