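#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm sd median quantile var qf pf pt qnorm optim
#'   predict coef lm setNames
#' @importFrom utils read.csv write.csv
NULL

# Run `code` under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-trial substream seed; stays well inside 32-bit range.
trial_seed <- function(seed, subject_index, condition_index) {
  as.integer((as.numeric(seed) + 7919 * subject_index +
                104729 * condition_index) %% 2147483629L)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
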