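# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tilspatial <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tilspatial_error")))
}

assert_that <- function(cond, msg, class = "tilspatial_validation_error") {
  if (!isTRUE(cond)) stop_tilspatial(msg, class)
  invisible(TRUE)
}

#' Derive a deterministic substream seed for a named pipeline stage
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' draws from its own substream so that adding or reordering stages does not
#' perturb the others. The substream seed is a deterministic hash of the
#' master seed and the stage name, kept inside the 32-bit integer range.
#'
#' @param seed master integer seed
#' @param stage character stage name, e.g. `"tissue"`, `"cohort"`
#' @return an integer seed
#' @export
substream_seed <- function(seed, stage) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 10007 + 12345) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
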