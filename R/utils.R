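#' Round half away from zero
#'
#' Percentages in screen reports are conventionally printed with ties rounded
#' up (97.55 -> 97.6), unlike [base::round()]'s round-half-even rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(97.55, 1) # 97.6
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a total, printed style
#'
#' @param count Non-negative integer numerator.
#' @param total Positive integer denominator.
#' @return `100 * count / total`, rounded half-up to one decimal.
#' @export
#' @examples
#' percent_of(808, 828) # 97.6
percent_of <- function(count, total) {
  if (any(total <= 0)) abort("`total` must be positive.")
  round_half_up(100 * count / total, 1)
}

# Derive a per-replicate (or per-stage) RNG seed from a master seed.
# XOR keeps replicates individually reproducible and independent of order.
replicate_seed <- function(seed, index) {
  bitwXor(as.integer(seed), as.integer(index))
}

# Stable small integer seed from a stage name, mixed with the global seed, so
# reordering stages in a config does not reshuffle their randomness.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 1000003L
  replicate_seed(seed, h)
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# run an expression with a temporary RNG state so package functions do not
# disturb the caller's random stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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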