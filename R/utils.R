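#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the previous RNG state, so seeded package internals do
#' not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
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

#' Pearson correlation that tolerates zero-variance inputs
#' @keywords internal
#' @noRd
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

## Derive a child seed from a base seed and an index, kept inside the
## 32-bit integer range R requires of set.seed().
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
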