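#' @importFrom stats median p.adjust pnorm rnorm runif sd cor hclust as.dist
#'   model.matrix qr.resid pbinom setNames rgamma
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to whole numbers
#'
#' Base R's `round()` rounds half to even; reported percentages follow the
#' round-half-away-from-zero convention instead, so that e.g. 17.5 -> 18.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single user seed; independent
#' stages draw from substreams derived deterministically from that seed and a
#' stream label, so no stage perturbs another's random state. The result is
#' kept inside the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param stream character label of the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

assert_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x)) stop2(what, " must be a matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop2(what, " must be non-empty")
  if (anyNA(x) || any(!is.finite(x))) stop2(what, " contains missing or non-finite values")
  invisible(x)
}
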