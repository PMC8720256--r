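#' @import methods
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library code never perturbs user-level
#' random streams.
#'
#' @param seed Integer seed, or `NULL` to evaluate without reseeding.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Hashes a stage tag into the master seed so that every pipeline stage gets
#' an independent, reproducible stream. Result is always in [1, 2^31 - 2].
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the stage (e.g. `"augment"`, `"epoch3"`).
#' @return A positive integer seed.
#' @keywords internal
deriveSeed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 31 + h) %% 2147483629 + 1)
}

#' Squared Euclidean cross-distance matrix
#'
#' @param a Q x 3 matrix. @param b N x 3 matrix.
#' @return Q x N matrix of squared distances, clamped at 0.
#' @keywords internal
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

asCoordMatrix <- function(coords, what = "coords") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop(what, " must have exactly 3 columns, got ", ncol(coords))
  if (!all(is.finite(coords)))
    stop("non-finite values in ", what)
  storage.mode(coords) <- "double"
  coords
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))
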