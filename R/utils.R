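#' @useDynLib priorreach, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx coef convolve cor dnorm glm kruskal.test lm
#'   na.omit p.adjust pchisq plogis pnorm pt qnorm quantile rbinom rlnorm
#'   rnorm rpois runif sd setNames t.test var vcov binomial
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Directions are in degrees, 0 = rightward, counter-clockwise positive.
CARDINAL_DIRECTIONS <- c(0, 90, 180, 270)

#' Normalize an angle in degrees to [0, 360)
#' @param theta angle(s) in degrees.
#' @return angle(s) in [0, 360).
#' @keywords internal
wrapAngle <- function(theta) ((theta %% 360) + 360) %% 360

#' Smallest absolute angular difference between two directions
#' @param a,b angles in degrees.
#' @return difference in degrees, in [0, 180].
#' @keywords internal
angleDistance <- function(a, b) {
  d <- abs(wrapAngle(a) - wrapAngle(b))
  pmin(d, 360 - d)
}

#' Derive a deterministic child seed from a root seed and a stream name
#'
#' A single root seed spawns named child streams (trials, behavior, spikes,
#' ...) so that each simulation stage is independently reproducible: a stage
#' can be re-run in isolation under the same child seed without replaying
#' the streams of earlier stages.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return an integer seed in [0, 2^31 - 1), a deterministic function of
#'   `(seed, stream)`.
#' @examples
#' childSeed(1, "spikes")
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate with a local RNG state so callers' streams are not disturbed.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with a classed condition so callers/tests can distinguish errors.
prStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "priorreachError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
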