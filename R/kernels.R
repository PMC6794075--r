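#' Build a sampled smoothing kernel
#'
#' Two kernels are used for spike-density estimation. The causal EPSP-like
#' kernel, \eqn{(1 - e^{-t/\tau_g}) e^{-t/\tau_d}} for t >= 0 and 0
#' otherwise (rise 2 ms, decay 50 ms by default), mimics post-synaptic
#' integration and is used for display-style densities. The Gaussian
#' kernel (sigma = 50 ms by default) is non-causal but gives more reliable
#' velocity estimates and is used for all latency analyses. Both are
#' sampled on a `dt` grid and rescaled to unit area, so the density
#' integral over an interval estimates the expected spike count.
#'
#' @param kind `"epsp"` or `"gaussian"`.
#' @param tauG,tauD EPSP rise and decay time constants (ms).
#' @param sigma Gaussian width (ms).
#' @param dt grid step (ms).
#' @param support kernel support (ms); defaults to 8x the slowest
#'   constant (must be at least 5x).
#' @return an object of class `priorreachKernel`: list with `kind`, `dt`,
#'   `t` (sample times, ms) and `w` (weights, unit area: `sum(w) * dt`
#'   = 1).
#' @examples
#' k <- makeKernel("gaussian", sigma = 50)
#' max(k$w) # ~ 1 / (50 * sqrt(2 * pi))
#' @export
makeKernel <- function(kind = c("epsp", "gaussian"), tauG = 2, tauD = 50,
                       sigma = 50, dt = 1, support = NULL) {
  kind <- match.arg(kind)
  if (kind == "epsp") {
    if (tauG <= 0 || tauD <= 0)
      prStop("kernelParameterError", "time constants must be positive")
    slowest <- max(tauG, tauD)
    if (is.null(support)) support <- 8 * slowest
    if (support < 5 * slowest)
      prStop("kernelParameterError",
             "support must be at least 5x the slowest constant")
    t <- seq(0, support, by = dt)
    w <- (1 - exp(-t / tauG)) * exp(-t / tauD)
  } else {
    if (sigma <= 0)
      prStop("kernelParameterError", "sigma must be positive")
    if (is.null(support)) support <- 8 * sigma
    if (support < 5 * sigma)
      prStop("kernelParameterError",
             "support must be at least 5x sigma")
    t <- seq(-support, support, by = dt)
    w <- exp(-t^2 / (2 * sigma^2))
  }
  w <- w / (sum(w) * dt)
  structure(list(kind = kind, dt = dt, t = t, w = w),
            class = "priorreachKernel")
}

#' @export
print.priorreachKernel <- function(x, ...) {
  cat(sprintf("%s kernel: %d samples at dt = %g ms, support [%g, %g] ms\n",
              x$kind, length(x$t), x$dt, min(x$t), max(x$t)))
  invisible(x)
}

#' Evaluate a kernel at arbitrary times
#'
#' Linear interpolation of the sampled kernel; zero outside the support
#' (in particular for t < 0 with the causal EPSP kernel).
#'
#' @param kernel a `priorreachKernel`.
#' @param t times in ms.
#' @return kernel values (1/ms).
#' @export
kernelValue <- function(kernel, t) {
  approx(kernel$t, kernel$w, xout = t, yleft = 0, yright = 0)$y
}
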