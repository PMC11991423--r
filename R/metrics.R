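#' Structural similarity index (SSIM)
#'
#' Compares luminance, contrast and structure of two images:
#' `SSIM = (2*mu_x*mu_y + c1) * (2*sigma_xy + c2) /
#'         ((mu_x^2 + mu_y^2 + c1) * (sigma_x^2 + sigma_y^2 + c2))`
#' with `c1 = (k1*L)^2`, `c2 = (k2*L)^2`. Two identical images score
#' exactly 1; for non-negative images on a common range the value lies in
#' `(0, 1]`.
#'
#' Two windowing modes are offered. `"gaussian_11x11"` (the default, and
#' the convention of the standard mean-SSIM) evaluates the formula on
#' Gaussian-weighted 11 x 11 local statistics (sigma 1.5, valid-region
#' crop) and averages the local scores. `"global"` evaluates the formula
#' once on whole-image (population) statistics.
#'
#' By default both images are jointly min-max rescaled to `[0, L]`, so the
#' dynamic-range constants match 8-bit conventions regardless of the input
#' scale; images already on `[0, L]` with a shared scale can pass
#' `rescale = FALSE`.
#'
#' @param x,y Real matrices of identical shape.
#' @param L Dynamic range (255 for 8-bit images).
#' @param k1,k2 Stabilization constants (defaults 0.01 and 0.03).
#' @param window `"gaussian_11x11"` or `"global"`.
#' @param rescale Jointly min-max rescale `c(x, y)` to `[0, L]` first.
#' @return Scalar SSIM value.
#' @export
#' @examples
#' a <- matrix(runif(64), 8, 8)
#' ssim(a, a)                       # exactly 1
#' ssim(a, 1 - a, window = "global")
ssim <- function(x, y, L = 255, k1 = 0.01, k2 = 0.03,
                 window = c("gaussian_11x11", "global"), rescale = TRUE) {
  window <- match.arg(window)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("images must have the same shape", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("images must be finite", call. = FALSE)
  if (isTRUE(rescale)) {
    lo <- min(x, y); hi <- max(x, y)
    if (hi > lo) {
      x <- (x - lo) / (hi - lo) * L
      y <- (y - lo) / (hi - lo) * L
    }
  }
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (window == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (any(dim(x) < 11L)) {
    stop("gaussian_11x11 window requires images of at least 11 x 11; use window = \"global\"",
         call. = FALSE)
  }
  g <- stats::dnorm(-5:5, sd = 1.5)
  g <- g / sum(g)
  smooth <- function(m) .valid_sep_filter(m, g)
  mx <- smooth(x); my <- smooth(y)
  vx <- smooth(x * x) - mx^2
  vy <- smooth(y * y) - my^2
  cxy <- smooth(x * y) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

# Separable valid-mode correlation with a symmetric 1D kernel, via banded
# convolution matrices: K_row %*% M %*% t(K_col).
.valid_sep_filter <- function(m, g) {
  k <- length(g)
  band <- function(n) {
    nb <- n - k + 1L
    B <- matrix(0, nb, n)
    for (i in seq_len(nb)) B[i, i:(i + k - 1L)] <- g
    B
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Mean squared error between two images
#'
#' @param x,y Real matrices of identical shape.
#' @return Mean of squared pixel differences.
#' @export
mse <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("images must have the same shape", call. = FALSE)
  mean((x - y)^2)
}

#' Centered log-magnitude Fourier spectrum
#'
#' `log(1 + |FFT(x)|)` with the zero frequency shifted to the centre of the
#' frame, for qualitative comparison of reconstruction spectra.
#'
#' @param x Real matrix.
#' @return Real matrix of the same shape.
#' @export
log_spectrum <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("image must be finite", call. = FALSE)
  log1p(Mod(fft_shift(stats::fft(x))))
}

#' Shift the zero-frequency component to the centre
#'
#' @param m Matrix (typically an FFT output).
#' @param inverse Undo the shift (for odd dimensions the two differ).
#' @return Shifted matrix.
#' @export
fft_shift <- function(m, inverse = FALSE) {
  sh <- function(n) if (inverse) ceiling(n / 2) else floor(n / 2)
  idx <- function(n) ((seq_len(n) - 1 + n - sh(n)) %% n) + 1
  m[idx(nrow(m)), idx(ncol(m)), drop = FALSE]
}
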