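# Independent oracles used across the suite. These deliberately avoid the
# package's own FFT/accumulation code paths: the Fresnel oracle evaluates
# the discretized kernel by dense DFT matrix products, the AP oracle
# enumerates every confidence cut.

# Direct (non-FFT) evaluation of the discretized Fresnel transfer-function
# kernel: dense DFT matrices, pointwise kernel, dense inverse DFT.
oracle_fresnel <- function(U, z, lambda, pitch) {
  M <- nrow(U); N <- ncol(U)
  fy <- c(0:(M / 2 - 1), -(M / 2):-1) / (M * pitch)
  fx <- c(0:(N / 2 - 1), -(N / 2):-1) / (N * pitch)
  H <- exp(1i * 2 * pi / lambda * z) *
    exp(-1i * pi * lambda * z * outer(fy^2, fx^2, `+`))
  Wm <- exp(-2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  Wn <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  Fm <- Wm %*% U %*% Wn
  (Conj(Wm) %*% (Fm * H) %*% Conj(Wn)) / (M * N)
}

# Brute-force all-point-interpolated AP from a ranked TP/FP flag vector:
# each true positive contributes the best precision achieved at or below
# its rank, divided by the number of ground-truth boxes.
oracle_ap <- function(tp_flags, n_truth) {
  if (n_truth == 0) stop("empty truth")
  n <- length(tp_flags)
  if (n == 0) return(0)
  prec <- cumsum(tp_flags) / seq_len(n)
  total <- 0
  for (i in seq_len(n)) {
    if (tp_flags[i]) total <- total + max(prec[i:n])
  }
  total / n_truth
}

# Brute-force PR points: precision/recall at every cut depth.
oracle_pr_points <- function(tp_flags, n_truth) {
  k <- seq_along(tp_flags)
  tp <- cumsum(tp_flags)
  data.frame(precision = tp / k, recall = tp / n_truth)
}

transform_mask_for_test <- function(mask, rot, flip) {
  gpsholo:::transform_mask(mask, rot, flip)
}

tempfile_empty <- function() {
  p <- tempfile(fileext = ".txt")
  writeLines(character(0), p)
  p
}

desk_config <- function(n = 64L, z = 2.4e-3, strict = FALSE) {
  optical_config(530e-9, z, 5e-6, c(n, n), strict = strict)
}

# A small scene + hologram set on an n x n grid.
desk_scene <- function(seed, n = 64L, phase_mode = "none", count = c(2L, 4L),
                       delta = pi / 2) {
  bank <- shape_bank(2L, max(8L, n %/% 5L), seed = seed)
  scene <- compose_scene(bank, c(n, n), count, seed = seed + 1L,
                         phase_mode = phase_mode)
  cfg <- desk_config(n)
  list(scene = scene, config = cfg,
       holoset = synthesize_hologram_set(scene$object, cfg, delta = delta))
}
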