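#' Two-step phase-shifting hologram set
#'
#' The four intensity frames consumed by the two-step generalized
#' phase-shifting (GPS) reconstruction: two interferograms `I1` (reference
#' phase 0) and `I2` (reference phase `delta`), the object-wave intensity
#' `Io = A_o^2` and the reference intensity `Ir = A_r^2` (nominally
#' uniform). `delta` may be recorded (simulation) or left `NULL` and
#' estimated from the frames ([estimate_phase_shift()]).
#'
#' @param I1,I2,Io,Ir Real non-negative matrices of identical shape.
#' @param delta Optional known phase step in radians; must satisfy
#'   `abs(sin(delta)) > 1e-3` when supplied.
#' @param provenance `"simulated"` or `"experimental"`.
#' @param background Optional background frame (experimental flat-field);
#'   never produced by the simulator.
#' @return An object of class `hologram_set`.
#' @export
hologram_set <- function(I1, I2, Io, Ir, delta = NULL,
                         provenance = c("simulated", "experimental"),
                         background = NULL) {
  provenance <- match.arg(provenance)
  frames <- list(I1 = as.matrix(I1), I2 = as.matrix(I2),
                 Io = as.matrix(Io), Ir = as.matrix(Ir))
  shp <- dim(frames$I1)
  for (nm in names(frames)) {
    f <- frames[[nm]]
    if (!identical(dim(f), shp)) stop("all four frames must share one shape", call. = FALSE)
    if (!all(is.finite(f))) stop(sprintf("%s contains non-finite values", nm), call. = FALSE)
    if (any(f < 0)) stop(sprintf("%s must be non-negative", nm), call. = FALSE)
  }
  if (!is.null(delta)) {
    stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
    if (abs(sin(delta)) <= 1e-3) {
      stop("delta is degenerate: |sin(delta)| must exceed 1e-3", call. = FALSE)
    }
  }
  if (!is.null(background)) {
    background <- as.matrix(background)
    if (!identical(dim(background), shp)) {
      stop("background frame shape mismatch", call. = FALSE)
    }
  }
  structure(c(frames, list(delta = delta, provenance = provenance,
                           background = background)),
            class = "hologram_set")
}

#' @export
print.hologram_set <- function(x, ...) {
  cat(sprintf("hologram_set (%s): %d x %d, delta = %s\n", x$provenance,
              nrow(x$I1), ncol(x$I1),
              if (is.null(x$delta)) "unknown" else sprintf("%.4f rad", x$delta)))
  invisible(x)
}

#' Reference amplitude from the reference intensity frame
#'
#' The reference is a plane wave, so its amplitude is a single positive
#' scalar; it is taken as the square root of the spatial mean of `Ir`,
#' which averages out sensor noise on experimental frames.
#'
#' @param Ir Non-negative intensity matrix, not identically zero.
#' @return Positive scalar `A_r`.
#' @export
ar_from_reference <- function(Ir) {
  Ir <- as.matrix(Ir)
  if (any(!is.finite(Ir)) || any(Ir < 0)) {
    stop("Ir must be finite and non-negative", call. = FALSE)
  }
  m <- mean(Ir)
  if (m == 0) stop("reference intensity is identically zero", call. = FALSE)
  sqrt(m)
}

# sin-delta degeneracy guard used by Eq-style two-frame inversion
.eps_delta <- 1e-3

#' Estimate the phase step between the two interferograms
#'
#' In generalized phase-shifting holography the phase step `delta` between
#' the two reference states is not controlled but recovered from the frames
#' themselves. Normalizing the interference terms,
#' `c1 = (I1 - Io - Ir) / (2*sqrt(Io*Ir)) = cos(phi_o)` and
#' `c2 = (I2 - Io - Ir) / (2*sqrt(Io*Ir)) = cos(phi_o - delta)`, so when the
#' object-wave phase `phi_o` is broadly distributed over the frame (true
#' after Fresnel diffraction of compact objects and for diffuse scenes),
#' the normalized correlation of `c1` and `c2` converges to `cos(delta)`:
#' `delta_hat = acos( <c1*c2> / sqrt(<c1^2><c2^2>) )`.
#'
#' The two-frame problem cannot distinguish `+delta` from `-delta`; the
#' estimate is returned in `(0, pi)`.
#'
#' @param holoset A `hologram_set`.
#' @param support_frac Pixels with `Io` below `support_frac * max(Io)` are
#'   excluded from the statistic.
#' @return Estimated phase step in radians, in `(0, pi)`.
#' @export
estimate_phase_shift <- function(holoset, support_frac = 1e-3) {
  stopifnot(inherits(holoset, "hologram_set"))
  Io <- holoset$Io; Ir <- holoset$Ir
  keep <- Io > support_frac * max(Io) & Ir > 0
  if (mean(keep) < 0.01) {
    stop("object-wave intensity has support on fewer than 1% of pixels",
         call. = FALSE)
  }
  I1 <- holoset$I1[keep]; I2 <- holoset$I2[keep]
  denom <- 2 * sqrt(Io[keep] * Ir[keep])
  scale <- mean(abs(I1)) + mean(abs(I2))
  if (mean(abs(I1 - I2)) <= 1e-9 * max(scale, .Machine$double.eps)) {
    stop("interferograms are identical: phase step indistinguishable from zero",
         call. = FALSE)
  }
  c1 <- (I1 - Io[keep] - Ir[keep]) / denom
  c2 <- (I2 - Io[keep] - Ir[keep]) / denom
  rho <- mean(c1 * c2) / sqrt(mean(c1^2) * mean(c2^2))
  rho <- min(1, max(-1, rho))
  delta_hat <- acos(rho)
  if (delta_hat <= 0 || delta_hat >= pi) {
    stop("phase-step estimation failed: estimate collapsed to 0 or pi",
         call. = FALSE)
  }
  delta_hat
}

#' Recover the object wave on the recording plane (two-step GPS)
#'
#' Closed-form inversion of the two interferograms: with reference phases
#' `0` and `delta`, the complex object wave on the recording plane is
#' recovered pointwise as
#' `Re(Uo) = (I1 - Io - Ir) / (2*A_r)` and
#' `Im(Uo) = (I2 - I1*cos(delta) - (1 - cos(delta))*(Io + Ir)) /
#'           (2*A_r*sin(delta))`.
#'
#' @param holoset A `hologram_set`.
#' @param delta Phase step in radians; `abs(sin(delta))` must exceed `1e-3`
#'   (the formula divides by `sin(delta)`).
#' @param A_r Positive reference amplitude (see [ar_from_reference()]).
#' @return A `complex_field` on the recording plane.
#' @export
reconstruct_object_wave <- function(holoset, delta, A_r) {
  stopifnot(inherits(holoset, "hologram_set"))
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (abs(sin(delta)) <= .eps_delta) {
    stop(sprintf("degenerate phase step delta = %.6g: |sin(delta)| <= %g",
                 delta, .eps_delta), call. = FALSE)
  }
  if (!is.numeric(A_r) || length(A_r) != 1L || !is.finite(A_r) || A_r <= 0) {
    stop("A_r must be a positive scalar", call. = FALSE)
  }
  re <- (holoset$I1 - holoset$Io - holoset$Ir) / (2 * A_r)
  im <- (holoset$I2 - holoset$I1 * cos(delta) -
           (1 - cos(delta)) * (holoset$Io + holoset$Ir)) /
    (2 * A_r * sin(delta))
  complex_field(complex(real = re, imaginary = im) |>
                  matrix(nrow(re), ncol(re)),
                plane = "recording_plane")
}

#' Full two-step reconstruction to an object-plane amplitude image
#'
#' Composes the whole pipeline: reference amplitude from `Ir`, phase step
#' (recorded, supplied, or estimated from the frames), pointwise object-wave
#' recovery on the recording plane, inverse Fresnel propagation over `-z`,
#' and normalization of the object-plane amplitude to `[0, 1]` by its
#' maximum. An optional experimental background frame divides the
#' interferograms first (flat-field correction, off by default).
#'
#' @param holoset A `hologram_set`.
#' @param config An `optical_config`; `config$distance_z` is the recording
#'   distance refocused over.
#' @param delta Optional phase step override; defaults to the recorded
#'   `holoset$delta`, falling back to [estimate_phase_shift()].
#' @param flatfield If `TRUE` and a background frame is present, divide all
#'   frames by it before reconstruction.
#' @return Amplitude matrix in `[0, 1]` on the object plane, with the
#'   recovered recording-plane field attached as attribute
#'   `"recording_field"` and the phase step used as `"delta"`.
#' @export
two_step_reconstruct <- function(holoset, config, delta = NULL,
                                 flatfield = FALSE) {
  stopifnot(inherits(holoset, "hologram_set"), inherits(config, "optical_config"))
  if (isTRUE(flatfield) && !is.null(holoset$background)) {
    bg <- holoset$background
    if (any(bg <= 0)) stop("background frame must be strictly positive", call. = FALSE)
    holoset <- hologram_set(holoset$I1 / bg, holoset$I2 / bg,
                            holoset$Io / bg, holoset$Ir / bg,
                            delta = holoset$delta,
                            provenance = holoset$provenance)
  }
  A_r <- ar_from_reference(holoset$Ir)
  if (is.null(delta)) delta <- holoset$delta
  if (is.null(delta)) delta <- estimate_phase_shift(holoset)
  u_rec <- reconstruct_object_wave(holoset, delta, A_r)
  u_obj <- fresnel_propagate(u_rec, -config$distance_z, config)
  amp <- Mod(u_obj$values)
  mx <- max(amp)
  if (mx > 0) amp <- amp / mx
  attr(amp, "recording_field") <- u_rec
  attr(amp, "delta") <- delta
  amp
}
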