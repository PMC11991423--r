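#' Optical recording configuration
#'
#' Bundles the physical parameters that govern scalar Fresnel propagation
#' between the object plane and the recording plane: vacuum wavelength,
#' recording distance, sensor pixel pitch (square pixels) and grid size.
#' The wave number `k = 2*pi/wavelength` is always derived, never stored.
#'
#' The default values describe the reference simulation geometry: a
#' 530 nm laser, a 24 cm recording distance and a 512 x 512 sensor with
#' 5 um pixels.
#'
#' @param wavelength Vacuum wavelength in metres.
#' @param distance_z Object-to-sensor distance in metres (positive).
#' @param pixel_pitch Sensor pixel pitch in metres (square pixels).
#' @param grid_shape Integer vector `c(rows, cols)`; both even and >= 8.
#' @param strict If `TRUE`, a propagation request that violates the
#'   transfer-function sampling criterion is an error instead of a warning.
#' @return An object of class `optical_config`.
#' @export
#' @examples
#' cfg <- optical_config()
#' cfg$wavelength
#' wave_number(cfg)
optical_config <- function(wavelength = 530e-9,
                           distance_z = 0.24,
                           pixel_pitch = 5e-6,
                           grid_shape = c(512L, 512L),
                           strict = FALSE) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  stopifnot(is.numeric(distance_z), length(distance_z) == 1L, distance_z > 0)
  stopifnot(is.numeric(pixel_pitch), length(pixel_pitch) == 1L, pixel_pitch > 0)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 8L) || any(grid_shape %% 2L != 0L)) {
    stop("grid_shape must be two even integers >= 8", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, distance_z = distance_z,
         pixel_pitch = pixel_pitch, grid_shape = grid_shape,
         strict = isTRUE(strict)),
    class = "optical_config"
  )
}

#' @rdname optical_config
#' @param config An `optical_config`.
#' @export
wave_number <- function(config) 2 * pi / config$wavelength

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "optical_config: lambda = %.4g nm, z = %.4g mm, pitch = %.4g um, grid %d x %d\n",
    x$wavelength * 1e9, x$distance_z * 1e3, x$pixel_pitch * 1e6,
    x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' Critical transfer-function propagation distance
#'
#' The single-FFT transfer-function propagator samples the Fresnel chirp in
#' the frequency domain; it is alias-free while the local kernel frequency
#' stays below Nyquist, i.e. for `|z| <= N * pitch^2 / wavelength` (with `N`
#' the smaller grid dimension). Beyond that distance the quadratic phase
#' wraps and replicas fold in.
#'
#' @param config An `optical_config`.
#' @return The critical distance in metres.
#' @export
fresnel_critical_distance <- function(config) {
  min(config$grid_shape) * config$pixel_pitch^2 / config$wavelength
}

#' Thin-object transmission function
#'
#' A thin sample multiplies the incident wave pointwise by
#' `exp(-a) * exp(1i * phi)`: `a >= 0` is the absorption map and `phi` the
#' phase delay in radians. Pure amplitude objects (the plankton silhouette
#' regime: seawater background, opaque organisms) have `phi = 0` everywhere.
#'
#' @param absorption Non-negative real matrix `a`.
#' @param phase Real matrix of phase delays in radians, or `NULL` for a
#'   pure-amplitude object.
#' @return An object of class `transmission_object`.
#' @export
transmission_object <- function(absorption, phase = NULL) {
  absorption <- as.matrix(absorption)
  if (!all(is.finite(absorption)) || any(absorption < 0)) {
    stop("absorption must be finite and non-negative", call. = FALSE)
  }
  if (is.null(phase)) {
    phase <- matrix(0, nrow(absorption), ncol(absorption))
  } else {
    phase <- as.matrix(phase)
    if (!identical(dim(phase), dim(absorption))) {
      stop("phase and absorption must have the same shape", call. = FALSE)
    }
    if (!all(is.finite(phase))) stop("phase must be finite", call. = FALSE)
  }
  structure(list(absorption = absorption, phase = phase),
            class = "transmission_object")
}

#' Complex transmission values of a transmission object
#' @param object A `transmission_object`.
#' @return A complex matrix `exp(-a) * exp(1i * phi)`.
#' @export
transmission_values <- function(object) {
  exp(-object$absorption) * exp(1i * object$phase)
}

#' Sampled complex wavefront
#'
#' A complex-valued matrix sampled on the sensor grid, tagged with the plane
#' it lives on. Amplitude and phase are `Mod(values)` and `Arg(values)`;
#' internally the package uses the `exp(+1i * phase)` convention throughout.
#'
#' @param values Complex (or real) matrix; all entries finite.
#' @param plane Either `"object_plane"` or `"recording_plane"`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, plane = c("object_plane", "recording_plane")) {
  plane <- match.arg(plane)
  values <- as.matrix(values)
  storage.mode(values) <- "complex"
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("field values must be finite", call. = FALSE)
  }
  structure(list(values = values, plane = plane), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field (%s): %d x %d, power %.6g\n", x$plane,
              nrow(x$values), ncol(x$values), sum(Mod(x$values)^2)))
  invisible(x)
}

#' Uniform plane-wave field
#'
#' @param config An `optical_config` fixing the grid shape.
#' @param amplitude Real amplitude of the plane wave.
#' @param plane Plane tag for the resulting field.
#' @return A constant `complex_field`.
#' @export
plane_wave <- function(config, amplitude = 1, plane = "object_plane") {
  complex_field(matrix(complex(real = amplitude), config$grid_shape[1],
                       config$grid_shape[2]), plane = plane)
}

#' Plane reference wave
#'
#' The reference is a clean plane wave `A_r * exp(1i * delta)` that shares
#' the optical axis with the object wave (in-line geometry). The phase
#' `delta` is stored wrapped to `(-pi, pi]`.
#'
#' @param amplitude Positive real amplitude `A_r`.
#' @param phase Reference phase `delta` in radians.
#' @return An object of class `plane_reference`.
#' @export
plane_reference <- function(amplitude = 1, phase = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (amplitude <= 0) stop("reference amplitude must be positive", call. = FALSE)
  stopifnot(is.numeric(phase), length(phase) == 1L, is.finite(phase))
  structure(list(amplitude = amplitude, phase = wrap_phase(phase)),
            class = "plane_reference")
}

#' Wrap an angle to (-pi, pi]
#' @param theta Angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Pass a field through a thin transmission object
#'
#' Pointwise product of the incident wave with the object transmission
#' `exp(-a) * exp(1i * phi)`: the exit wave just behind the object.
#'
#' @param object A `transmission_object`.
#' @param incident A `complex_field` on the object plane (or a bare matrix).
#' @return A `complex_field` on the object plane.
#' @export
transmit <- function(object, incident) {
  inc <- if (inherits(incident, "complex_field")) incident$values else as.matrix(incident)
  if (!identical(dim(inc), dim(object$absorption))) {
    stop(sprintf("shape mismatch: incident %d x %d vs object %d x %d",
                 nrow(inc), ncol(inc),
                 nrow(object$absorption), ncol(object$absorption)),
         call. = FALSE)
  }
  complex_field(transmission_values(object) * inc, plane = "object_plane")
}

# FFT sample frequencies for n points at spacing d (cycles per metre),
# in the wrap-around order used by stats::fft.
fft_freq <- function(n, d) {
  c(0:(n %/% 2 - 1), -(n %/% 2):-1) / (n * d)
}

#' Fresnel propagation by the transfer-function method
#'
#' Propagates a sampled field over a signed distance using a single-FFT
#' transfer-function propagator: the paraxial (Fresnel) kernel
#' `H(fx, fy) = exp(1i * k * z) * exp(-1i * pi * lambda * z * (fx^2 + fy^2))`
#' is applied in the frequency domain. `|H| = 1`, so total power is
#' conserved exactly and propagation by `-z` undoes propagation by `+z` to
#' machine precision; a negative `z_signed` is the inverse (refocusing)
#' transform. The global `exp(1i*k*z)` prefactor is retained; it cancels in
#' any intensity image.
#'
#' A warning (error when `config$strict`) is raised when `|z_signed|`
#' exceeds [fresnel_critical_distance()], beyond which the sampled kernel
#' aliases.
#'
#' @param field A `complex_field` (or complex matrix).
#' @param z_signed Signed propagation distance in metres; `0` returns the
#'   input unchanged with no FFT applied.
#' @param config An `optical_config` supplying wavelength and pixel pitch.
#' @return A `complex_field` on the destination plane.
#' @export
fresnel_propagate <- function(field, z_signed, config) {
  vals <- if (inherits(field, "complex_field")) field$values else as.matrix(field)
  storage.mode(vals) <- "complex"
  if (!identical(dim(vals), as.integer(config$grid_shape))) {
    stop("field shape does not match config grid_shape", call. = FALSE)
  }
  if (!all(is.finite(Re(vals))) || !all(is.finite(Im(vals)))) {
    stop("field values must be finite", call. = FALSE)
  }
  stopifnot(is.numeric(z_signed), length(z_signed) == 1L, is.finite(z_signed))
  src_plane <- if (inherits(field, "complex_field")) field$plane else "object_plane"
  dst_plane <- if (z_signed > 0) "recording_plane"
               else if (z_signed < 0) "object_plane"
               else src_plane
  if (z_signed == 0) {
    return(complex_field(vals, plane = dst_plane))
  }
  zc <- fresnel_critical_distance(config)
  if (abs(z_signed) > zc * (1 + 1e-12)) {
    msg <- sprintf(paste0(
      "|z| = %.4g m exceeds the transfer-function sampling limit %.4g m; ",
      "the propagated field will alias"), abs(z_signed), zc)
    if (isTRUE(config$strict)) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  lam <- config$wavelength
  fy <- fft_freq(nrow(vals), config$pixel_pitch)
  fx <- fft_freq(ncol(vals), config$pixel_pitch)
  chirp <- outer(fy^2, rep(1, length(fx))) + outer(rep(1, length(fy)), fx^2)
  H <- exp(1i * 2 * pi / lam * z_signed) *
    exp(-1i * pi * lam * z_signed * chirp)
  out <- stats::fft(stats::fft(vals) * H, inverse = TRUE) / length(vals)
  complex_field(out, plane = dst_plane)
}

#' Interference intensity with a plane reference
#'
#' The recorded hologram intensity `|U_z + A_r * exp(1i * delta)|^2`,
#' evaluated pointwise. Setting `amplitude = 0` in a bare reference is not
#' permitted by [plane_reference()]; pass `reference = NULL` to get the
#' object-wave intensity alone.
#'
#' @param object_field A `complex_field` on the recording plane (or matrix).
#' @param reference A `plane_reference`, or `NULL` for no reference beam.
#' @return A real, non-negative intensity matrix.
#' @export
interfere <- function(object_field, reference = NULL) {
  vals <- if (inherits(object_field, "complex_field")) object_field$values
          else as.matrix(object_field)
  if (is.null(reference)) return(Mod(vals)^2)
  stopifnot(inherits(reference, "plane_reference"))
  ur <- reference$amplitude * exp(1i * reference$phase)
  Mod(vals + ur)^2
}

#' Total optical power of a field
#'
#' Discrete power `sum(|U|^2) * pitch^2`, the quantity conserved by the
#' transfer-function propagator.
#'
#' @param field A `complex_field` or complex matrix.
#' @param config An `optical_config` (for the pixel area).
#' @return Scalar power.
#' @export
field_power <- function(field, config) {
  vals <- if (inherits(field, "complex_field")) field$values else as.matrix(field)
  sum(Mod(vals)^2) * config$pixel_pitch^2
}
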