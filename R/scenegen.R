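#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards; with `seed = NULL` the code runs on the current
#' stream. Used by every generator so that a dataset build never perturbs
#' the caller's RNG.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Exact 90-degree clockwise rotation of a matrix.
rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Apply k in 0:3 clockwise quarter-turns, then an optional flip.
transform_mask <- function(m, rot = 0L, flip = c("none", "horizontal", "vertical")) {
  flip <- match.arg(flip)
  for (i in seq_len(rot %% 4L)) m <- rot90_cw(m)
  if (flip == "horizontal") m <- m[, ncol(m):1, drop = FALSE]
  if (flip == "vertical") m <- m[nrow(m):1, , drop = FALSE]
  m
}

# 3x3 box blur with zero padding; softens silhouette edges so opacity
# takes fractional values at the boundary.
box_blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + p[(1:h) + di, (1:w) + dj]
  }
  out / 9
}

# Crop a mask to the tight bounding box of its support.
trim_mask <- function(m) {
  rows <- which(rowSums(m > 0) > 0)
  cols <- which(colSums(m > 0) > 0)
  m[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}

#' Generate one procedural plankton-like silhouette
#'
#' Stand-ins for the four plankton silhouette families used to compose
#' scenes, one visually distinct morphology per class index:
#' \describe{
#'   \item{0}{elongated body with an undulating tail (appendicularian-like)}
#'   \item{1}{radial form with exact 4-fold symmetric arms (echinoderm-like)}
#'   \item{2}{bell with trailing tentacles (hydromedusa-like)}
#'   \item{3}{slender, slightly curved rod (chaetognath-like)}
#' }
#' The mask is a grayscale opacity map in `[0, 1]` (1 = fully opaque),
#' soft-edged, cropped to its support, deterministic given
#' `(class_id, size, seed)`.
#'
#' @param class_id Integer in `0:3`.
#' @param size Nominal canvas size in pixels.
#' @param seed Optional integer seed.
#' @return A list with `class_id`, `mask` and `size`.
#' @export
make_shape <- function(class_id, size = 24L, seed = NULL) {
  stopifnot(class_id %in% 0:3)
  size <- as.integer(size)
  stopifnot(size >= 8L)
  with_seed(seed, {
    u <- stats::runif(8)
    xs <- seq(-1, 1, length.out = size)
    X <- matrix(xs, size, size, byrow = TRUE)
    Y <- matrix(xs, size, size)
    # half-thickness floor so sub-pixel strokes cannot fall between samples
    tmin <- 0.65 * (xs[2] - xs[1])
    m <- switch(as.character(class_id),
      "0" = {
        a <- 0.40 + 0.12 * u[1]; b <- 0.18 + 0.08 * u[2]; cx <- -0.30
        body <- ((X - cx) / a)^2 + (Y / b)^2 <= 1
        amp <- 0.12 + 0.12 * u[3]; freq <- 3 + 3 * u[4]; ph <- 2 * pi * u[5]
        x0 <- cx + 0.5 * a
        tail <- X >= x0 & X <= 0.92 &
          abs(Y - amp * sin(freq * (X - x0) + ph) * (X - x0)) < max(0.09, tmin)
        body | tail
      },
      "1" = {
        disk <- X^2 + Y^2 <= (0.22 + 0.06 * u[1])^2
        len <- 0.70 + 0.20 * u[2]; thick <- max(0.06 + 0.04 * u[3], tmin)
        arm <- X > 0 & X < len & abs(Y) < thick * (1 + 0.5 * (1 - X / len))
        disk | arm | rot90_cw(arm) | rot90_cw(rot90_cw(arm)) |
          rot90_cw(rot90_cw(rot90_cw(arm)))
      },
      "2" = {
        a <- 0.45 + 0.12 * u[1]; b <- 0.30 + 0.10 * u[2]
        bell <- (X / a)^2 + ((Y + 0.35) / b)^2 <= 1 & Y <= -0.15
        k <- 3L + (u[3] > 0.5)
        xi <- seq(-0.6 * a, 0.6 * a, length.out = k)
        tent <- matrix(FALSE, size, size)
        for (t in seq_len(k)) {
          wob <- 0.07 * sin(5 * Y + 2 * pi * u[4] + t)
          tent <- tent | (abs(X - (xi[t] + wob)) < max(0.045, tmin) &
                            Y > -0.2 & Y < 0.75)
        }
        bell | tent
      },
      "3" = {
        curv <- (u[1] - 0.5) * 0.7; thick <- max(0.05 + 0.04 * u[2], tmin)
        abs(Y - curv * X^2 + 0.15 * curv) < thick & abs(X) < 0.88
      })
    if (!any(m)) {                      # unreachable safety net
      m <- X^2 + Y^2 <= 0.25^2
    }
    omax <- 0.75 + 0.2 * u[8]
    mask <- box_blur3(omax * m)
    mask <- pmin(mask, omax)
    list(class_id = as.integer(class_id), mask = trim_mask(mask), size = size)
  })
}

#' Build a bank of silhouettes covering all four classes
#'
#' @param n_per_class Silhouette variants generated per class.
#' @param size Nominal silhouette canvas size in pixels.
#' @param seed Optional integer seed.
#' @return An object of class `shape_bank`: a list with `entries`.
#' @export
shape_bank <- function(n_per_class = 3L, size = 24L, seed = NULL) {
  with_seed(seed, {
    entries <- list()
    for (cls in 0:3) {
      for (i in seq_len(n_per_class)) {
        entries[[length(entries) + 1L]] <-
          make_shape(cls, size = size,
                     seed = as.integer(stats::runif(1, 1, 2^30)))
      }
    }
    structure(list(entries = entries), class = "shape_bank")
  })
}

#' Compose a labeled scene of non-overlapping silhouettes
#'
#' Draws a random number of silhouettes from the bank, applies a random
#' quarter-turn rotation (0/90/180/270 degrees) and one of three flips
#' (none, horizontal, vertical) to each, and places them by rejection
#' sampling on an empty frame so that silhouette supports are pairwise
#' disjoint (bounding boxes may touch). Pixels covered by no silhouette
#' transmit fully (empty seawater); opacity maps to absorption
#' `a = -log(1 - opacity)` with the transmission clipped at `1e-3` so fully
#' opaque pixels stay finite.
#'
#' An object whose placement fails `max_attempts` times is dropped; the
#' scene errors only if fewer than `count_range[1]` objects could be placed.
#'
#' @param bank A `shape_bank`.
#' @param frame_shape Frame size `c(rows, cols)`.
#' @param count_range Inclusive bounds on the object count per scene.
#' @param seed Optional integer seed.
#' @param phase_mode `"none"` for pure-amplitude scenes (the plankton
#'   regime); `"diffuse"` adds an independent uniform random phase in
#'   `(-pi, pi]` at every pixel, emulating diffuser illumination for
#'   phase-step-estimator exercises.
#' @param max_attempts Rejection-sampling attempts per object.
#' @return A list with `object` (a [transmission_object()]) and `spec`
#'   (a `scene_spec`: placements, pixel boxes, YOLO records, frame shape,
#'   seed).
#' @export
compose_scene <- function(bank, frame_shape = c(512L, 512L),
                          count_range = c(5L, 10L), seed = NULL,
                          phase_mode = c("none", "diffuse"),
                          max_attempts = 200L) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(inherits(bank, "shape_bank"))
  if (length(bank$entries) == 0L) stop("shape bank is empty", call. = FALSE)
  H <- as.integer(frame_shape[1]); W <- as.integer(frame_shape[2])
  lo <- as.integer(count_range[1]); hi <- as.integer(count_range[2])
  stopifnot(lo >= 1L, hi >= lo)
  with_seed(seed, {
    n_target <- sample(lo:hi, 1L)
    opacity <- matrix(0, H, W)
    occupied <- matrix(FALSE, H, W)
    placements <- list()
    for (obj in seq_len(n_target)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        idx <- sample(length(bank$entries), 1L)
        entry <- bank$entries[[idx]]
        rot <- sample(0:3, 1L)
        flip <- sample(c("none", "horizontal", "vertical"), 1L)
        m <- transform_mask(entry$mask, rot, flip)
        hm <- nrow(m); wm <- ncol(m)
        if (hm > H || wm > W) next
        r0 <- sample(H - hm + 1L, 1L)
        c0 <- sample(W - wm + 1L, 1L)
        rows <- r0:(r0 + hm - 1L); cols <- c0:(c0 + wm - 1L)
        if (any(occupied[rows, cols] & m > 0)) next
        opacity[rows, cols] <- pmax(opacity[rows, cols], m)
        occupied[rows, cols] <- occupied[rows, cols] | m > 0
        placements[[length(placements) + 1L]] <- list(
          class_id = entry$class_id, entry = idx, rot = rot, flip = flip,
          r0 = r0, c0 = c0, h = hm, w = wm)
        placed <- TRUE
        break
      }
      if (!placed) next
    }
    if (length(placements) < lo) {
      stop(sprintf("could only place %d objects (minimum %d)",
                   length(placements), lo), call. = FALSE)
    }
    # 0-based half-open pixel boxes [x0, x0+w) x [y0, y0+h)
    px <- do.call(rbind, lapply(placements, function(p) {
      data.frame(class_id = p$class_id, x0 = p$c0 - 1L, y0 = p$r0 - 1L,
                 w = p$w, h = p$h)
    }))
    yolo <- yolo_record(px$class_id,
                        xc = (px$x0 + px$w / 2) / W,
                        yc = (px$y0 + px$h / 2) / H,
                        w = px$w / W, h = px$h / H)
    phase <- if (phase_mode == "diffuse") {
      matrix(stats::runif(H * W, -pi, pi), H, W)
    } else NULL
    transmission <- pmax(1 - opacity, 1e-3)
    object <- transmission_object(-log(transmission), phase)
    spec <- structure(
      list(placements = placements, pixel_boxes = px, boxes = yolo,
           frame_shape = c(H, W), seed = seed, phase_mode = phase_mode),
      class = "scene_spec")
    list(object = object, spec = spec)
  })
}

#' Synthesize the four-frame hologram set for a scene
#'
#' Forward model of in-line two-step phase-shifting recording: unit plane
#' wave through the transmission object, Fresnel propagation to the sensor,
#' then interference with the plane reference at phase 0 (`I1`) and phase
#' `delta` (`I2`), plus the object-wave intensity `Io` and the uniform
#' reference intensity `Ir`. The raw floating-point frames are returned so
#' the algebraic GPS inversion stays exact; export normalization (each
#' image divided by its maximum) is applied by the dataset writer, which
#' records the scale factor.
#'
#' @param object A [transmission_object()] matching `config$grid_shape`.
#' @param config An `optical_config`.
#' @param delta Reference phase step in radians (`|sin(delta)| > 1e-3`).
#' @param A_r Reference wave amplitude.
#' @return A [hologram_set()] with `delta` recorded.
#' @export
synthesize_hologram_set <- function(object, config, delta = pi / 2, A_r = 1) {
  stopifnot(inherits(object, "transmission_object"),
            inherits(config, "optical_config"))
  if (abs(sin(delta)) <= 1e-3) {
    stop("degenerate phase step: |sin(delta)| must exceed 1e-3", call. = FALSE)
  }
  exit_wave <- transmit(object, plane_wave(config))
  u_z <- fresnel_propagate(exit_wave, config$distance_z, config)
  I1 <- interfere(u_z, plane_reference(A_r, 0))
  I2 <- interfere(u_z, plane_reference(A_r, delta))
  Io <- interfere(u_z, NULL)
  Ir <- matrix(A_r^2, nrow(I1), ncol(I1))
  hologram_set(I1, I2, Io, Ir, delta = delta, provenance = "simulated")
}

#' Normalize an image by its maximum value
#'
#' @param img Non-negative matrix.
#' @return The normalized image (peak exactly 1 unless all-zero), with the
#'   scale factor attached as attribute `"scale"`.
#' @export
normalize_image <- function(img) {
  mx <- max(img)
  out <- if (mx > 0) img / mx else img
  attr(out, "scale") <- mx
  out
}

#' Train/test partition sizes
#'
#' @param n Total number of scenes.
#' @param split_ratio Fraction assigned to training (`0 < ratio < 1`).
#' @return `c(train = ..., test = ...)`; at the reference scale
#'   (`n = 10000`, ratio 0.9) this is the 9000/1000 partition.
#' @export
dataset_split <- function(n, split_ratio = 0.9) {
  stopifnot(n >= 2, split_ratio > 0, split_ratio < 1)
  n_train <- round(n * split_ratio)
  n_train <- min(max(n_train, 1L), n - 1L)
  c(train = as.integer(n_train), test = as.integer(n - n_train))
}

#' Built-in dataset profiles
#'
#' `"paper"` mirrors the reference recording geometry (512 x 512 frame,
#' 5 um pitch, 530 nm, z = 24 cm, 5-10 objects per scene). `"desk"` is a
#' reduced geometry for CPU-scale runs (64 x 64 frame, same pitch and
#' wavelength, z = 2.4 mm — inside the transfer-function sampling limit —
#' 2-4 smaller objects per scene).
#'
#' @param profile `"desk"` or `"paper"`.
#' @return A list with `config`, `count_range`, `shape_size`,
#'   `n_per_class`.
#' @export
dataset_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    list(config = optical_config(530e-9, 0.24, 5e-6, c(512L, 512L)),
         count_range = c(5L, 10L), shape_size = 80L, n_per_class = 3L)
  } else {
    list(config = optical_config(530e-9, 2.4e-3, 5e-6, c(64L, 64L)),
         count_range = c(2L, 4L), shape_size = 13L, n_per_class = 3L)
  }
}

# Derive a per-scene seed below 2^31 from the master seed.
scene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
}

#' Build a labeled synthetic hologram dataset on disk
#'
#' For each scene: composes non-overlapping silhouettes, synthesizes the
#' four-frame hologram set, writes the max-normalized `I1` hologram
#' (16-bit PGM) under `images/`, the two-step GPS reconstruction (the
#' learning label) under `targets/`, and the YOLO boxes under `labels/`.
#' A `manifest.json` records the profile, per-scene seeds, phase steps,
#' normalization scales and the train/test partition
#' (first `round(n * split_ratio)` scenes train, remainder test). The
#' build is fully deterministic given `seed`.
#'
#' @param n_scenes Number of scenes (>= 2).
#' @param out_dir Output directory (created if needed).
#' @param split_ratio Training fraction, in (0, 1).
#' @param seed Master integer seed.
#' @param profile `"desk"` or `"paper"` (see [dataset_profile()]).
#' @param delta_mode `"fixed"` uses `delta` for every scene; `"random"`
#'   draws a per-scene step uniformly from `[0.3, 2.8]` rad.
#' @param delta Phase step used in `"fixed"` mode.
#' @return The manifest, invisibly.
#' @export
build_dataset <- function(n_scenes, out_dir, split_ratio = 0.9, seed = 1L,
                          profile = c("desk", "paper"),
                          delta_mode = c("fixed", "random"), delta = pi / 2) {
  profile <- match.arg(profile)
  delta_mode <- match.arg(delta_mode)
  stopifnot(n_scenes >= 2)
  prof <- dataset_profile(profile)
  split <- dataset_split(n_scenes, split_ratio)
  for (d in file.path(out_dir, c("images", "labels", "targets"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  bank <- shape_bank(prof$n_per_class, prof$shape_size,
                     seed = scene_seed(seed, 0L))
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sseed <- scene_seed(seed, i)
    scene <- compose_scene(bank, prof$config$grid_shape, prof$count_range,
                           seed = sseed)
    delta_i <- if (delta_mode == "random") {
      with_seed(scene_seed(seed, n_scenes + i), stats::runif(1, 0.3, 2.8))
    } else delta
    hs <- synthesize_hologram_set(scene$object, prof$config, delta = delta_i)
    target <- two_step_reconstruct(hs, prof$config)
    holo <- normalize_image(hs$I1)
    name <- sprintf("scene_%05d", i)
    write_pgm(holo, file.path(out_dir, "images", paste0(name, ".pgm")))
    write_pgm(target, file.path(out_dir, "targets", paste0(name, ".pgm")))
    write_yolo_labels(scene$spec$boxes,
                      file.path(out_dir, "labels", paste0(name, ".txt")))
    scenes[[i]] <- list(name = name, seed = sseed, delta = delta_i,
                        scale = attr(holo, "scale"),
                        n_objects = nrow(scene$spec$boxes),
                        split = if (i <= split[["train"]]) "train" else "test")
  }
  manifest <- list(
    generator = "gpsholo", version = "1",
    profile = profile, seed = as.integer(seed),
    n_scenes = as.integer(n_scenes), split_ratio = split_ratio,
    n_train = split[["train"]], n_test = split[["test"]],
    delta_mode = delta_mode,
    config = list(wavelength = prof$config$wavelength,
                  distance_z = prof$config$distance_z,
                  pixel_pitch = prof$config$pixel_pitch,
                  grid_shape = prof$config$grid_shape,
                  count_range = prof$count_range,
                  shape_size = prof$shape_size),
    scenes = scenes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset built by [build_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A list with `manifest` and, per split, `x` (holograms) and `y`
#'   (target reconstructions) as `H x W x n` arrays plus scene names.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  shp <- as.integer(manifest$config$grid_shape)
  read_split <- function(which) {
    names <- manifest$scenes$name[manifest$scenes$split == which]
    x <- array(0, c(shp[1], shp[2], length(names)))
    y <- array(0, c(shp[1], shp[2], length(names)))
    for (i in seq_along(names)) {
      x[, , i] <- read_pgm(file.path(dir, "images", paste0(names[i], ".pgm")))
      y[, , i] <- read_pgm(file.path(dir, "targets", paste0(names[i], ".pgm")))
    }
    list(x = x, y = y, names = names)
  }
  list(manifest = manifest,
       train = read_split("train"),
       test = read_split("test"))
}
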