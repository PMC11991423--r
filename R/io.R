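#' Write a matrix as a binary PGM image
#'
#' Portable graymap (P5) is the package's plain image format: single
#' channel, 8- or 16-bit, no compression, readable by scikit-image, PIL,
#' ImageMagick and netpbm. Values are clipped to `[0, 1]` and quantized to
#' `maxval` levels.
#'
#' @param img Real matrix with values in `[0, 1]`.
#' @param path Output file path.
#' @param maxval Maximum gray value: 255 (8-bit) or 65535 (16-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  img <- as.matrix(img)
  if (!all(is.finite(img))) stop("image must be finite", call. = FALSE)
  maxval <- as.integer(maxval)
  if (!maxval %in% c(255L, 65535L)) stop("maxval must be 255 or 65535", call. = FALSE)
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval),
            con, eos = NULL)
  # PGM is row-major (English reading order); R matrices are column-major
  v <- as.integer(t(q))
  if (maxval == 255L) {
    writeBin(as.raw(v), con)
  } else {
    writeBin(v, con, size = 2L, endian = "big")
  }
  invisible(path)
}

#' Read a binary or plain PGM image
#'
#' @param path PGM file (P5 binary or P2 plain).
#' @return Real matrix scaled to `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval; '#' comments allowed
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      # skip
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  n <- w * h
  if (magic == "P5") {
    if (maxval <= 255L) {
      v <- as.integer(readBin(con, "raw", n))
    } else {
      v <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  } else if (magic == "P2") {
    v <- scan(con, integer(), n = n, quiet = TRUE)
  } else {
    stop("not a PGM file: ", path, call. = FALSE)
  }
  matrix(v / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' YOLO-format bounding-box record(s)
#'
#' One row per object: integer class id and the box in normalized
#' center form (`xc`, `yc`, `w`, `h`, all fractions of the frame).
#' Coordinates are quantized to the 6-decimal precision of the YOLO text
#' format at construction, with the half-extents clamped so a quantized
#' box can never leave the unit square; written records therefore
#' round-trip through [write_yolo_labels()] / [read_yolo_labels()] with
#' zero coordinate error.
#'
#' @param class_id Integer vector of class indices (>= 0).
#' @param xc,yc,w,h Numeric vectors: box centre and extents in `[0, 1]`.
#' @return A `data.frame` with columns `class_id, xc, yc, w, h`.
#' @export
yolo_record <- function(class_id, xc, yc, w, h) {
  q <- function(v) round(v * 1e6) / 1e6
  qdown <- function(v) floor(v * 1e6 + 1e-9) / 1e6
  class_id <- as.integer(class_id)
  if (any(class_id < 0)) stop("class_id must be non-negative", call. = FALSE)
  xc <- q(xc); yc <- q(yc); w <- q(w); h <- q(h)
  if (any(w <= 0) || any(h <= 0)) stop("box extents must be positive", call. = FALSE)
  w <- pmin(w, qdown(2 * xc), qdown(2 * (1 - xc)))
  h <- pmin(h, qdown(2 * yc), qdown(2 * (1 - yc)))
  bad <- xc - w / 2 < -1e-12 | xc + w / 2 > 1 + 1e-12 |
         yc - h / 2 < -1e-12 | yc + h / 2 > 1 + 1e-12 | w <= 0 | h <= 0
  if (any(bad)) stop("box extends outside the unit square", call. = FALSE)
  data.frame(class_id = class_id, xc = xc, yc = yc, w = w, h = h)
}

#' Write YOLO label file
#'
#' One line per object: `class xc yc w h`, space-separated, 6-decimal fixed.
#'
#' @param records Data frame from [yolo_record()].
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(records, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", records$class_id,
                   records$xc, records$yc, records$w, records$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO label file
#'
#' @param path Label text file (`class xc yc w h` per line).
#' @return A `data.frame` with columns `class_id, xc, yc, w, h`; zero rows
#'   for an empty file.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(class_id = integer(0), xc = numeric(0), yc = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric))
  if (ncol(m) != 5L) stop("expected 5 fields per YOLO label line", call. = FALSE)
  data.frame(class_id = as.integer(m[, 1]), xc = m[, 2], yc = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Read a YOLO-style detection results file
#'
#' One line per detection: `class confidence xc yc w h`.
#'
#' @param path Detection text file.
#' @return A `data.frame` with columns
#'   `class_id, confidence, xc, yc, w, h`.
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(class_id = integer(0), confidence = numeric(0),
                      xc = numeric(0), yc = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric))
  if (ncol(m) != 6L) stop("expected 6 fields per detection line", call. = FALSE)
  data.frame(class_id = as.integer(m[, 1]), confidence = m[, 2],
             xc = m[, 3], yc = m[, 4], w = m[, 5], h = m[, 6])
}
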