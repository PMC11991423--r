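test_that("make_shape is deterministic and produces valid opacity masks", {
  for (cls in 0:3) {
    s1 <- make_shape(cls, size = 20, seed = 100 + cls)
    s2 <- make_shape(cls, size = 20, seed = 100 + cls)
    expect_identical(s1$mask, s2$mask)
    expect_gt(sum(s1$mask > 0), 0)
    expect_lte(max(s1$mask), 1)
    expect_gte(min(s1$mask), 0)
    expect_equal(s1$class_id, cls)
  }
  expect_error(make_shape(4), "class_id")
})

test_that("radial family has 4-fold rotational symmetry of support", {
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (seed in c(5, 50, 500)) {
    s <- make_shape(1, size = 25, seed = seed)
    # embed in a square canvas for exact rotation comparison
    d <- max(dim(s$mask))
    sq <- matrix(0, d, d)
    sq[seq_len(nrow(s$mask)), seq_len(ncol(s$mask))] <- s$mask
    supp <- sq > 0
    overlap <- sum(supp & rot90(supp)) / sum(supp)
    expect_gte(overlap, 0.8)
  }
})

test_that("compose_scene places the requested count with disjoint supports", {
  bank <- shape_bank(2, 13, seed = 1)
  sc <- compose_scene(bank, c(64, 64), c(5, 5), seed = 2)
  expect_equal(nrow(sc$spec$boxes), 5)
  expect_equal(length(sc$spec$placements), 5)
  # a pixel covered by no silhouette transmits fully
  covered <- matrix(FALSE, 64, 64)
  for (p in sc$spec$placements) {
    covered[p$r0:(p$r0 + p$h - 1), p$c0:(p$c0 + p$w - 1)] <- TRUE
  }
  expect_true(all(exp(-sc$object$absorption)[!covered] == 1))
  expect_error(compose_scene(shape_bank(0, 13), c(64, 64), c(2, 4)), "empty")
})

test_that("supports never overlap and boxes stay in frame over 100 scenes", {
  bank <- shape_bank(2, 13, seed = 3)
  for (seed in 1:100) {
    sc <- compose_scene(bank, c(64, 64), c(2, 4), seed = seed)
    n <- length(sc$spec$placements)
    expect_gte(n, 2); expect_lte(n, 4)
    # exhaustive pairwise support intersection on a shared canvas
    canvases <- lapply(sc$spec$placements, function(p) {
      m <- matrix(FALSE, 64, 64)
      mk <- transform_mask_for_test(bank$entries[[p$entry]]$mask, p$rot, p$flip)
      m[p$r0:(p$r0 + p$h - 1), p$c0:(p$c0 + p$w - 1)] <- mk > 0
      m
    })
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        expect_equal(sum(canvases[[i]] & canvases[[j]]), 0)
      }
    }
    b <- sc$spec$boxes
    expect_true(all(b$xc - b$w / 2 >= -1e-12 & b$xc + b$w / 2 <= 1 + 1e-12))
    expect_true(all(b$yc - b$h / 2 >= -1e-12 & b$yc + b$h / 2 <= 1 + 1e-12))
    expect_true(all(b$class_id %in% 0:3))
  }
})

test_that("scene composition is deterministic given the seed", {
  bank <- shape_bank(2, 13, seed = 4)
  a <- compose_scene(bank, c(64, 64), c(2, 4), seed = 99)
  b <- compose_scene(bank, c(64, 64), c(2, 4), seed = 99)
  expect_identical(a$object$absorption, b$object$absorption)
  expect_identical(a$spec$boxes, b$spec$boxes)
})

test_that("synthesized hologram sets follow the forward model", {
  sc <- desk_scene(55)
  hs <- sc$holoset
  expect_s3_class(hs, "hologram_set")
  expect_equal(hs$Ir, matrix(1, 64, 64))
  expect_equal(hs$delta, pi / 2)
  # empty object: plane-plane interference gives a constant map
  cfg <- desk_config(32L, z = 1e-3)
  empty <- transmission_object(matrix(0, 32, 32))
  h0 <- synthesize_hologram_set(empty, cfg, delta = pi / 2)
  expect_lt(stats::sd(h0$I1), 1e-10)
  kz <- 2 * pi / cfg$wavelength * cfg$distance_z
  expect_equal(h0$I1[1, 1], Mod(exp(1i * kz) + 1)^2, tolerance = 1e-10)
  # round trip through the reconstruction
  rec <- two_step_reconstruct(hs, sc$config)
  truth <- exp(-sc$scene$object$absorption)
  expect_gt(ssim(rec, truth / max(truth)), 0.99)
  expect_error(synthesize_hologram_set(empty, cfg, delta = 0), "degenerate")
})

test_that("normalized exports peak at exactly 1", {
  sc <- desk_scene(66)
  norm <- normalize_image(sc$holoset$I1)
  expect_identical(max(norm), 1)
  expect_equal(attr(norm, "scale"), max(sc$holoset$I1))
})

test_that("dataset_split reproduces the 9000/1000 partition", {
  expect_equal(dataset_split(10000, 0.9), c(train = 9000L, test = 1000L))
  expect_equal(dataset_split(10, 0.9), c(train = 9L, test = 1L))
  expect_equal(dataset_split(550, 500 / 550), c(train = 500L, test = 50L))
  expect_error(dataset_split(1, 0.9))
})

test_that("build_dataset writes a coherent, reproducible tree", {
  d1 <- file.path(tempdir(), "ds_a")
  d2 <- file.path(tempdir(), "ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- build_dataset(10, d1, split_ratio = 0.9, seed = 77)
  m2 <- build_dataset(10, d2, split_ratio = 0.9, seed = 77)
  expect_equal(m1$n_train, 9L)
  expect_equal(m1$n_test, 1L)
  # identical seeds give byte-identical trees (manifest included)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  expect_equal(length(list.files(file.path(d1, "images"))), 10L)
  # exported holograms peak at exactly 1 (up to 16-bit quantization none:
  # the maximum pixel maps to maxval exactly)
  img <- read_pgm(file.path(d1, "images", "scene_00001.pgm"))
  expect_identical(max(img), 1)
  # labels round-trip and match the manifest object counts
  lab <- read_yolo_labels(file.path(d1, "labels", "scene_00001.txt"))
  expect_equal(nrow(lab), m1$scenes[[1]]$n_objects)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("YOLO records round-trip through write and read exactly", {
  set.seed(31)
  recs <- yolo_record(sample(0:3, 25, TRUE),
                      xc = stats::runif(25, 0.2, 0.8),
                      yc = stats::runif(25, 0.2, 0.8),
                      w = stats::runif(25, 0.01, 0.3),
                      h = stats::runif(25, 0.01, 0.3))
  path <- tempfile(fileext = ".txt")
  write_yolo_labels(recs, path)
  back <- read_yolo_labels(path)
  expect_identical(back$class_id, recs$class_id)
  for (col in c("xc", "yc", "w", "h")) {
    expect_lt(max(abs(back[[col]] - recs[[col]])), 1e-9)
  }
  # edge-touching boxes survive quantization without leaving the frame
  edge <- yolo_record(0, xc = 127 / 128, yc = 0.5, w = 1 / 64, h = 0.25)
  expect_lte(edge$xc + edge$w / 2, 1)
  unlink(path)
})

test_that("load_dataset returns arrays aligned with the manifest", {
  d <- file.path(tempdir(), "ds_load")
  unlink(d, recursive = TRUE)
  build_dataset(6, d, split_ratio = 2 / 3, seed = 12)
  ds <- load_dataset(d)
  expect_equal(dim(ds$train$x), c(64, 64, 4))
  expect_equal(dim(ds$test$x), c(64, 64, 2))
  expect_true(all(ds$train$x >= 0 & ds$train$x <= 1))
  expect_true(all(ds$train$y >= 0 & ds$train$y <= 1))
  unlink(d, recursive = TRUE)
})
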