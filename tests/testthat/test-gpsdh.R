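test_that("hologram_set validates frames and the recorded phase step", {
  m <- matrix(1, 8, 8)
  expect_s3_class(hologram_set(m, m, m, m, delta = 1), "hologram_set")
  expect_error(hologram_set(m, m, m, matrix(1, 8, 9)), "shape")
  expect_error(hologram_set(m, m, m - 2, m), "non-negative")
  expect_error(hologram_set(m, m, m, m, delta = 0), "degenerate")
  expect_error(hologram_set(m, m, m, m, delta = pi), "degenerate")
})

test_that("ar_from_reference is the root of the spatial mean", {
  expect_equal(ar_from_reference(matrix(4, 8, 8)), 2)
  expect_equal(ar_from_reference(matrix(1, 8, 8)), 1)
  set.seed(5)
  ir <- matrix(stats::runif(64, 0.9, 1.1), 8, 8)
  expect_equal(ar_from_reference(ir), sqrt(sum(ir) / 64))
  expect_error(ar_from_reference(matrix(0, 8, 8)), "zero")
})

test_that("hand-computed single-amplitude case recovers Uo = 1 + 0i", {
  # A_o = 1, A_r = 1, phi_o = 0, delta = pi/2:
  # I1 = 4, I2 = 2, Io = 1, Ir = 1
  m <- function(v) matrix(v, 8, 8)
  hs <- hologram_set(m(4), m(2), m(1), m(1), delta = pi / 2)
  u <- reconstruct_object_wave(hs, pi / 2, A_r = 1)
  expect_equal(u$values, m(1 + 0i))
  expect_equal(u$plane, "recording_plane")
})

test_that("object-wave recovery is exact for any simulated field", {
  set.seed(13)
  for (delta in c(pi / 3, 0.3, 2.8)) {
    n <- 16L
    ao <- matrix(stats::runif(n * n, 0, 1.5), n, n)
    phi <- matrix(stats::runif(n * n, -pi, pi), n, n)
    uo <- ao * exp(1i * phi)
    A_r <- 1.3
    I1 <- Mod(uo + A_r)^2
    I2 <- Mod(uo + A_r * exp(1i * delta))^2
    hs <- hologram_set(I1, I2, ao^2, matrix(A_r^2, n, n), delta = delta)
    got <- reconstruct_object_wave(hs, delta, A_r)$values
    expect_lt(max(Mod(got - uo)) / max(Mod(uo)), 1e-8)
  }
})

test_that("recovery is linear in the object wave", {
  set.seed(17)
  n <- 16L
  uo <- matrix(complex(real = stats::rnorm(n * n), imaginary = stats::rnorm(n * n)),
               n, n) * 0.3
  make_set <- function(u, delta = 1.1, A_r = 1) {
    hologram_set(Mod(u + A_r)^2, Mod(u + A_r * exp(1i * delta))^2,
                 Mod(u)^2, matrix(A_r^2, n, n), delta = delta)
  }
  base <- reconstruct_object_wave(make_set(uo), 1.1, 1)$values
  for (c_scale in c(0.5, 2)) {
    scaled <- reconstruct_object_wave(make_set(c_scale * uo), 1.1, 1)$values
    expect_equal(scaled, c_scale * base, tolerance = 1e-10)
  }
})

test_that("zero object wave yields a zero reconstruction", {
  n <- 8L
  hs <- hologram_set(matrix(1, n, n), matrix(1, n, n), matrix(0, n, n),
                     matrix(1, n, n), delta = pi / 2)
  u <- reconstruct_object_wave(hs, pi / 2, 1)
  expect_equal(u$values, matrix(0 + 0i, n, n))
})

test_that("degenerate phase steps and amplitudes are rejected", {
  m <- matrix(1, 8, 8)
  hs <- hologram_set(m, m, m, m)
  expect_error(reconstruct_object_wave(hs, 0, 1), "degenerate phase step")
  expect_error(reconstruct_object_wave(hs, pi, 1), "degenerate phase step")
  expect_error(reconstruct_object_wave(hs, 1e-4, 1), "degenerate phase step")
  expect_error(reconstruct_object_wave(hs, pi / 2, 0), "positive")
  expect_error(reconstruct_object_wave(hs, pi / 2, -2), "positive")
})

test_that("phase-step estimation recovers delta on diffuse scenes", {
  sc <- desk_scene(31, n = 128L, phase_mode = "diffuse")
  for (delta in c(0.3, 0.8, pi / 2, 2.0, 2.8)) {
    hs <- synthesize_hologram_set(sc$scene$object, sc$config, delta = delta)
    expect_lt(abs(estimate_phase_shift(hs) - delta), 0.01)
  }
})

test_that("identical interferograms raise an estimation-failure error", {
  sc <- desk_scene(37, n = 64L, phase_mode = "diffuse")
  hs <- sc$holoset
  degen <- hologram_set(hs$I1, hs$I1, hs$Io, hs$Ir)
  expect_error(estimate_phase_shift(degen), "indistinguishable from zero")
})

test_that("two_step_reconstruct inverts the forward model end to end", {
  sc <- desk_scene(41)
  rec <- two_step_reconstruct(sc$holoset, sc$config)
  truth <- exp(-sc$scene$object$absorption)
  expect_gt(ssim(rec, truth / max(truth)), 0.99)
  expect_true(all(rec >= 0 & rec <= 1))
  expect_equal(attr(rec, "delta"), pi / 2)
})

test_that("a blank object reconstructs to a flat amplitude image", {
  cfg <- desk_config(32L, z = 1e-3)
  obj <- transmission_object(matrix(0, 32, 32))
  hs <- synthesize_hologram_set(obj, cfg, delta = pi / 2)
  rec <- two_step_reconstruct(hs, cfg)
  expect_lt(stats::sd(rec) / mean(rec), 1e-6)
})

test_that("refocusing selects the correct depth for each object", {
  # two small discs multiplexed at different depths; reconstructing at each
  # depth maximizes that object's edge-gradient energy
  n <- 64L
  z1 <- 1.4e-3; z2 <- 2.2e-3
  disc <- function(ci, cj) {
    a <- matrix(0, n, n)
    ij <- expand.grid(i = 1:n, j = 1:n)
    r2 <- (ij$i - ci)^2 + (ij$j - cj)^2
    a[r2 <= 16] <- 3
    a
  }
  cfg1 <- desk_config(n, z = z1); cfg2 <- desk_config(n, z = z2)
  o1 <- transmission_object(disc(20, 20))
  o2 <- transmission_object(disc(45, 45))
  # plane of o1 sits z1 from the sensor, o2 at z2 (z2 > z1)
  u <- transmit(o2, plane_wave(cfg2))
  u <- fresnel_propagate(u, z2 - z1, cfg2)
  u <- transmit(o1, complex_field(u$values))
  uz <- fresnel_propagate(u, z1, cfg1)
  grad_energy <- function(img, rows, cols) {
    gx <- diff(img[rows, cols])
    gy <- t(diff(t(img[rows, cols])))
    sum(gx^2) + sum(gy^2)
  }
  amp_at <- function(z) Mod(fresnel_propagate(uz, -z, desk_config(n, z))$values)
  a1 <- amp_at(z1); a2 <- amp_at(z2)
  expect_gt(grad_energy(a1, 12:28, 12:28), grad_energy(a2, 12:28, 12:28))
  expect_gt(grad_energy(a2, 37:53, 37:53), grad_energy(a1, 37:53, 37:53))
})
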