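test_that("phantom is deterministic, bounded and compactly supported", {
  p1 <- make_phantom(32, 40, 8, seed = 7)
  p2 <- make_phantom(32, 40, 8, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_phantom(32, 40, 8, seed = 8)))
  expect_true(all(abs(p1) <= 1 + 1e-12))
  expect_true(all(is.finite(Mod(p1))))
  # nonzero voxels strictly inside the central 90% box
  nz <- which(abs(p1) > 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] > 32 * 0.05 & nz[, 1] < 32 * 0.95))
  expect_true(all(nz[, 2] > 40 * 0.05 & nz[, 2] < 40 * 0.95))
  expect_error(make_phantom(8, 32, 8), "small")
})

test_that("coil maps have exact spectral support and near-unit mean SOS", {
  S <- make_sensitivities(6, 48, 48, s = 5, seed = 3)
  expect_identical(unclass(S), unclass(make_sensitivities(6, 48, 48, 5, 3)))
  h <- 2L
  ctr <- 48 %/% 2 + 1
  for (v in c(1, 4, 6)) {
    sp <- fftc(S[, , v])
    outside <- abs(sp)
    outside[ctr + (-h:h), ctr + (-h:h)] <- 0
    expect_lt(max(outside), 1e-12)
  }
  sos <- sqrt(apply(abs(unclass(S))^2, c(1, 2), sum))
  expect_equal(mean(sos[13:36, 13:36]), 1, tolerance = 1e-8)
  expect_true(all(sos > 0))
  expect_error(make_sensitivities(4, 48, 48, s = 4), "odd")
  expect_error(make_sensitivities(4, 48, 48, s = 15), "too large")
  # DC-only support gives a spatially constant map
  S1 <- make_sensitivities(1, 32, 32, s = 1, seed = 1)
  expect_lt(diff(range(abs(S1))), 1e-12)
})

test_that("shot phases are band-limited with shot 1 as zero reference", {
  psi <- make_shot_phases(8, 64, 64, amplitude = 3, seed = 5)
  expect_equal(max(abs(psi[, , 1])), 0)
  expect_true(all(abs(psi) <= 3 + 1e-9))
  expect_true(max(abs(psi[, , 2])) >= 0.7 * 3)
  ctr <- 33
  for (j in c(2, 5, 8)) {
    sp <- abs(fftc(psi[, , j]))^2
    inside <- sum(sp[ctr + (-16:15), ctr + (-16:15)])
    expect_lt((sum(sp) - inside) / sum(sp), 1e-6)
  }
  expect_identical(psi, make_shot_phases(8, 64, 64, 3, seed = 5))
  expect_equal(make_shot_phases(4, 32, 32, amplitude = 0, seed = 1),
               array(0, c(32, 32, 4)))
  expect_error(noise_spec(-1), "sigma")
})

test_that("encode applies the forward model with an exact adjoint", {
  sim <- tiny_sim()
  ks <- encode(sim$phantom, sim$sens, sim$psi, sim$pats)
  d <- dim(ks$y)
  expect_equal(d, c(32, 32, 6, 3, 6))
  # sampled entries match the mask; unsampled are exactly zero
  for (j in c(1, 4)) {
    keep <- array(rep(ks$mask[, , j], each = 32), c(32, 32, 6))
    expect_true(all(ks$y[, , , 2, j][!keep] == 0))
    expect_true(any(ks$y[, , , 2, j][keep] != 0))
  }
  op <- selfnav3d:::encode_operator(sim$sens, sim$psi, sim$pats)
  set.seed(1)
  x <- rand_carr(c(32, 32, 6))
  y <- rand_carr(d)
  expect_lt(adjoint_gap(op$forward, op$adjoint, x, y), 1e-12)
  # linearity
  x2 <- rand_carr(c(32, 32, 6))
  lhs <- op$forward(2 * x + (1 - 2i) * x2)
  rhs <- 2 * op$forward(x) + (1 - 2i) * op$forward(x2)
  expect_lt(rel_diff(lhs, rhs), 1e-12)
  # zero in, zero out
  expect_equal(max(Mod(op$forward(array(0i, c(32, 32, 6))))), 0)
})

test_that("fully sampled single-coil encoding inverts by FFT", {
  Nkz <- 4L
  ph <- make_phantom(32, 32, Nkz, seed = 2)
  sens <- make_sensitivities(1, 32, 32, s = 1, seed = 1)
  sens <- sens / as.vector(abs(sens[1, 1, 1]))  # unit constant sensitivity
  psi <- array(0, c(32, 32, Nkz))
  # one synthetic shot per kz plane covering every ky line
  cfg0 <- list(Ny = 32L, Nkz = Nkz, kz_center = Nkz %/% 2L)
  pats <- lapply(seq_len(Nkz) - 1L, function(k) {
    structure(list(params = shot_params(0, NA, NA),
                   lines = cbind(ky = 0:31, kz = rep(k, 32L)),
                   is_kz0_traversal = k == cfg0$kz_center,
                   Ny = 32L, Nkz = Nkz, kz_center = cfg0$kz_center),
              class = "shot_pattern")
  })
  ks <- encode(ph, sens, psi, pats)
  collected <- array(0i, c(32, 32, Nkz))
  for (j in seq_len(Nkz)) collected <- collected + ks$y[, , , 1, j]
  expect_lt(rel_diff(ifftc(collected) * exp(-1i * Arg(sens[1, 1, 1])), ph),
            1e-10)
  # Parseval bookkeeping at full sampling
  expect_equal(sum(abs(collected)^2), sum(abs(ph)^2), tolerance = 1e-10)
})

test_that("noise is reproducible and confined to acquired samples", {
  sim <- tiny_sim()
  ks1 <- encode(sim$phantom, sim$sens, sim$psi, sim$pats,
                noise_spec(0.05, seed = 9))
  ks2 <- encode(sim$phantom, sim$sens, sim$psi, sim$pats,
                noise_spec(0.05, seed = 9))
  expect_identical(ks1$y, ks2$y)
  ks0 <- encode(sim$phantom, sim$sens, sim$psi, sim$pats)
  dif <- ks1$y - ks0$y
  # broadcast the [Ny, Nkz, Nshot] mask to [Nx, Ny, Nkz, Ncoil, Nshot]
  keep <- aperm(array(rep(ks0$mask, 32 * 3), c(32, 6, 6, 32, 3)),
                c(4, 1, 2, 5, 3)) > 0
  expect_true(all(dif[!keep] == 0))
  expect_gt(sd(Re(dif[keep])), 0.04)
})

test_that("calibration volume matches the z-projected coil images", {
  sim <- tiny_sim()
  calib <- make_calibration(sim$phantom, sim$sens)
  ck <- calib_kz0(calib)
  proj <- apply(abs(sim$phantom), c(1, 2), sum) / sqrt(6)
  for (v in 1:3) {
    expect_lt(rel_diff(ifftc(ck[, , v]), proj * sim$sens[, , v]), 1e-10)
  }
  # independent of any shot phases (phases are not an input)
  expect_identical(calib, make_calibration(sim$phantom, sim$sens))
})
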