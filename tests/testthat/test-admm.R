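admm_fixture <- function() {
  memo("admm_fix", {
    sim <- tiny_sim(Nc = 4L)
    ks <- encode(sim$phantom, sim$sens, sim$psi, sim$pats)
    ck <- calib_kz0(make_calibration(sim$phantom, sim$sens))
    G <- calibrate_kernel(ck)
    sos <- sqrt(apply(abs(unclass(sim$sens))^2, c(1, 2), sum))
    Sn <- unclass(sim$sens) /
      array(rep(pmax(sos, 1e-12), 4), dim(sim$sens))
    sn <- extract_selfnav(ks)
    proj <- apply(sim$phantom, c(1, 2), sum)
    c(sim, list(ks = ks, G = G, Sn = Sn, sn = sn, proj = proj,
                support = abs(proj) > 0.1 * max(abs(proj))))
  })
}

test_that("self-navigation extraction books lines correctly", {
  fx <- admm_fixture()
  sn <- fx$sn
  expect_equal(dim(sn$y), c(32L, 32L, 4L, 6L))
  expect_equal(sn$traversal, 1L)
  # traversal shot: every Ry-th ky line selected
  expect_equal(which(sn$sel[, 1]) - 1L, seq.int(0L, 31L, by = 2L))
  # selected lines sum to the combined central-plane line count
  comb <- sampling_masks(fx$pats, fx$cfg)$combined
  expect_equal(sum(sn$sel), sum(comb[, fx$cfg$kz_center + 1L] > 0) +
                 sum(pmax(comb[, fx$cfg$kz_center + 1L] - 1L, 0L)))
  # published-geometry count: one crossing per period -> 5 lines
  cfg180 <- sampling_config(180, 12, 12, Ry = 3, dmax = 15)
  s36 <- basic_shot_trajectory(cfg180, shot_params(0, 0, 0))
  expect_equal(sum(s36$lines[, "kz"] == 6L), 5L)
  # a shot without central-plane lines is rejected
  bad <- fx$ks
  bad$patterns[[2]]$lines[, "kz"] <- 0L
  expect_error(extract_selfnav(bad), "shot 2")
})

test_that("magnitude reference reconstructs the traversal plane", {
  fx <- admm_fixture()
  mr <- magnitude_reference(fx$sn, fx$G)
  expect_true(all(mr$m >= 0))
  sos <- sqrt(apply(abs(unclass(fx$sens))^2, c(1, 2), sum))
  truth <- abs(fx$proj) / sqrt(6) * sos
  expect_lt(nrmse(mr$m, truth), 0.05)
  expect_error(magnitude_reference(list(y = fx$sn$y, sel = fx$sn$sel,
                                        traversal = NA_integer_), fx$G),
               "traversal")
  # fully sampled traversal at Ry = 1 with the data term alone is exact
  cfg1 <- sampling_config(32, 6, 6, Ry = 1, dmax = 4)
  pats1 <- greedy_optimize(cfg1)
  ks1 <- encode(fx$phantom, fx$sens, fx$psi, pats1)
  sn1 <- extract_selfnav(ks1)
  mr1 <- magnitude_reference(sn1, fx$G, lambda1 = 0, cg_iters = 5)
  expect_lt(nrmse(mr1$m, truth), 1e-8)
})

test_that("phase bootstrap recovers smooth shot phases from nav lines", {
  fx <- admm_fixture()
  mr <- magnitude_reference(fx$sn, fx$G)
  phi <- selfnav_phase_fit(fx$sn, mr, fx$Sn)
  expect_true(all(abs(Mod(phi) - 1) < 1e-9 | Mod(phi) == 1))
  truth <- exp(1i * fx$psi)
  mae <- phase_mae(reference_to_shot1(phi), reference_to_shot1(truth),
                   fx$support)
  expect_lt(mae, 0.25)
})

test_that("phase extraction is unit-magnitude and exact on clean data", {
  fx <- admm_fixture()
  # ground-truth kz0 k-space built directly from the forward model
  xt <- array(0i, dim(fx$sn$y))
  for (j in 1:6) for (v in 1:4)
    xt[, , v, j] <- fftc(fx$proj / sqrt(6) * exp(1i * fx$psi[, , j]) *
                           fx$Sn[, , v])
  est <- extract_phase(xt, fx$Sn)
  expect_true(all(Mod(est) > 1 - 1e-9 & Mod(est) < 1 + 1e-9))
  truth <- exp(1i * fx$psi)
  expect_lt(phase_mae(reference_to_shot1(est), reference_to_shot1(truth),
                      fx$support), 0.02)
  # identical shots give identical maps
  xt2 <- xt
  xt2[, , , 3] <- xt2[, , , 2]
  est2 <- extract_phase(xt2, fx$Sn)
  expect_identical(est2[, , 2], est2[, , 3])
})

test_that("Hamming filter acts as the expected spectral window", {
  set.seed(3)
  img <- matrix(rand_cplx(64 * 64), 64, 64)
  # filtering twice equals filtering once with the squared window
  f2 <- hamming_filter(hamming_filter(img, 16), 16)
  h <- 0.54 - 0.46 * cos(2 * pi * seq(0, 15) / 15)
  w <- matrix(0, 64, 64)
  w[33 - 8 + 0:15, 33 - 8 + 0:15] <- outer(h, h)^2
  f2b <- ifftc(fftc(img) * w)
  expect_lt(rel_diff(f2, f2b), 1e-12)
  # DC image only rescaled; Nyquist checkerboard annihilated
  dc <- matrix(1 + 0i, 64, 64)
  fdc <- hamming_filter(dc, 16)
  expect_lt(diff(range(Mod(fdc))), 1e-10)
  nyq <- outer((-1)^(1:64), (-1)^(1:64)) + 0i
  expect_lt(max(Mod(hamming_filter(nyq, 16))), 1e-10)
  expect_error(hamming_filter(matrix(0i, 8, 8), 16), "window")
})

test_that("the ADMM engine runs all modes and logs its objective", {
  fx <- admm_fixture()
  mr <- magnitude_reference(fx$sn, fx$G)
  prm <- admm_params(wH = 6L, N_keep = 100L, admm_iters = 3L,
                     cg_iters = 10L)
  fit <- admm_solve(fx$sn, fx$G, mr, fx$Sn, params = prm)
  expect_s3_class(fit, "admm_result")
  expect_equal(dim(fit$xhat), dim(fx$sn$y))
  expect_equal(nrow(fit$log), 3L)
  expect_true(all(is.finite(fit$log$data)))
  fit_cc <- admm_solve(fx$sn, fx$G, mr, fx$Sn, params = prm,
                       mode = "shots")
  expect_equal(dim(fit_cc$xhat)[3], 1L)
  fit_c <- admm_solve(fx$sn, fx$G, NULL, fx$Sn, params = prm,
                      mode = "coils")
  expect_equal(dim(fit_c$xhat), dim(fx$sn$y))
  expect_equal(max(fit_c$log$shot), 6L)
  # determinism
  fit2 <- admm_solve(fx$sn, fx$G, mr, fx$Sn, params = prm)
  expect_identical(fit$xhat, fit2$xhat)
})

test_that("zero motion phases stay zero through the pipeline", {
  sim <- tiny_sim(Nc = 4L, amplitude = 0)
  ks <- encode(sim$phantom, sim$sens, sim$psi, sim$pats)
  ck <- calib_kz0(make_calibration(sim$phantom, sim$sens))
  G <- calibrate_kernel(ck)
  sos <- sqrt(apply(abs(unclass(sim$sens))^2, c(1, 2), sum))
  Sn <- unclass(sim$sens) / array(rep(pmax(sos, 1e-12), 4), dim(sim$sens))
  sn <- extract_selfnav(ks)
  mr <- magnitude_reference(sn, G)
  prm <- admm_params(wH = 6L, N_keep = 100L, admm_iters = 5L,
                     cg_iters = 10L)
  fit <- admm_solve(sn, G, mr, Sn, params = prm)
  est <- extract_phase(fit$xhat, Sn)
  proj <- apply(sim$phantom, c(1, 2), sum)
  supp <- abs(proj) > 0.1 * max(abs(proj))
  expect_lt(phase_mae(reference_to_shot1(est),
                      array(1 + 0i, dim(est)), supp), 0.05)
})
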