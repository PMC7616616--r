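recon_fixture <- function() {
  memo("recon_fix", {
    sim <- tiny_sim(Nc = 4L, Nkz = 8L)
    ks <- encode(sim$phantom, sim$sens, sim$psi, sim$pats)
    calib <- make_calibration(sim$phantom, sim$sens)
    Gs <- calibrate_slab_kernels(calib)
    sos <- sqrt(apply(abs(unclass(sim$sens))^2, c(1, 2), sum))
    truth_sos <- abs(sim$phantom) * array(rep(sos, 8), dim(sim$phantom))
    c(sim, list(ks = ks, Gs = Gs, truth_sos = truth_sos))
  })
}

test_that("phase-informed forward operator matches the encoder exactly", {
  fx <- recon_fixture()
  Xt <- array(0i, c(32, 32, 8, 4))
  for (v in 1:4)
    Xt[, , , v] <- fftc(fx$phantom *
                          array(rep(fx$sens[, , v], 8), c(32, 32, 8)))
  phi <- exp(1i * fx$psi)
  yf <- forward_operator(Xt, phi, fx$pats)
  expect_lt(rel_diff(yf, fx$ks$y), 1e-10)
  # exact adjoint
  set.seed(11)
  x <- rand_carr(c(32, 32, 8, 4))
  y <- rand_carr(dim(yf))
  expect_lt(adjoint_gap(function(z) forward_operator(z, phi, fx$pats),
                        function(z) forward_operator(z, phi, fx$pats,
                                                     adjoint = TRUE),
                        x, y), 1e-12)
  expect_error(forward_operator(Xt, 2 * phi, fx$pats), "unit")
})

test_that("unit phases with a full non-overlapping union act as identity", {
  Nkz <- 4L
  ph <- make_phantom(24, 24, Nkz, seed = 5)
  sens <- make_sensitivities(2, 24, 24, s = 3, seed = 6)
  pats <- lapply(seq_len(Nkz) - 1L, function(k) {
    structure(list(params = shot_params(0, NA, NA),
                   lines = cbind(ky = 0:23, kz = rep(k, 24L)),
                   is_kz0_traversal = k == Nkz %/% 2L,
                   Ny = 24L, Nkz = Nkz, kz_center = Nkz %/% 2L),
              class = "shot_pattern")
  })
  X <- array(0i, c(24, 24, Nkz, 2))
  for (v in 1:2)
    X[, , , v] <- fftc(ph * array(rep(sens[, , v], Nkz), c(24, 24, Nkz)))
  phi <- array(1 + 0i, c(24, 24, Nkz))
  y <- forward_operator(X, phi, pats)
  stacked <- array(0i, dim(X))
  for (j in seq_len(Nkz)) stacked <- stacked + y[, , , , j]
  expect_lt(rel_diff(stacked, X), 1e-12)
})

test_that("error metrics follow their definitions", {
  set.seed(7)
  a <- array(abs(rnorm(4 * 5 * 3)), c(4, 5, 3))
  b <- array(abs(rnorm(4 * 5 * 3)), c(4, 5, 3))
  expect_equal(nrmse(a, a), 0)
  expect_equal(nrmse(2 * b, b), 1)
  expect_equal(nrmse(a, b), sqrt(sum((a - b)^2)) / sqrt(sum(b^2)))
  expect_error(nrmse(a, 0 * b), "zero")
  expect_error(nrmse(a, b[, , 1:2]), "shape")
  # phase MAE: global offsets are removed, formula matches by hand
  ps <- array(runif(6 * 6 * 2, -1, 1), c(6, 6, 2))
  off <- exp(1i * 0.8)
  expect_lt(phase_mae(exp(1i * ps) * off, exp(1i * ps)), 1e-10)
  est <- exp(1i * (ps + 0.2 * array(rnorm(72), dim(ps))))
  r1 <- (est[, , 1] * Conj(exp(1i * ps[, , 1])))
  o1 <- sum(r1); r1 <- r1 * Conj(o1 / abs(o1))
  r2 <- (est[, , 2] * Conj(exp(1i * ps[, , 2])))
  o2 <- sum(r2); r2 <- r2 * Conj(o2 / abs(o2))
  expect_equal(phase_mae(est, exp(1i * ps)),
               mean(c(mean(abs(Arg(r1))), mean(abs(Arg(r2))))),
               tolerance = 1e-12)
})

test_that("sum-of-squares combination is nonnegative and tight", {
  fx <- recon_fixture()
  X <- array(0i, c(32, 32, 8, 4))
  for (v in 1:4)
    X[, , , v] <- fftc(fx$phantom *
                         array(rep(fx$sens[, , v], 8), c(32, 32, 8)))
  s <- sos_combine(X)
  expect_true(all(s >= 0))
  expect_lt(rel_diff(s, fx$truth_sos), 1e-10)
  # single unit coil: |image|
  X1 <- array(fftc(fx$phantom), c(32, 32, 8, 1))
  expect_lt(rel_diff(sos_combine(X1), abs(fx$phantom)), 1e-12)
  # Parseval-type bound: SOS energy <= sum of coil image energies
  expect_lte(sum(s^2), sum(abs(X)^2) + 1e-8)
})

test_that("slab reconstruction recovers the object with known phases", {
  fx <- recon_fixture()
  X <- reconstruct_slab(fx$ks, exp(1i * fx$psi), fx$Gs, lambda4 = 1,
                        cg_iters = 30)
  expect_s3_class(X, "corrected_kspace")
  nr_true <- nrmse(sos_combine(X), fx$truth_sos)
  expect_lt(nr_true, 0.2)
  # ignoring the phase corruption is strictly worse
  Xn <- reconstruct_slab(fx$ks, array(1 + 0i, c(32, 32, 8)), fx$Gs,
                         lambda4 = 1, cg_iters = 30)
  expect_gt(nrmse(sos_combine(Xn), fx$truth_sos), nr_true)
  expect_error(reconstruct_slab(fx$ks, exp(1i * fx$psi), fx$Gs[1:3]),
               "kernel")
})

test_that("a fully determined acquisition reconstructs near-exactly", {
  # Nshot = Nkz at Ry = 1: every ky column gets Nkz kz samples; with known
  # (zero) phases and strong SPIRiT conditioning the solution is tight
  Nkz <- 8L
  cfg <- sampling_config(32, Nkz, Nkz, Ry = 1, dmax = 4)
  pats <- greedy_optimize(cfg)
  ph <- make_phantom(32, 32, Nkz, seed = 3)
  sens <- make_sensitivities(4, 32, 32, s = 5, seed = 4)
  psi <- array(0, c(32, 32, Nkz))
  ks <- encode(ph, sens, psi, pats)
  cover <- mean(sampling_masks(pats, cfg)$combined > 0)
  Gs <- calibrate_slab_kernels(make_calibration(ph, sens))
  X <- reconstruct_slab(ks, exp(1i * psi), Gs, lambda4 = 1,
                        cg_iters = 120)
  sos <- sqrt(apply(abs(unclass(sens))^2, c(1, 2), sum))
  truth_sos <- abs(ph) * array(rep(sos, Nkz), dim(ph))
  nr <- nrmse(sos_combine(X), truth_sos)
  if (cover >= 1) expect_lt(nr, 1e-3) else expect_lt(nr, 0.05)
})
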