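#' Phase-informed multi-shot forward operator
#'
#' Maps a phase-error-corrected multi-coil 3D k-space to the per-shot
#' sampled measurements: inverse FFT to image space, multiplication by the
#' shot's unit-magnitude 2D phase map (broadcast along z), FFT, and the
#' shot's (ky,kz) sampling mask. Because the phase maps vary only in
#' (x, y), the operator decouples exactly across x after a kx transform;
#' this routine applies the full 3D form. Linear, with an exact adjoint.
#'
#' @param Xhat complex array `[Nx, Ny, Nkz, Ncoil]`.
#' @param phi unit-magnitude complex phase maps `[Nx, Ny, Nshot]`.
#' @param patterns list of `shot_pattern`s.
#' @param adjoint if `TRUE`, `Xhat` must be the 5D data array and the
#'   adjoint is applied.
#' @return `[Nx, Ny, Nkz, Ncoil, Nshot]` array (forward) or
#'   `[Nx, Ny, Nkz, Ncoil]` (adjoint).
#' @export
forward_operator <- function(Xhat, phi, patterns, adjoint = FALSE) {
  if (max(abs(abs(phi) - 1)) > 1e-6)
    stop("phase maps must have unit magnitude")
  if (!adjoint) {
    d <- dim(Xhat)
    Nshot <- length(patterns)
    y <- array(0i, c(d, Nshot))
    for (v in seq_len(d[4])) {
      img <- ifftc(Xhat[, , , v])
      for (j in seq_len(Nshot)) {
        mk <- shot_mask(patterns[[j]], list(Ny = d[2], Nkz = d[3])) > 0
        k <- fftc(img * array(rep(phi[, , j], d[3]), d[1:3]))
        k[!array(rep(mk, each = d[1]), d[1:3])] <- 0i
        y[, , , v, j] <- k
      }
    }
    y
  } else {
    d5 <- dim(Xhat)
    d <- d5[1:4]
    out <- array(0i, d)
    for (v in seq_len(d[4])) {
      acc <- array(0i, d[1:3])
      for (j in seq_len(d5[5])) {
        mk <- shot_mask(patterns[[j]], list(Ny = d[2], Nkz = d[3])) > 0
        k <- Xhat[, , , v, j]
        k[!array(rep(mk, each = d[1]), d[1:3])] <- 0i
        acc <- acc + ifftc(k) *
          array(rep(Conj(phi[, , j]), d[3]), d[1:3])
      }
      out[, , , v] <- fftc(acc)
    }
    out
  }
}

#' Train per-x SPIRiT kernels for the slab reconstruction
#'
#' Transforms the calibration volume along kx and calibrates one ky-kz
#' SPIRiT kernel per x position.
#'
#' @param calib `[Nx, Ny, Nkz, Ncoil]` calibration k-space.
#' @param kernel_size odd kernel width.
#' @param tikhonov Tikhonov weight.
#' @return list of `Nx` `spirit_kernel`s (scope `"slab"`).
#' @export
calibrate_slab_kernels <- function(calib, kernel_size = 5L,
                                   tikhonov = 1e-4) {
  dec <- fftc_along(calib, 1, inverse = TRUE)
  d <- dim(calib)
  lapply(seq_len(d[1]), function(ix) {
    g <- calibrate_kernel(array(dec[ix, , , ], d[2:4]),
                          kernel_size = kernel_size, tikhonov = tikhonov)
    attr(g, "scope") <- "slab"
    g
  })
}

#' Phase-corrected multi-shot SPIRiT slab reconstruction
#'
#' Solves, per x position after kx decoupling, the normal equations of the
#' phase-informed data term plus the SPIRiT penalty
#' `lambda4 ||(G_slab - I) X||^2` by conjugate gradient with a fixed
#' iteration budget, and concatenates the per-x solutions into the
#' corrected 3D k-space.
#'
#' @param kspace a `kspace_data` from [encode()].
#' @param phi unit-magnitude phase maps `[Nx, Ny, Nshot]` (use an all-ones
#'   array for an uncorrected reconstruction).
#' @param G_slab per-x kernels from [calibrate_slab_kernels()].
#' @param lambda4 SPIRiT weight.
#' @param cg_iters CG iterations.
#' @return a `corrected_kspace`: complex `[Nx, Ny, Nkz, Ncoil]` array.
#' @export
reconstruct_slab <- function(kspace, phi, G_slab, lambda4 = 1e-4,
                             cg_iters = 30L) {
  d <- dim(kspace$y)
  Nx <- d[1]; Ny <- d[2]; Nkz <- d[3]; Nc <- d[4]; Nshot <- d[5]
  if (length(G_slab) != Nx) stop("need one slab kernel per x position")
  ydec <- fftc_along(kspace$y, 1, inverse = TRUE)
  masks <- lapply(kspace$patterns, function(p)
    shot_mask(p, list(Ny = Ny, Nkz = Nkz)) > 0)
  Xdec <- array(0i, c(Nx, Ny, Nkz, Nc))
  for (ix in seq_len(Nx)) {
    yx <- array(ydec[ix, , , , ], c(Ny, Nkz, Nc, Nshot))
    phix <- phi[ix, , ]                    # [Ny, Nshot]
    G <- G_slab[[ix]]
    Ef <- function(X) {
      img <- fft2_all(X, inverse = TRUE)   # (y, z, coil)
      out <- array(0i, c(Ny, Nkz, Nc, Nshot))
      for (j in seq_len(Nshot)) {
        kj <- fft2_all(img * array(rep(phix[, j], Nkz * Nc),
                                   c(Ny, Nkz, Nc)))
        kj[!array(rep(masks[[j]], Nc), c(Ny, Nkz, Nc))] <- 0i
        out[, , , j] <- kj
      }
      out
    }
    Eh <- function(y5) {
      acc <- array(0i, c(Ny, Nkz, Nc))
      for (j in seq_len(Nshot)) {
        kj <- y5[, , , j]
        kj[!array(rep(masks[[j]], Nc), c(Ny, Nkz, Nc))] <- 0i
        acc <- acc + fft2_all(kj, inverse = TRUE) *
          array(rep(Conj(phix[, j]), Nkz * Nc), c(Ny, Nkz, Nc))
      }
      fft2_all(acc)
    }
    Aop <- function(X) {
      t1 <- apply_kernel(G, X) - X
      Eh(Ef(X)) + lambda4 *
        (apply_kernel(G, t1, adjoint = TRUE) - t1)
    }
    Xdec[ix, , , ] <- cg_solve(Aop, Eh(yx), array(0i, c(Ny, Nkz, Nc)),
                               cg_iters)
  }
  structure(fftc_along(Xdec, 1), class = "corrected_kspace")
}

#' Sum-of-squares coil combination of a 3D k-space
#'
#' @param Xhat `[Nx, Ny, Nkz, Ncoil]` corrected k-space.
#' @return real nonnegative `[Nx, Ny, Nkz]` magnitude volume.
#' @export
sos_combine <- function(Xhat) {
  d <- dim(Xhat)
  acc <- array(0, d[1:3])
  for (v in seq_len(d[4])) acc <- acc + abs(ifftc(Xhat[, , , v]))^2
  sqrt(acc)
}

#' Normalized root-mean-square error
#'
#' `||recon - reference|| / ||reference||` over magnitude volumes (complex
#' inputs are reduced to magnitudes first).
#'
#' @param recon,reference arrays of identical shape.
#' @return nonnegative number.
#' @export
nrmse <- function(recon, reference) {
  if (is.complex(recon)) recon <- abs(recon)
  if (is.complex(reference)) reference <- abs(reference)
  if (!all(dim(recon) == dim(reference))) stop("shape mismatch")
  nref <- sqrt(sum(reference^2))
  if (nref == 0) stop("zero reference norm")
  sqrt(sum((recon - reference)^2)) / nref
}

#' Circular mean absolute phase error
#'
#' Mean over a mask and over shots of `|angle(est * conj(truth))|` after
#' removing each shot's global phase offset (the magnitude-weighted
#' circular mean of the phase difference over the mask). Inputs may be
#' unit-magnitude complex maps or real phase maps in radians.
#'
#' @param est,truth `[Nx, Ny, Nshot]` phase maps.
#' @param mask logical `[Nx, Ny]` evaluation region (default: all).
#' @return MAE in radians.
#' @export
phase_mae <- function(est, truth, mask = NULL) {
  if (!is.complex(est)) est <- exp(1i * est)
  if (!is.complex(truth)) truth <- exp(1i * truth)
  if (!all(dim(est) == dim(truth))) stop("shape mismatch")
  d <- dim(est)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  errs <- vapply(seq_len(d[3]), function(j) {
    r <- (est[, , j] * Conj(truth[, , j]))[mask]
    off <- sum(r)
    if (abs(off) > 0) r <- r * Conj(off / abs(off))
    mean(abs(Arg(r)))
  }, numeric(1))
  mean(errs)
}
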