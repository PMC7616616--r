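#' SPIRiT self-consistency kernel calibration
#'
#' Fits, by Tikhonov-regularized least squares on fully sampled calibration
#' k-space, a kernel expressing every k-space sample of every coil as a
#' linear combination of its `kernel_size x kernel_size` multi-coil
#' neighborhood (the sample's own center weight is excluded and stored as
#' zero). A fully sampled multi-coil k-space consistent with the
#' calibration coils is then (approximately) a fixed point of the kernel.
#'
#' @param calib fully sampled multi-coil 2D k-space `[Nx, Ny, Ncoil]`.
#' @param kernel_size odd kernel width (default 5).
#' @param tikhonov Tikhonov weight, scaled by `trace(A^H A)/ncol`; must be
#'   `> 0` unless the normal equations happen to be well conditioned.
#' @return a `spirit_kernel`: complex array
#'   `[kernel_size, kernel_size, Ncoil_in, Ncoil_out]` with zero own-center
#'   weights.
#' @export
calibrate_kernel <- function(calib, kernel_size = 5L, tikhonov = 1e-4) {
  d <- dim(calib)
  if (length(d) != 3) stop("calib must be [Nx, Ny, Ncoil]")
  w <- as.integer(kernel_size)
  if (w %% 2 == 0) stop("kernel_size must be odd")
  if (d[1] < w + 2 || d[2] < w + 2) stop("calibration grid too small")
  Nc <- d[3]
  A <- build_hankel(calib, w)            # [npatch x w^2*Nc], plane-major
  npar <- ncol(A)
  if (nrow(A) < npar - 1 && tikhonov <= 0)
    stop("under-determined calibration; use tikhonov > 0")
  AtA <- crossprod(Conj(A), A)
  lam <- tikhonov * Re(sum(diag(AtA))) / npar
  ctr <- (w * w + 1L) %/% 2L             # own-center offset index within a plane
  G <- array(0i, c(w, w, Nc, Nc))
  for (vout in seq_len(Nc)) {
    own <- (vout - 1L) * w * w + ctr
    keep <- setdiff(seq_len(npar), own)
    lhs <- AtA[keep, keep]
    diag(lhs) <- diag(lhs) + lam
    g <- tryCatch(solve(lhs, AtA[keep, own]),
                  error = function(e)
                    stop("singular normal equations; use tikhonov > 0"))
    full <- complex(npar)
    full[keep] <- g
    G[, , , vout] <- array(full, c(w, w, Nc))
  }
  structure(G, class = "spirit_kernel", scope = "kz0")
}

#' @export
print.spirit_kernel <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spirit_kernel> %dx%d, %d -> %d coils (scope: %s)\n",
              d[1], d[2], d[3], d[4], attr(x, "scope")))
  invisible(x)
}

# kernel array -> [Cin, Cout, w^2] cube for the C++ routine
kernel_cube <- function(G) {
  d <- dim(G)
  aperm(array(G, c(d[1] * d[2], d[3], d[4])), c(2, 3, 1))
}

#' Apply a SPIRiT kernel in k-space
#'
#' Convolves multi-coil k-space with the kernel (zero-padded borders):
#' `out_vout(p) = sum_{vin, delta} G[delta, vin, vout] x_vin(p + delta)`.
#' The exact adjoint is available via `adjoint = TRUE`; both directions are
#' linear operators and pass dot-product tests to machine precision.
#'
#' @param G a `spirit_kernel`.
#' @param x complex array `[Nx, Ny, Ncoil]` (or `[Nx, Ny, Ncoil, Nblock]`
#'   to apply the same kernel to several plane groups at once).
#' @param adjoint apply the adjoint operator instead.
#' @param pad `"zero"` (convolution with zero-padded borders) or
#'   `"circular"` (periodic borders, matching the circular k-space
#'   structure of discrete coil-modulated spectra; used inside the
#'   iterative solvers).
#' @return array shaped like `x`.
#' @export
apply_kernel <- function(G, x, adjoint = FALSE, pad = c("zero", "circular")) {
  pad <- match.arg(pad)
  d <- dim(x)
  Nc <- dim(G)[3]
  if (d[3] != Nc) stop("coil count mismatch")
  nblock <- if (length(d) == 4) d[4] else 1L
  xx <- x
  dim(xx) <- c(d[1], d[2], Nc * nblock)
  if (pad == "zero") {
    out <- cpp_spirit_apply(as.vector(xx), as.vector(kernel_cube(unclass(G))),
                            d[1], d[2], Nc, Nc, dim(G)[1],
                            as.integer(nblock), isTRUE(adjoint))
  } else {
    Kimg <- kernel_image(G, d[1], d[2])
    if (isTRUE(adjoint)) Kimg <- Conj(aperm(Kimg, c(1, 2, 4, 3)))
    out <- array(0i, dim(xx))
    img <- fftc2_slices(xx, inverse = TRUE)
    for (blk in seq_len(nblock)) {
      sl <- (blk - 1L) * Nc
      for (vo in seq_len(Nc)) {
        acc <- matrix(0i, d[1], d[2])
        for (vi in seq_len(Nc))
          acc <- acc + Kimg[, , vi, vo] * img[, , sl + vi]
        out[, , sl + vo] <- acc
      }
    }
    out <- fftc2_slices(out)
  }
  dim(out) <- d
  out
}

# image-domain transfer functions of a k-space kernel (circular borders):
# Kimg[, , vin, vout] multiplies coil vin's image to contribute to vout
kernel_image <- function(G, Nx, Ny) {
  d <- dim(G)
  h <- (d[1] - 1L) %/% 2L
  cx <- Nx %/% 2L + 1L
  cy <- Ny %/% 2L + 1L
  Kimg <- array(0i, c(Nx, Ny, d[3], d[4]))
  for (vi in seq_len(d[3])) for (vo in seq_len(d[4])) {
    spec <- matrix(0i, Nx, Ny)
    spec[cx + seq(-h, h), cy + seq(-h, h)] <- G[, , vi, vo]
    Kimg[, , vi, vo] <- fftc(spec) * sqrt(Nx * Ny)
  }
  Kimg
}

#' Simplified eigenvector coil sensitivity estimation
#'
#' Estimates 2D sensitivity maps from fully sampled kz0-plane calibration
#' k-space: coil images are formed by inverse FFT, a local spatial average
#' of the coil covariance `I_v conj(I_u)` is computed per voxel, and the
#' leading eigenvector gives the sensitivity direction (a single-map
#' eigen-based estimator in the spirit of subspace calibration methods;
#' no soft weighting or secondary maps). Maps are normalized to unit
#' sum-of-squares per voxel, phase-referenced to coil 1, and voxels whose
#' leading eigenvalue falls below `crop_threshold` times the maximum are
#' zeroed.
#'
#' @param calib complex `[Nx, Ny, Ncoil]` kz0 calibration k-space.
#' @param crop_threshold relative eigenvalue cutoff in `[0, 1)`.
#' @param window odd width of the local covariance average.
#' @return a `sensitivity_maps` complex array `[Nx, Ny, Ncoil]`.
#' @export
estimate_sensitivities <- function(calib, crop_threshold = 0.05,
                                   window = 3L) {
  d <- dim(calib)
  Nc <- d[3]
  imgs <- array(0i, d)
  for (v in seq_len(Nc)) imgs[, , v] <- ifftc(calib[, , v])
  h <- (window - 1L) %/% 2L
  box <- function(m) {
    # zero-padded box average
    out <- matrix(0i, d[1], d[2])
    for (a in -h:h) for (b in -h:h) {
      i <- seq_len(d[1]) + a
      j <- seq_len(d[2]) + b
      ok_i <- i >= 1 & i <= d[1]
      ok_j <- j >= 1 & j <= d[2]
      out[ok_i, ok_j] <- out[ok_i, ok_j] + m[i[ok_i], j[ok_j]]
    }
    out / window^2
  }
  cov <- array(0i, c(d[1], d[2], Nc, Nc))
  for (u in seq_len(Nc)) for (v in seq_len(u)) {
    cuv <- box(imgs[, , u] * Conj(imgs[, , v]))
    cov[, , u, v] <- cuv
    if (u != v) cov[, , v, u] <- Conj(cuv)
  }
  S <- array(0i, d)
  ev <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    e <- eigen(matrix(cov[i, j, , ], Nc, Nc), symmetric = TRUE)
    ev[i, j] <- e$values[1]
    S[i, j, ] <- e$vectors[, 1]
  }
  keep <- ev >= crop_threshold * max(ev)
  for (v in seq_len(Nc)) S[, , v][!keep] <- 0i
  # phase-reference to coil 1
  ref <- S[, , 1]
  ph <- ifelse(abs(ref) > 0, Conj(ref) / abs(ref), 1 + 0i)
  for (v in seq_len(Nc)) S[, , v] <- S[, , v] * ph
  structure(S, class = "sensitivity_maps")
}

#' SVD coil compression
#'
#' Fits an orthonormal compression matrix on calibration data and applies
#' it along the coil dimension. With `target == Ncoil` the rotation is
#' unitary and preserves energy exactly.
#'
#' @param calib array whose last dimension is coils, used to fit the
#'   compression (typically calibration k-space).
#' @param target number of virtual coils to keep (>= 1).
#' @return list with `matrix` (`Ncoil x target`, orthonormal columns) and
#'   `energy` (fraction of calibration energy retained).
#' @export
coil_compression <- function(calib, target) {
  d <- dim(calib)
  Nc <- d[length(d)]
  if (target < 1) stop("target must be >= 1")
  if (target > Nc) stop("target exceeds coil count")
  M <- matrix(calib, ncol = Nc)
  s <- svd(M, nu = 0, nv = Nc)
  list(matrix = s$v[, seq_len(target), drop = FALSE],
       energy = sum(s$d[seq_len(target)]^2) / sum(s$d^2))
}

#' @rdname coil_compression
#' @param x array whose last dimension is coils (k-space or images).
#' @param compression a `coil_compression()` result (or its `matrix`).
#' @return `compress_coils`: array like `x` with the coil dimension reduced
#'   to `target`.
#' @export
compress_coils <- function(x, compression) {
  mat <- if (is.list(compression)) compression$matrix else compression
  d <- dim(x)
  Nc <- d[length(d)]
  if (nrow(mat) != Nc) stop("coil count mismatch")
  out <- matrix(x, ncol = Nc) %*% mat
  array(out, c(d[-length(d)], ncol(mat)))
}
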