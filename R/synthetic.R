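#' Synthetic slabs, coils, phases and k-space
#'
#' The forward model generated here is the multi-shot multi-coil 3D-slab
#' acquisition: for shot `j` and coil `v`,
#' `y_jv = M_j F ( S_v . exp(i psi_j) . rho ) + n_jv`,
#' with `rho` the complex slab image, `S_v` a smooth 2D coil sensitivity
#' (shared across the thin slab), `psi_j` a smooth 2D motion-induced phase
#' (broadcast along z), `F` the centered orthonormal 3D FFT, `M_j` the
#' shot's (ky,kz) line mask (kx fully sampled) and `n` i.i.d. complex
#' Gaussian noise. Shot 1 is the phase reference (`psi_1 = 0`).
#'
#' @name synthetic-data
NULL

# evaluate expr with a private, restored RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic complex slab phantom
#'
#' Overlapping ellipsoids with piecewise-constant magnitude in `[0, 1]`, a
#' smooth low-order background phase, and a slab profile that tapers along
#' z. All nonzero voxels lie strictly inside the central 90% box, so the
#' periodic FFT introduces no wrap-around of signal.
#'
#' @param Nx,Ny grid size (each >= 16).
#' @param Nz slab thickness in slices (>= 4).
#' @param seed integer seed; the same seed reproduces the same phantom.
#' @return complex array `[Nx, Ny, Nz]`.
#' @export
make_phantom <- function(Nx, Ny, Nz, seed = 1L) {
  if (min(Nx, Ny) < 16 || Nz < 4) stop("grid too small")
  with_seed(seed, {
    x <- (seq_len(Nx) - 1 - Nx %/% 2) / (Nx / 2)
    y <- (seq_len(Ny) - 1 - Ny %/% 2) / (Ny / 2)
    z <- (seq_len(Nz) - 1 - Nz %/% 2) / (Nz / 2)
    X <- array(rep(x, times = Ny * Nz), c(Nx, Ny, Nz))
    Y <- array(rep(rep(y, each = Nx), times = Nz), c(Nx, Ny, Nz))
    Z <- array(rep(z, each = Nx * Ny), c(Nx, Ny, Nz))
    mag <- array(0, c(Nx, Ny, Nz))
    # outer "head" ellipsoid, strictly inside the central 90% box
    outer <- (X / 0.82)^2 + (Y / 0.78)^2 + (Z / 0.85)^2 <= 1
    mag[outer] <- 0.55
    n_ell <- 5L
    for (k in seq_len(n_ell)) {
      cx <- runif(3, -0.35, 0.35)
      ax <- runif(3, 0.12, 0.38)
      amp <- runif(1, -0.35, 0.45)
      e <- ((X - cx[1]) / ax[1])^2 + ((Y - cx[2]) / ax[2])^2 +
        ((Z - cx[3]) / ax[3])^2 <= 1
      mag[e & outer] <- mag[e & outer] + amp
    }
    mag <- pmin(pmax(mag, 0), 1)
    # slab excitation profile: flat core, smooth taper, zero at outer slices
    prof <- rep(1, Nz)
    edge <- pmax(abs(z) - 0.55, 0) / 0.35
    prof <- pmax(1 - edge^2, 0)
    mag <- sweep(mag, 3, prof, `*`)
    ph <- runif(1, -1, 1) + 0.8 * runif(1, -1, 1) * X +
      0.8 * runif(1, -1, 1) * Y + 0.5 * runif(1, -1, 1) * X * Y +
      0.4 * runif(1, -1, 1) * (X^2 - Y^2) + 0.3 * runif(1, -1, 1) * Z
    mag * exp(1i * ph)
  })
}

#' Band-limited synthetic coil sensitivities
#'
#' Each 2D coil map is synthesized directly in k-space on an `s x s`
#' centered support (a strong shared smooth base plus coil-specific random
#' low-frequency structure, Gaussian-tapered), so the centered spectrum of
#' every map is exactly zero outside the `s x s` block. A single global
#' scale sets the mean voxelwise sum-of-squares to 1 over the central
#' field of view (per-voxel normalization would break the spectral
#' support).
#'
#' @param Ncoil number of coils.
#' @param Nx,Ny grid size.
#' @param s odd spectral support size, `s <= min(Nx, Ny) / 4`.
#' @param seed integer seed.
#' @return a `coil_sensitivities` object: complex array `[Nx, Ny, Ncoil]`
#'   with attribute `support` = `s`.
#' @export
make_sensitivities <- function(Ncoil, Nx, Ny, s = 5L, seed = 1L) {
  if (s %% 2 == 0) stop("spectral support s must be odd")
  if (s > min(Nx, Ny) / 4) stop("s too large for grid")
  with_seed(seed, {
    h <- (s - 1L) / 2L
    d <- seq(-h, h)
    # The coil system concentrates on four strong orthonormal coil-space
    # modes - DC and three first-order harmonics - plus a weak tapered
    # random remainder. The harmonics give the spatial diversity parallel
    # imaging needs while the 4-mode structure makes the array highly
    # compressible, emulating the strong coil correlation of real arrays.
    modes <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    wmode <- c(1, 0.4, 0.4, 0.4)
    ok <- abs(modes[, 1]) <= h & abs(modes[, 2]) <= h
    modes <- modes[ok, , drop = FALSE]
    wmode <- wmode[ok]
    nm <- min(nrow(modes), Ncoil)
    U <- qr.Q(qr(matrix(complex(real = rnorm(Ncoil * nm),
                                imaginary = rnorm(Ncoil * nm)), Ncoil, nm)))
    taper <- as.vector(exp(-outer(d^2, d^2, `+`) / (2 * (s / 3)^2)))
    resid <- matrix(complex(real = rnorm(s * s * Ncoil, sd = 0.02),
                            imaginary = rnorm(s * s * Ncoil, sd = 0.02)),
                    s * s, Ncoil)
    maps <- array(0i, c(Nx, Ny, Ncoil))
    cx <- Nx %/% 2L + 1L
    cy <- Ny %/% 2L + 1L
    for (v in seq_len(Ncoil)) {
      spec_s <- matrix(0i, s, s)
      for (k in seq_len(nm)) {
        io <- h + 1L + modes[k, 1]
        jo <- h + 1L + modes[k, 2]
        spec_s[io, jo] <- spec_s[io, jo] + wmode[k] * U[v, k]
      }
      spec_s <- spec_s + matrix(resid[, v] * taper, s, s)
      spec <- matrix(0i, Nx, Ny)
      spec[cx + d, cy + d] <- spec_s
      maps[, , v] <- ifftc(spec) * sqrt(Nx * Ny)
    }
    sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
    # normalize mean SOS over the central FOV to 1 (global scale only)
    ctr <- list(seq.int(Nx %/% 4 + 1, Nx - Nx %/% 4),
                seq.int(Ny %/% 4 + 1, Ny - Ny %/% 4))
    maps <- maps / mean(sos[ctr[[1]], ctr[[2]]])
    structure(maps, support = as.integer(s), class = "coil_sensitivities")
  })
}

#' Smooth shot-to-shot motion phase maps
#'
#' Shot 1 (the kz0 traversal shot) is the phase reference and has zero
#' phase. Every other shot receives a random band-limited phase: a sum of
#' sinusoids with at most two cycles across the field of view (the discrete
#' frequencies are exact grid harmonics, so the spectral support is a small
#' central block), including ramp-like one-cycle terms, scaled so the peak
#' magnitude is between 70% and 100% of `amplitude`.
#'
#' @param Nshot number of shots.
#' @param Nx,Ny grid size.
#' @param amplitude peak phase magnitude in radians (>= 0).
#' @param seed integer seed.
#' @return real array `[Nx, Ny, Nshot]` of phases in radians.
#' @export
make_shot_phases <- function(Nshot, Nx, Ny, amplitude = 2, seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  with_seed(seed, {
    x <- (seq_len(Nx) - 1) / Nx
    y <- (seq_len(Ny) - 1) / Ny
    X <- outer(x, rep(1, Ny))
    Y <- outer(rep(1, Nx), y)
    psi <- array(0, c(Nx, Ny, Nshot))
    if (amplitude == 0 || Nshot < 2) return(psi)
    for (j in seq_len(Nshot)[-1]) {
      # ramp-like term: one-cycle sinusoids (monotone across the object),
      # the band-limited realization of the linear phase of bulk motion
      th <- runif(1, 0, 2 * pi)
      ph <- rnorm(1) * sin(2 * pi * X + th) +
        rnorm(1) * sin(2 * pi * Y + runif(1, 0, 2 * pi))
      # plus one random smooth sinusoid with at most 2 cycles across FOV
      f <- sample(c(-2, -1, 1, 2), 2, replace = TRUE)
      ph <- ph + rnorm(1, sd = 0.7) *
        cos(2 * pi * (f[1] * X + f[2] * Y) + runif(1, 0, 2 * pi))
      psi[, , j] <- ph / max(abs(ph)) * amplitude * runif(1, 0.7, 1)
    }
    psi
  })
}

#' Noise specification
#'
#' @param sigma standard deviation per real/imaginary channel (>= 0).
#' @param seed integer seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(sigma = 0, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  list(sigma = sigma, seed = as.integer(seed))
}

check_encode_shapes <- function(phantom, sens, phases, patterns) {
  d <- dim(phantom)
  if (length(d) != 3) stop("phantom must be a 3D array")
  if (!all(dim(sens)[1:2] == d[1:2])) stop("sensitivity/phantom shape mismatch")
  if (!all(dim(phases)[1:2] == d[1:2])) stop("phase/phantom shape mismatch")
  if (dim(phases)[3] != length(patterns)) stop("phase/pattern count mismatch")
  if (any(vapply(patterns, function(p) p$Nkz, integer(1)) != d[3]))
    stop("pattern Nkz does not match phantom z dimension")
  invisible(TRUE)
}

# linear encoding operator (no noise): image volume -> sampled k-space
encode_operator <- function(sens, phases, patterns) {
  Ncoil <- dim(sens)[3]
  Nshot <- length(patterns)
  list(
    forward = function(x) {
      d <- dim(x)
      y <- array(0i, c(d[1], d[2], d[3], Ncoil, Nshot))
      for (j in seq_len(Nshot)) {
        mk <- shot_mask(patterns[[j]],
                        list(Ny = d[2], Nkz = d[3])) > 0
        keep <- array(rep(mk, each = d[1]), d)
        xj <- x * array(rep(exp(1i * phases[, , j]), d[3]), d)
        for (v in seq_len(Ncoil)) {
          k <- fftc(xj * array(rep(sens[, , v], d[3]), d))
          k[!keep] <- 0i
          y[, , , v, j] <- k
        }
      }
      y
    },
    adjoint = function(y) {
      d <- dim(y)[1:3]
      x <- array(0i, d)
      for (j in seq_len(Nshot)) {
        mk <- shot_mask(patterns[[j]],
                        list(Ny = d[2], Nkz = d[3])) > 0
        keep <- array(rep(mk, each = d[1]), d)
        acc <- array(0i, d)
        for (v in seq_len(Ncoil)) {
          k <- y[, , , v, j]
          k[!keep] <- 0i
          acc <- acc + ifftc(k) * array(rep(Conj(sens[, , v]), d[3]), d)
        }
        x <- x + acc * array(rep(exp(-1i * phases[, , j]), d[3]), d)
      }
      x
    }
  )
}

#' Encode multi-shot multi-coil k-space
#'
#' Applies the forward model to a phantom: per shot, multiply by the shot
#' phase and each coil sensitivity, take the centered orthonormal 3D FFT,
#' sample the shot's (ky,kz) lines (kx fully sampled) and add complex
#' Gaussian noise to the acquired samples.
#'
#' @param phantom complex `[Nx, Ny, Nz]` array (see [make_phantom()]).
#' @param sens `[Nx, Ny, Ncoil]` coil maps (see [make_sensitivities()]).
#' @param phases `[Nx, Ny, Nshot]` phase maps (see [make_shot_phases()]).
#' @param patterns list of `shot_pattern`s, one per shot.
#' @param noise a [noise_spec()].
#' @return a `kspace_data` object: complex array `y` of shape
#'   `[Nx, Ny, Nkz, Ncoil, Nshot]` (zeros at unsampled positions), logical
#'   `mask` `[Ny, Nkz, Nshot]`, and the input `patterns`.
#' @export
encode <- function(phantom, sens, phases, patterns,
                   noise = noise_spec(0)) {
  check_encode_shapes(phantom, sens, phases, patterns)
  op <- encode_operator(sens, phases, patterns)
  y <- op$forward(phantom)
  d <- dim(phantom)
  mask <- vapply(patterns, function(p)
    shot_mask(p, list(Ny = d[2], Nkz = d[3])) > 0,
    matrix(TRUE, d[2], d[3]))
  dim(mask) <- c(d[2], d[3], length(patterns))
  if (noise$sigma > 0) {
    y <- with_seed(noise$seed, {
      keep <- aperm(array(rep(mask, each = d[1]),
                          c(d[1], d[2], d[3], length(patterns))),
                    c(1, 2, 3, 4))
      n_samp <- sum(keep) * dim(sens)[3]
      noise_vals <- complex(real = rnorm(n_samp, sd = noise$sigma),
                            imaginary = rnorm(n_samp, sd = noise$sigma))
      idx <- 1L
      for (j in seq_along(patterns)) for (v in seq_len(dim(sens)[3])) {
        sel <- array(rep(mask[, , j], each = d[1]), d)
        nsel <- sum(sel)
        yy <- y[, , , v, j]
        yy[sel] <- yy[sel] + noise_vals[idx:(idx + nsel - 1L)]
        y[, , , v, j] <- yy
        idx <- idx + nsel
      }
      y
    })
  }
  structure(list(y = y, mask = mask, patterns = patterns),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf("<kspace_data> %d x %d x %d grid, %d coils, %d shots, %.1f%% sampled\n",
              d[1], d[2], d[3], d[4], d[5],
              100 * mean(x$mask)))
  invisible(x)
}

#' Fully sampled coil calibration k-space
#'
#' Multi-coil 3D k-space of `sens * |phantom|` (magnitude image, no
#' diffusion phase), emulating a separate gradient-echo calibration scan.
#' The central-kz slice of this volume is the kz0-plane calibration used to
#' train the kz0 SPIRiT kernel and to estimate sensitivities; transforming
#' along kx and slicing x gives the per-plane calibration for the slab
#' kernel.
#'
#' @inheritParams encode
#' @return complex array `[Nx, Ny, Nkz, Ncoil]`.
#' @export
make_calibration <- function(phantom, sens) {
  d <- dim(phantom)
  Ncoil <- dim(sens)[3]
  calib <- array(0i, c(d, Ncoil))
  mag <- abs(phantom)
  for (v in seq_len(Ncoil)) {
    calib[, , , v] <- fftc(mag * array(rep(sens[, , v], d[3]), d))
  }
  calib
}

#' Central-plane (kz0) slice of a calibration volume
#'
#' The kz-DC plane of the slab's 3D k-space; its 2D inverse FFT is the
#' z-projected (z-summed, up to the orthonormal scale) coil image of the
#' slab, which shares the 2D coil sensitivities of the slab.
#'
#' @param calib `[Nx, Ny, Nkz, Ncoil]` calibration k-space.
#' @return complex array `[Nx, Ny, Ncoil]`.
#' @export
calib_kz0 <- function(calib) {
  c_idx <- dim(calib)[3] %/% 2L + 1L
  calib[, , c_idx, , drop = TRUE]
}
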