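#' Multi-shot multi-coil block-Hankel matrix
#'
#' Builds the sliding-window (block-Hankel) matrix used by the structured
#' low-rank phase reconstruction. Each `wH x wH` window of each k-space
#' plane becomes one row segment; planes are ordered shot-major,
#' coil-minor, i.e. `H = [Hshot(x1) Hshot(x2) ...]` with
#' `Hshot(xu) = [H1(xu,coil1) ... H1(xu,coilNc)]`. Annihilation relations
#' between shots sharing a magnitude image, and the limited k-space support
#' of coil sensitivities, make this matrix rank-deficient.
#'
#' @param xhat complex array `[Nx, Ny, Ncoil, Nshot]` (or `[Nx, Ny, P]` for
#'   a plain plane stack) of kz0-plane k-space.
#' @param wH window (kernel) size, `wH <= min(Nx, Ny)`.
#' @return complex matrix of shape
#'   `[(Nx-wH+1)(Ny-wH+1)] x [wH^2 * Ncoil * Nshot]`.
#' @export
build_hankel <- function(xhat, wH) {
  d <- dim(xhat)
  if (wH > min(d[1], d[2])) stop("wH too large for grid")
  P <- prod(d[-(1:2)])
  cpp_hankel_build(as.vector(xhat), d[1], d[2], as.integer(P),
                   as.integer(wH))
}

#' Adjoint of the block-Hankel construction
#'
#' Exact linear adjoint (overlap-add): `adjoint_hankel(build_hankel(x))`
#' equals `x` weighted elementwise by the window-count map
#' [hankel_weights()].
#'
#' @param H matrix shaped like a [build_hankel()] output.
#' @param Nx,Ny plane size.
#' @param P number of planes (`Ncoil * Nshot`).
#' @param wH window size.
#' @return complex array `[Nx, Ny, P]`.
#' @export
adjoint_hankel <- function(H, Nx, Ny, P, wH) {
  out <- cpp_hankel_adjoint(H, as.integer(Nx), as.integer(Ny),
                            as.integer(P), as.integer(wH))
  dim(out) <- c(Nx, Ny, P)
  out
}

#' Window-count weights of the Hankel normal operator
#'
#' `adjoint_hankel(build_hankel(x))` multiplies each k-space sample by the
#' number of sliding windows containing it; this returns that count map.
#'
#' @param Nx,Ny plane size.
#' @param wH window size.
#' @return integer matrix `[Nx, Ny]`.
#' @export
hankel_weights <- function(Nx, Ny, wH) {
  cnt1 <- function(n) pmin(seq_len(n), wH, n - wH + 1, rev(seq_len(n)))
  outer(cnt1(Nx), cnt1(Ny))
}

# truncated SVD factors; randomized sketch for large matrices
svd_trunc_factors <- function(M, k, method = c("auto", "exact", "randomized"),
                              oversample = 10L, power = 1L, warm_v = NULL) {
  method <- match.arg(method)
  mn <- min(dim(M))
  k <- min(k, mn)
  if (method == "auto")
    method <- if (mn > 600 && k < mn / 2) "randomized" else "exact"
  if (method == "exact") {
    s <- svd(M, nu = k, nv = k)
    return(list(u = s$u, d = s$d[seq_len(k)], v = s$v, method = "exact"))
  }
  ks <- min(k + oversample, mn)
  if (!is.null(warm_v) && ncol(warm_v) >= ks) {
    # warm-started projection: the previous right singular subspace is an
    # excellent range sketch once the iterates stabilize, so M is
    # truncated within span(V) directly (one large product per call)
    V <- warm_v[, seq_len(ks), drop = FALSE]
    Y <- M %*% V
    s <- svd(Y, nu = k, nv = ks)
    v_new <- V %*% s$v
    return(list(u = s$u, d = s$d[seq_len(k)],
                v = v_new[, seq_len(k), drop = FALSE], v_sketch = v_new,
                method = "randomized"))
  }
  Om <- matrix(complex(real = rnorm(ncol(M) * ks),
                       imaginary = rnorm(ncol(M) * ks)), ncol(M), ks)
  Y <- M %*% Om
  for (q in seq_len(power)) Y <- M %*% Conj(crossprod(M, Conj(Y)))
  Q <- qr.Q(qr(Y))
  B <- crossprod(Conj(Q), M)
  s <- svd(B, nu = k, nv = ks)
  list(u = Q %*% s$u, d = s$d[seq_len(k)],
       v = s$v[, seq_len(k), drop = FALSE], v_sketch = s$v,
       method = "randomized")
}

#' Best rank-N approximation by singular value hard thresholding
#'
#' Retains the `N_keep` largest singular values and their vectors. If the
#' matrix rank is at most `N_keep`, the input is returned to numerical
#' precision. For large matrices (smallest dimension above 600 and
#' `N_keep` well below it) a randomized range sketch with one power
#' iteration computes the truncation; `method = "exact"` forces a full
#' LAPACK SVD.
#'
#' @param M complex or numeric matrix.
#' @param N_keep rank to retain (>= 1).
#' @param method `"auto"` (default), `"exact"`, or `"randomized"`.
#' @return matrix of the same shape with rank at most `N_keep`.
#' @export
svd_hard_threshold <- function(M, N_keep, method = "auto") {
  if (N_keep < 1) stop("N_keep must be >= 1")
  f <- svd_trunc_factors(M, N_keep, method = method)
  f$u %*% (f$d * Conj(t(f$v)))
}
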