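#' Centered FFT utilities
#'
#' All k-space in this package uses the centered convention: the DC component
#' of an `N`-point axis sits at 0-based index `floor(N/2)` (R index
#' `floor(N/2) + 1`), and transforms are orthonormal (scaled by
#' `1/sqrt(prod(N))`), so Parseval's identity holds exactly. These helpers
#' convert between centered image space and centered k-space.
#'
#' @param x numeric or complex array.
#' @param dims integer vector of dimensions to shift (default: all).
#' @return array of the same shape.
#' @name fft-utils
NULL

shift_index <- function(n, k) {
  # circular shift by k: out[i] = in[(i - k - 1) mod n + 1]
  ((seq_len(n) - 1 - k) %% n) + 1
}

shift_dims <- function(x, dims, amounts) {
  d <- dim(x)
  if (is.null(d)) {
    return(x[shift_index(length(x), amounts[1])])
  }
  idx <- lapply(seq_along(d), function(i) seq_len(d[i]))
  for (j in seq_along(dims)) {
    idx[[dims[j]]] <- shift_index(d[dims[j]], amounts[j])
  }
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @rdname fft-utils
#' @export
fftshift <- function(x, dims = NULL) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  if (is.null(dims)) dims <- seq_along(d)
  shift_dims(x, dims, vapply(d[dims], function(n) n %/% 2L, integer(1)))
}

#' @rdname fft-utils
#' @export
ifftshift <- function(x, dims = NULL) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  if (is.null(dims)) dims <- seq_along(d)
  shift_dims(x, dims, vapply(d[dims], function(n) -(n %/% 2L), integer(1)))
}

#' @rdname fft-utils
#' @export
fftc <- function(x) {
  n <- if (is.null(dim(x))) length(x) else prod(dim(x))
  fftshift(stats::fft(ifftshift(x))) / sqrt(n)
}

#' @rdname fft-utils
#' @export
ifftc <- function(x) {
  n <- if (is.null(dim(x))) length(x) else prod(dim(x))
  fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / sqrt(n)
}

# centered orthonormal transform along a single dimension of an array
fftc_along <- function(x, dim, inverse = FALSE) {
  d <- dim(x)
  nd <- length(d)
  if (dim == 1L) {
    m <- matrix(x, nrow = d[1])
    m <- m[shift_index(d[1], -(d[1] %/% 2L)), , drop = FALSE]
    m <- stats::mvfft(m, inverse = inverse)
    m <- m[shift_index(d[1], d[1] %/% 2L), , drop = FALSE] / sqrt(d[1])
    dim(m) <- d
    return(m)
  }
  perm <- c(dim, setdiff(seq_len(nd), dim))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[dim])
  m <- m[shift_index(d[dim], -(d[dim] %/% 2L)), , drop = FALSE]
  m <- stats::mvfft(m, inverse = inverse)
  m <- m[shift_index(d[dim], d[dim] %/% 2L), , drop = FALSE] / sqrt(d[dim])
  xp <- array(m, d[perm])
  aperm(xp, order(perm))
}

# centered orthonormal 2D transform applied to the first two dims of an
# array, batched across all remaining dims
fftc2_slices <- function(x, inverse = FALSE) {
  fftc_along(fftc_along(x, 1L, inverse = inverse), 2L, inverse = inverse)
}
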