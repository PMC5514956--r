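# Internal separable-convolution machinery.
#
# All spatial filtering in the package is exact finite-support correlation
# ("filtering" convention: out[i,j] = sum_{a,b} k[a,b] * x[i+a, j+b]) with
# symmetric (mirror, edge-repeating) boundary padding.  Separable kernels are
# applied as banded matrix products so that batches of images reduce to a few
# large BLAS calls; this is algebraically identical to direct 2-D convolution.

#' @noRd
mirror_index <- function(n, k) {
  if (k == 0L) return(seq_len(n))
  if (k > n) stop("padding exceeds image size", call. = FALSE)
  c(k:1, 1:n, n:(n - k + 1L))
}

# banded matrix applying a 1-D correlation with kernel v (odd length) to a
# mirror-padded axis of length n + 2k; rows index output positions
#' @noRd
conv_band <- function(n, v) {
  k <- (length(v) - 1L) / 2L
  mat <- matrix(0, n, n + 2L * k)
  for (i in seq_len(n)) mat[i, i:(i + 2L * k)] <- v
  mat
}

# exact 2-D correlation of a single image with an arbitrary kernel (odd dims),
# mirror padding; reference implementation used by the modular operations.
#' @noRd
conv2_mirror <- function(x, kernel) {
  ky <- (nrow(kernel) - 1L) / 2L
  kx <- (ncol(kernel) - 1L) / 2L
  n <- nrow(x); m <- ncol(x)
  xp <- x[mirror_index(n, ky), mirror_index(m, kx), drop = FALSE]
  out <- matrix(0, n, m)
  if (is.complex(kernel)) out <- matrix(0i, n, m)
  for (i in seq_len(n)) {
    rows <- i:(i + 2L * ky)
    for (j in seq_len(m)) {
      out[i, j] <- sum(kernel * xp[rows, j:(j + 2L * kx)])
    }
  }
  out
}

# separable 2-D correlation (kernel = outer(vy, vx)) of a single real or
# complex image, mirror padding; exact, BLAS-backed.
#' @noRd
sepconv2_mirror <- function(x, vy, vx) {
  n <- nrow(x); m <- ncol(x)
  ky <- (length(vy) - 1L) / 2L
  kx <- (length(vx) - 1L) / 2L
  xp <- x[mirror_index(n, ky), mirror_index(m, kx), drop = FALSE]
  cy <- conv_band(n, vy)
  cx <- conv_band(m, vx)
  if (is.complex(vy) || is.complex(vx) || is.complex(x)) {
    # split complex matrix products into real BLAS calls (R's complex
    # matrix product is not BLAS-backed)
    cmul <- function(a, b) {
      ar <- Re(a); ai <- Im(a); br <- Re(b); bi <- Im(b)
      complex(real = ar %*% br - ai %*% bi,
              imaginary = ar %*% bi + ai %*% br)
    }
    mid <- matrix(cmul(cy + 0i, xp + 0i), n, m + 2L * kx)
    matrix(cmul(mid, t(cx) + 0i), n, m)
  } else {
    cy %*% xp %*% t(cx)
  }
}

# batched separable real correlation: x3 is an (n, m, B) array (all images
# the same size), vy/vx real kernels; returns (n, m, B).  Compiled.
#' @noRd
sepconv2_batch <- function(x3, vy, vx) {
  sepconv2_batch_cpp(x3, vy, vx)
}
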