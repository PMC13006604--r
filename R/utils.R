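# Internal helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Round to 8-bit, half away from zero
#'
#' Maps values in \[0,1\] to integers in 0..255. Ties (x.5) round away from
#' zero, unlike base `round()` which rounds half to even.
#' @param x numeric array in \[0,1\].
#' @return integer array in 0..255.
#' @keywords internal
to_uint8 <- function(x) {
  storage <- floor(x * 255 + 0.5)
  storage[storage < 0] <- 0
  storage[storage > 255] <- 255
  storage
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# All stochastic operations in the package route through this so they are
# pure functions of (input, parameters, seed).
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a parent seed and a stream label, so one
# top-level seed drives several independent random streams deterministically.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483587L) + 1L
}

# Reflected (symmetric, edge-repeating) index vector for padding:
# for n columns and radius r returns indices of length n + 2r.
reflect_index <- function(n, r) {
  if (r == 0) return(seq_len(n))
  left <- pmin(pmax(seq(r, 1), 1), n)
  right <- pmin(pmax(seq(n, n - r + 1), 1), n)
  c(left, seq_len(n), right)
}

pad_reflect <- function(m, r) {
  m[reflect_index(nrow(m), r), reflect_index(ncol(m), r), drop = FALSE]
}

# Separable 2D convolution with a 1D kernel applied along both axes,
# symmetric-reflection padding. Kernel length must be odd.
conv_separable <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  p <- pad_reflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  # along rows (vertical)
  acc <- matrix(0, nr, nc + 2 * r)
  for (i in seq_along(k)) {
    acc <- acc + k[i] * p[i:(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * acc[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

# Full (non-separable) 3x3 convolution with reflection padding.
conv3x3 <- function(m, kern) {
  p <- pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in 0:2) {
    for (dj in 0:2) {
      w <- kern[di + 1L, dj + 1L]
      if (w != 0) {
        out <- out + w * p[(1L + di):(nr + di), (1L + dj):(nc + dj), drop = FALSE]
      }
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur of a matrix (or each plane of an h x w x k array),
# symmetric-reflection boundary; exactly preserves constants.
blur_gaussian <- function(x, sigma, radius = NULL) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma, radius)
  if (is.matrix(x)) return(conv_separable(x, k))
  out <- x
  for (ch in seq_len(dim(x)[3])) out[, , ch] <- conv_separable(x[, , ch], k)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}
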