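#' @useDynLib carnafold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cor cov rnorm runif rbinom rmultinom rpois sd var
#'   median p.adjust phyper wilcox.test quantile setNames complete.cases
#' @importFrom utils head tail write.table read.table
NULL

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 1D Gaussian kernel truncated at `trunc` standard deviations.
gaussian_kernel <- function(sigma, trunc = 2) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(trunc * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D Gaussian smoothing with edge renormalization; NAs propagate
# unless na_ignore, in which case they are treated as missing mass.
smooth_gaussian2d <- function(m, sigma = 1, trunc = 2, na_ignore = FALSE) {
  k <- gaussian_kernel(sigma, trunc)
  if (length(k) == 1L) return(m)
  conv1 <- function(x) {
    # convolve each column of x with k, renormalizing at edges
    n <- nrow(x); r <- (length(k) - 1L) / 2L
    w <- !is.na(x)
    x0 <- x; x0[!w] <- 0
    num <- matrix(0, n, ncol(x)); den <- matrix(0, n, ncol(x))
    for (t in seq_along(k)) {
      off <- t - 1L - r
      src <- (1:n) + off
      ok <- src >= 1L & src <= n
      num[ok, ] <- num[ok, ] + k[t] * x0[src[ok], , drop = FALSE]
      den[ok, ] <- den[ok, ] + k[t] * w[src[ok], , drop = FALSE]
    }
    out <- num / den
    out[den == 0] <- NA_real_
    if (!na_ignore) out[!w] <- NA_real_
    out
  }
  t(conv1(t(conv1(m))))
}

# Longest run of TRUE in a logical vector.
longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# Symmetrize a square matrix.
symmetrize <- function(m) (m + t(m)) / 2

upper_tri_idx <- function(n, offset = 2L) {
  which(col(diag(n)) - row(diag(n)) >= offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
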