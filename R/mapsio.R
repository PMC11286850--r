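#' Genome bin grid
#'
#' Tiles each chromosome with fixed-size bins and provides the global bin
#' index <-> (chrom, start) mapping. Bin coordinates are 0-based half-open;
#' 1-based .pairs positions are converted exactly once, in [bin_contacts()].
#'
#' @param chromsizes Named vector of chromosome lengths (each a multiple of
#'   `bin_size`; a trailing partial bin is dropped).
#' @param bin_size Bin width in bp (default 2048 = 2^11).
#' @return A `bin_grid` list with `bins` (data.frame chrom, start, index),
#'   `bin_size`, `chromsizes`, `offsets`.
#' @export
bin_grid <- function(chromsizes, bin_size = 2048L) {
  nb <- as.integer(chromsizes) %/% bin_size
  offsets <- cumsum(c(0L, nb[-length(nb)]))
  names(offsets) <- names(chromsizes)
  bins <- do.call(rbind, lapply(seq_along(chromsizes), function(i)
    data.frame(chrom = names(chromsizes)[i],
               start = (seq_len(nb[i]) - 1L) * bin_size)))
  bins$index <- seq_len(nrow(bins))
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 chromsizes = chromsizes, n_bins = nrow(bins),
                 offsets = offsets),
            class = "bin_grid")
}

# Global 1-based bin index of a 1-based genomic position; NA off-grid.
grid_index <- function(grid, chrom, pos) {
  off <- grid$offsets[chrom]
  b <- (pos - 1L) %/% grid$bin_size
  idx <- unname(off + b + 1L)
  nb <- as.integer(grid$chromsizes[chrom]) %/% grid$bin_size
  idx[is.na(off) | b < 0L | b >= nb] <- NA_integer_
  idx
}

#' Bin DNA-DNA contact pairs into a raw contact matrix
#'
#' Each retained read pair increments exactly one (i, j) cell with i <= j;
#' the matrix is stored sparse upper-triangular and symmetrized on densify.
#' Malformed records and unknown chromosomes are skipped and counted.
#'
#' @param pairs data.frame of .pairs records (chrom1, pos1, chrom2, pos2,
#'   1-based positions) or a [read_pairs()] result.
#' @param grid A [bin_grid()].
#' @return List with `mat` (dgCMatrix, upper triangle), `grid`,
#'   `n_retained`, `n_skipped`.
#' @export
bin_contacts <- function(pairs, grid) {
  if (is.list(pairs) && !is.null(pairs$records)) pairs <- pairs$records
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(pairs))) stop("pairs lack required columns")
  ok <- !is.na(pairs$pos1) & !is.na(pairs$pos2) &
    pairs$pos1 >= 1 & pairs$pos2 >= 1
  i <- grid_index(grid, pairs$chrom1, pairs$pos1)
  j <- grid_index(grid, pairs$chrom2, pairs$pos2)
  ok <- ok & !is.na(i) & !is.na(j)
  n_skipped <- sum(!ok)
  if (n_skipped) warning(n_skipped, " records skipped (malformed or off-grid)")
  i <- i[ok]; j <- j[ok]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(grid$n_bins, grid$n_bins))
  list(mat = mat, grid = grid, n_retained = length(i), n_skipped = n_skipped)
}

# Dense symmetric matrix from the upper-triangular store.
densify_contacts <- function(raw) {
  m <- as.matrix(raw$mat)
  d <- diag(m)
  m <- m + t(m)
  diag(m) <- d
  m
}

#' Iterative correction (ICE) balancing
#'
#' Rescales a symmetric contact matrix so every unmasked bin has equal total
#' visibility. Low-coverage bins (marginal below `min_frac` of the nonzero
#' median, or zero) are masked before balancing.
#'
#' @param m Dense symmetric matrix of raw counts.
#' @param max_iter,tol Iteration controls; rows of the balanced matrix over
#'   unmasked bins agree within `tol` (relative) at convergence.
#' @param min_frac Mask threshold relative to the median nonzero marginal.
#' @return List `balanced`, `weights` (per-bin multipliers, NA where masked),
#'   `mask` (logical, TRUE = masked), `converged`.
#' @export
ice_normalize <- function(m, max_iter = 200L, tol = 1e-5, min_frac = 0.1) {
  stopifnot(nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  n <- nrow(m)
  marg <- rowSums(m)
  mask <- marg == 0 | marg < min_frac * median(marg[marg > 0])
  w <- rep(1, n); w[mask] <- 0
  b <- m
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(b)
    s_u <- s[!mask]
    if (!length(s_u)) break
    rel <- s_u / mean(s_u)
    if (max(abs(rel - 1)) < tol) { converged <- TRUE; break }
    adj <- rep(1, n)
    adj[!mask] <- sqrt(rel)
    b <- b / outer(adj, adj)
    w[!mask] <- w[!mask] / adj[!mask]
  }
  # scale so unmasked rows of the balanced matrix sum to 1 (cooler-style):
  # balanced = outer(weights, weights) * raw
  s <- mean(rowSums(b)[!mask])
  if (is.finite(s) && s > 0) {
    b <- b / s
    w[!mask] <- w[!mask] / sqrt(s)
  }
  b[mask, ] <- NA_real_; b[, mask] <- NA_real_
  w[mask] <- NA_real_
  list(balanced = b, weights = w, mask = mask, converged = converged)
}

#' Fill low-coverage entries from dyadic neighborhood averages
#'
#' Entries whose raw support reaches `min_count` are kept; others are
#' replaced by the mean balanced value over the smallest aligned dyadic
#' (2^l x 2^l) block whose summed raw support reaches `min_count`. Entries
#' with no support at any scale stay NA.
#'
#' @param balanced Balanced matrix (NAs allowed at masked bins).
#' @param raw Raw count matrix, same geometry.
#' @param min_count Minimum raw support (default 8).
#' @export
coarsegrain_smooth <- function(balanced, raw, min_count = 8) {
  stopifnot(all(dim(balanced) == dim(raw)))
  n <- nrow(raw)
  out <- balanced
  need <- raw < min_count
  if (!any(need)) return(out)
  bsum <- ifelse(is.na(balanced), 0, balanced)
  bcnt <- matrix(as.numeric(!is.na(balanced)), n, n)
  rsum <- raw
  level_block <- function(m, l) {
    # aggregate into 2^l-aligned blocks (ragged tail allowed)
    f <- ceiling(n / 2^l)
    idx <- (seq_len(n) - 1L) %/% 2^l + 1L
    rowsum_t <- function(x) t(rowsum(t(rowsum(x, idx)), idx))
    rowsum_t(m)
  }
  max_l <- ceiling(log2(n))
  for (l in seq_len(max_l)) {
    rs <- level_block(rsum, l)
    bs <- level_block(bsum, l)
    bc <- level_block(bcnt, l)
    idx <- (seq_len(n) - 1L) %/% 2^l + 1L
    ok_block <- rs >= min_count & bc > 0
    fill <- need & ok_block[cbind(idx[row(raw)], idx[col(raw)])]
    if (any(fill)) {
      vals <- (bs / pmax(bc, 1))[cbind(idx[row(raw)], idx[col(raw)])]
      out[fill] <- vals[fill]
      need <- need & !fill
    }
    if (!any(need)) break
  }
  out
}

#' Observed-over-expected normalization within a window
#'
#' The expected value at diagonal offset d is the mean of the matrix over
#' unmasked entries at that offset (computed within the window); the output
#' is the elementwise ratio. Offsets with zero/undefined expected value are
#' masked.
#'
#' @param m Dense symmetric matrix (NAs = masked entries).
#' @return Matrix of the same geometry.
#' @export
observed_over_expected <- function(m) {
  n <- nrow(m)
  off <- col(m) - row(m)
  exp_d <- vapply(0:(n - 1), function(d) {
    v <- m[off == d]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  exp_d[!is.na(exp_d) & exp_d == 0] <- NA_real_
  e <- exp_d[abs(off) + 1L]
  out <- m / e
  dim(out) <- dim(m)
  out
}

#' Finalize a per-window target map
#'
#' Natural log, clipping to the configured bounds, linear interpolation of
#' masked entries along rows and columns, symmetrization, 2D Gaussian
#' smoothing, and a final re-clip so the bounds are invariant.
#'
#' @param oe Observed/expected matrix for one window (NA = masked).
#' @param clip_bounds Two-element numeric, default c(-2, 2).
#' @param gaussian_sigma Smoothing sigma in bins (0 disables).
#' @param trunc Kernel truncation in sigmas.
#' @param window Optional list(chrom, start) carried as attributes.
#' @return A `target_map`: the finished matrix with attributes `mask`
#'   (interpolated entries) and window metadata.
#' @export
finalize_target <- function(oe, clip_bounds = c(-2, 2), gaussian_sigma = 1,
                            trunc = 2, window = NULL) {
  if (all(is.na(oe))) stop("unusable window: fully masked")
  lg <- suppressWarnings(log(oe))
  lg[is.infinite(lg)] <- NA_real_
  lg <- clip(lg, clip_bounds[1], clip_bounds[2])
  mask <- is.na(lg)
  filled <- interp_na_2d(lg)
  filled <- symmetrize(filled)
  if (gaussian_sigma > 0)
    filled <- smooth_gaussian2d(filled, gaussian_sigma, trunc,
                                na_ignore = TRUE)
  filled <- clip(filled, clip_bounds[1], clip_bounds[2])
  filled <- symmetrize(filled)
  if (anyNA(filled)) {
    # rows/cols with no information anywhere: fall back to 0 (= expected)
    filled[is.na(filled)] <- 0
  }
  structure(filled, mask = mask, window = window, class = c("target_map",
                                                            "matrix"))
}

# Linear interpolation of NAs along rows then columns, averaged.
interp_na_2d <- function(m) {
  fill_rows <- function(x) {
    t(apply(x, 1, function(v) {
      ok <- !is.na(v)
      if (sum(ok) < 2) return(v)
      approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
    }))
  }
  a <- fill_rows(m)
  b <- t(fill_rows(t(m)))
  out <- (a + b) / 2
  only_a <- is.na(b) & !is.na(a); out[only_a] <- a[only_a]
  only_b <- is.na(a) & !is.na(b); out[only_b] <- b[only_b]
  out
}

#' Partition the genome into model windows
#'
#' Non-overlapping (or fixed-stride) windows of `window_bp`, each assigned a
#' split label. Assignment is deterministic: by default a repeating pattern
#' derived from the requested fractions; alternatively an explicit region
#' list (chrom, start, label) is honored verbatim.
#'
#' @param grid A [bin_grid()].
#' @param window_bp Window size (default 2^20).
#' @param stride Stride between window starts (default = window size).
#' @param fractions Named numeric (train/valid/test) summing to 1.
#' @param split_file Optional TSV with columns chrom, start, label.
#' @return data.frame(chrom, start, end, label) — the window set.
#' @export
partition_windows <- function(grid, window_bp = 2^20, stride = window_bp,
                              fractions = c(train = 0.8, valid = 0.1,
                                            test = 0.1),
                              split_file = NULL) {
  wins <- do.call(rbind, lapply(names(grid$chromsizes), function(ch) {
    L <- as.integer(grid$chromsizes[[ch]])
    if (L < window_bp) return(NULL)
    starts <- seq(0L, L - window_bp, by = stride)
    data.frame(chrom = ch, start = starts, end = starts + window_bp)
  }))
  if (!is.null(split_file)) {
    sp <- read.table(split_file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    key <- paste(wins$chrom, wins$start)
    skey <- paste(sp$chrom, sp$start)
    wins$label <- sp$label[match(key, skey)]
    wins <- wins[!is.na(wins$label), , drop = FALSE]
    return(wins)
  }
  n <- nrow(wins)
  # deterministic interleaved assignment honoring the fractions
  counts <- round(fractions * n)
  counts[1] <- n - sum(counts[-1])
  lab <- rep(names(fractions), counts)
  pos <- order(order((seq_len(n) * 7919L) %% n))  # fixed permutation
  wins$label <- lab[pos]
  wins
}

#' Build per-window target maps from a .pairs file
#'
#' The full map-preparation recipe: bin, ICE-balance, coarse-grain fill,
#' then per window observed/expected, log, clip, interpolate, smooth.
#'
#' @param pairs .pairs path or records data.frame.
#' @param grid A [bin_grid()].
#' @param windows data.frame(chrom, start, end) as from
#'   [partition_windows()].
#' @param min_count Coarse-graining support threshold.
#' @param gaussian_sigma Target smoothing sigma (bins).
#' @param clip_bounds Log-ratio clip bounds.
#' @return List of `target_map`s, one per window row.
#' @export
prepare_target_maps <- function(pairs, grid, windows, min_count = 8,
                                gaussian_sigma = 1, clip_bounds = c(-2, 2)) {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  raw <- bin_contacts(pairs, grid)
  dense <- densify_contacts(raw)
  bal <- ice_normalize(dense)
  sm <- coarsegrain_smooth(bal$balanced, dense, min_count = min_count)
  lapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    i0 <- grid_index(grid, ch, windows$start[i] + 1L)
    nb <- (windows$end[i] - windows$start[i]) %/% grid$bin_size
    sub <- sm[i0:(i0 + nb - 1L), i0:(i0 + nb - 1L)]
    oe <- observed_over_expected(sub)
    finalize_target(oe, clip_bounds = clip_bounds,
                    gaussian_sigma = gaussian_sigma,
                    window = list(chrom = ch, start = windows$start[i]))
  })
}
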