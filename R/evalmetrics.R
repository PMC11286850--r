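#' Compare two contact maps
#'
#' MSE, Pearson, Spearman, stratum-adjusted correlation (SCC) and SSIM over
#' the defined entries of the upper triangle (excluding the `offset`
#' diagonal band). Correlations on constant maps are reported as NA.
#'
#' @param a,b Same-geometry matrices.
#' @param offset Excluded diagonal band.
#' @return Named numeric: mse, pearson, spearman, scc, ssim.
#' @export
score_maps <- function(a, b, offset = 2L) {
  stopifnot(all(dim(a) == dim(b)))
  idx <- upper_tri_idx(nrow(a), offset)
  av <- a[idx]; bv <- b[idx]
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]; bv <- bv[ok]
  pear <- if (sd(av) == 0 || sd(bv) == 0) NA_real_ else cor(av, bv)
  spear <- if (sd(av) == 0 || sd(bv) == 0) NA_real_ else
    cor(av, bv, method = "spearman")
  c(mse = mean((av - bv)^2), pearson = pear, spearman = spear,
    scc = scc(a, b, offset = offset), ssim = ssim(a, b))
}

#' Stratum-adjusted correlation coefficient
#'
#' Weighted sum of per-diagonal-offset Pearson correlations. Default weights
#' follow HiCRep: stratum size times the geometric mean of rank variances;
#' `weights = "equal"` uses plain averaging. Zero-variance strata are
#' skipped; if every stratum is degenerate the result is NA.
#'
#' @param a,b Same-geometry matrices.
#' @param offset First diagonal offset included.
#' @param min_entries Minimum entries per stratum.
#' @param weights "hicrep" or "equal".
#' @export
scc <- function(a, b, offset = 2L, min_entries = 2L, weights = "hicrep") {
  n <- nrow(a)
  rs <- ws <- numeric(0)
  for (d in offset:(n - 1)) {
    i <- seq_len(n - d)
    av <- a[cbind(i, i + d)]; bv <- b[cbind(i, i + d)]
    ok <- is.finite(av) & is.finite(bv)
    av <- av[ok]; bv <- bv[ok]
    if (length(av) < min_entries || sd(av) == 0 || sd(bv) == 0) next
    r <- cor(av, bv)
    w <- if (weights == "equal") 1 else
      length(av) * sqrt(var(rank(av)) * var(rank(bv)))
    rs <- c(rs, r); ws <- c(ws, w)
  }
  if (!length(rs) || sum(ws) == 0) return(NA_real_)
  sum(rs * ws) / sum(ws)
}

#' Structural similarity index between two maps
#'
#' Standard SSIM with a Gaussian window and a data range matching the clip
#' span of the target maps (4 for maps clipped to (-2, 2)).
#'
#' @param a,b Same-geometry matrices.
#' @param window Gaussian window width (odd; default 7).
#' @param sigma Gaussian sigma.
#' @param data_range Dynamic range of the values.
#' @export
ssim <- function(a, b, window = 7L, sigma = 1.5, data_range = 4) {
  stopifnot(all(dim(a) == dim(b)))
  sm <- function(x) smooth_gaussian2d(x, sigma, trunc = (window - 1) / 2 / sigma)
  mu_a <- sm(a); mu_b <- sm(b)
  va <- sm(a * a) - mu_a^2
  vb <- sm(b * b) - mu_b^2
  cab <- sm(a * b) - mu_a * mu_b
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s, na.rm = TRUE)
}

#' Insulation profile of a contact map
#'
#' Slides a diamond-shaped window along the diagonal: score(i) is the mean
#' of the block map[i-d..i-1, i+1..i+d]. Bins at the ends of the diagonal
#' (where the full diamond does not fit) are NA.
#'
#' @param map Square matrix.
#' @param diamond Half-width d in bins (default 10).
#' @return Numeric vector of length nrow(map).
#' @export
insulation_profile <- function(map, diamond = 10L) {
  n <- nrow(map)
  if (diamond < 1) stop("diamond must be >= 1")
  if (diamond > (n - 1) %/% 2) stop("diamond larger than half the map")
  out <- rep(NA_real_, n)
  for (i in (diamond + 1):(n - diamond)) {
    out[i] <- mean(map[(i - diamond):(i - 1), (i + 1):(i + diamond)],
                   na.rm = TRUE)
  }
  out
}

#' Correlation of insulation tracks between observed and predicted maps
#'
#' @param observed,predicted Lists of same-geometry maps.
#' @param diamond Diamond half-width.
#' @return Numeric vector: per-window Pearson correlation over jointly
#'   defined positions.
#' @export
insulation_correlation <- function(observed, predicted, diamond = 10L) {
  mapply(function(o, p) {
    po <- insulation_profile(o, diamond)
    pp <- insulation_profile(p, diamond)
    ok <- is.finite(po) & is.finite(pp)
    if (sum(ok) < 3 || sd(po[ok]) == 0 || sd(pp[ok]) == 0) return(NA_real_)
    cor(po[ok], pp[ok])
  }, observed, predicted)
}

#' Boundary strength from an insulation profile
#'
#' Depth of the insulation minimum at `i` relative to the mean of the
#' flanking profile (positions i +/- (d+1 .. 2d)); larger = stronger
#' insulation.
#'
#' @param profile Insulation profile.
#' @param i Boundary bin (1-based).
#' @param flank Flank width in bins.
#' @export
boundary_strength <- function(profile, i, flank = 5L) {
  n <- length(profile)
  fl <- c((i - 2 * flank):(i - flank - 1), (i + flank + 1):(i + 2 * flank))
  fl <- fl[fl >= 1 & fl <= n]
  mean(profile[fl], na.rm = TRUE) - profile[i]
}

#' Classify TAD boundaries by strength and cell-type sharing
#'
#' Strength classes: weak (0.2 < s <= 0.5), strong (s > 0.5). Boundaries
#' within 20 Kb of a boundary in the other cell type (mutual nearest
#' neighbor) are shared, otherwise unique. Shared boundaries are subdivided
#' by log2(strengthB/strengthA): stable (|lfc| <= 1), higher_in_A
#' (lfc < -1), higher_in_B (lfc > 1).
#'
#' @param callsA,callsB data.frames (chrom, pos, strength).
#' @param max_dist Sharing distance limit in bp (default 20000).
#' @param weak_range,strong_min Strength thresholds.
#' @param lfc_thr log2 fold-change threshold.
#' @return `callsA` augmented with strength_class, sharing, partner
#'   (row of B), lfc, shared_subclass.
#' @export
classify_boundaries <- function(callsA, callsB, max_dist = 20000,
                                weak_range = c(0.2, 0.5), strong_min = 0.5,
                                lfc_thr = 1) {
  cls <- function(s) ifelse(s > strong_min, "strong",
                            ifelse(s > weak_range[1], "weak", "below"))
  m <- mutual_nearest(callsA, callsB, max_dist)
  lfc <- rep(NA_real_, nrow(callsA))
  has <- !is.na(m)
  lfc[has] <- log2(callsB$strength[m[has]] / callsA$strength[has])
  sub <- rep(NA_character_, nrow(callsA))
  sub[has] <- ifelse(abs(lfc[has]) <= lfc_thr, "stable",
                     ifelse(lfc[has] < -lfc_thr, "higher_in_A",
                            "higher_in_B"))
  data.frame(callsA, strength_class = cls(callsA$strength),
             sharing = ifelse(has, "shared", "unique"), partner = m,
             lfc = lfc, shared_subclass = sub, stringsAsFactors = FALSE)
}

# Mutual nearest neighbor matching within max_dist, per chromosome.
mutual_nearest <- function(a, b, max_dist) {
  m <- rep(NA_integer_, nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    if (!length(ia) || !length(ib)) next
    near_ab <- vapply(a$pos[ia], function(p) ib[which.min(abs(b$pos[ib] - p))],
                      integer(1))
    near_ba <- vapply(b$pos[ib], function(p) ia[which.min(abs(a$pos[ia] - p))],
                      integer(1))
    for (k in seq_along(ia)) {
      j <- near_ab[k]
      if (abs(b$pos[j] - a$pos[ia[k]]) <= max_dist &&
          near_ba[match(j, ib)] == ia[k]) m[ia[k]] <- j
    }
  }
  m
}

#' Classify loop anchors as shared or cell-type unique
#'
#' Mutual-nearest-neighbor matching with the same 20 Kb distance limit used
#' for boundaries.
#'
#' @param anchorsA,anchorsB data.frames (chrom, pos).
#' @param max_dist Distance limit in bp.
#' @return `anchorsA` with `sharing` and `partner` columns.
#' @export
classify_loop_anchors <- function(anchorsA, anchorsB, max_dist = 20000) {
  m <- mutual_nearest(anchorsA, anchorsB, max_dist)
  data.frame(anchorsA, sharing = ifelse(is.na(m), "unique", "shared"),
             partner = m, stringsAsFactors = FALSE)
}

#' Select cell-type-specific window subsets
#'
#' Given per-window comparison scores between two cell types' experimental
#' maps, subset 1 holds windows with MSE > mse_thr, and subset 2 adds
#' windows with SCC < scc_thr or SSIM < ssim_thr (so subset 1 is always
#' contained in subset 2). An optional compartment-transition filter keeps
#' only windows whose majority compartment label changes in the stated
#' direction.
#'
#' @param scores data.frame with columns mse, scc, ssim (one row per
#'   window).
#' @param mse_thr,scc_thr,ssim_thr Thresholds (defaults 0.3, 0.2, 0.08).
#' @param transition NULL, "A->B" or "B->A".
#' @param comp_a,comp_b Per-window compartment labels for cell types A and B
#'   (required with a transition filter).
#' @return List `subset1`, `subset2` of window row indices.
#' @export
select_celltype_specific <- function(scores, mse_thr = 0.3, scc_thr = 0.2,
                                     ssim_thr = 0.08, transition = NULL,
                                     comp_a = NULL, comp_b = NULL) {
  s1 <- which(scores$mse > mse_thr)
  s2 <- sort(union(s1, which((!is.na(scores$scc) & scores$scc < scc_thr) |
                               (!is.na(scores$ssim) & scores$ssim < ssim_thr))))
  if (!is.null(transition)) {
    if (is.null(comp_a) || is.null(comp_b))
      stop("compartment labels required with a transition filter")
    keep <- switch(transition,
                   "A->B" = comp_a == "A" & comp_b == "B",
                   "B->A" = comp_a == "B" & comp_b == "A",
                   stop("unknown transition: ", transition))
    s1 <- intersect(s1, which(keep)); s2 <- intersect(s2, which(keep))
  }
  list(subset1 = s1, subset2 = s2)
}

#' Majority compartment label of each window
#'
#' @param windows data.frame(chrom, start, end).
#' @param compartments GRanges with `name` in {A, B} (as imported from a
#'   compartment BED).
#' @return Character vector of labels, NA where no overlap.
#' @export
window_compartments <- function(windows, compartments) {
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L,
                                               windows$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(w, compartments))
  out <- rep(NA_character_, nrow(windows))
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(w[qh]),
    IRanges::ranges(compartments[S4Vectors::subjectHits(hits)])))
  lab <- as.character(S4Vectors::mcols(compartments)$name[
    S4Vectors::subjectHits(hits)])
  for (q in unique(qh)) {
    k <- qh == q
    tb <- tapply(ov[k], lab[k], sum)
    out[q] <- names(tb)[which.max(tb)]
  }
  out
}
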