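#' Expected-gradients attribution against a background set
#'
#' For a scalar-valued differentiable function f of a feature matrix,
#' attributes f(x) - mean_b f(b) to the entries of x by integrated
#' gradients averaged over the background examples (the completeness
#' property holds up to integration error, exactly for linear f).
#'
#' @param fgrad Function(x) returning `list(value, grad)` with `grad` the
#'   same shape as x.
#' @param x Feature matrix to attribute.
#' @param backgrounds List of background feature matrices (non-empty).
#' @param steps Integration steps along each background path.
#' @return Matrix of scores, same shape as x, with attribute `completeness`
#'   = c(sum_scores, delta_f).
#' @export
expected_gradients <- function(fgrad, x, backgrounds, steps = 8L) {
  if (!length(backgrounds)) stop("background set is empty")
  total <- matrix(0, nrow(x), ncol(x))
  f_b <- numeric(length(backgrounds))
  for (bi in seq_along(backgrounds)) {
    b <- backgrounds[[bi]]
    d <- x - b
    acc <- matrix(0, nrow(x), ncol(x))
    for (s in seq_len(steps)) {
      alpha <- (s - 0.5) / steps       # midpoint rule
      g <- fgrad(b + alpha * d)$grad
      acc <- acc + g
    }
    total <- total + d * acc / steps
    f_b[bi] <- fgrad(b)$value
  }
  scores <- total / length(backgrounds)
  attr(scores, "completeness") <- c(sum_scores = sum(scores),
                                    delta_f = fgrad(x)$value - mean(f_b))
  scores
}

#' Background example scheme for attribution
#'
#' Validation and test windows use 20 windows sampled from the training
#' split; training windows are split in two halves, each half using random
#' examples from the other half as background. Seeded and deterministic.
#'
#' @param split_labels Character vector of window split labels
#'   (train/valid/test).
#' @param n Background set size (default 20, capped at the available pool).
#' @param seed RNG seed.
#' @return List with one integer vector of background window indices per
#'   window.
#' @export
background_scheme <- function(split_labels, n = 20L, seed = 1L) {
  train_idx <- which(split_labels == "train")
  with_seed(seed, {
    half1 <- sort(sample(train_idx, length(train_idx) %/% 2))
    half2 <- setdiff(train_idx, half1)
    lapply(seq_along(split_labels), function(i) {
      pool <- if (split_labels[i] %in% c("valid", "test")) train_idx
      else if (i %in% half1) half2 else half1
      sort(sample(pool, min(n, length(pool))))
    })
  })
}

#' Contribution scores of feature channels for a trained model
#'
#' Expected-gradients attribution of the model's mean predicted contact
#' value with respect to every feature bin, per window, against the
#' background scheme. Raw scores are then normalized per feature channel by
#' the maximum absolute value across the evaluated windows (sign
#' preserved, values in [-1, 1]).
#'
#' @param model Trained `carna_model` with feature channels.
#' @param data List of windows (`onehot`, `features`).
#' @param split_labels Split label per window.
#' @param n_background,seed,steps Background/integration controls.
#' @param normalize "split" (per feature over all windows, default) or
#'   "window".
#' @return List with `raw` and `normalized` (lists of n_bins x n_features
#'   matrices) and `input` (the feature matrices).
#' @export
contribution_scores <- function(model, data, split_labels,
                                n_background = 20L, seed = 1L, steps = 8L,
                                normalize = "split") {
  if (model$cfg$n_features == 0) stop("model has no feature channels")
  bg <- background_scheme(split_labels, n_background, seed)
  raw <- vector("list", length(data))
  for (i in seq_along(data)) {
    w <- data[[i]]
    fg <- function(f) model_feature_grad(model, w$onehot, f)
    raw[[i]] <- expected_gradients(fg, w$features,
                                   lapply(bg[[i]], function(j)
                                     data[[j]]$features), steps = steps)
  }
  norm <- normalize_scores(raw, scope = normalize)
  list(raw = raw, normalized = norm,
       input = lapply(data, function(w) w$features))
}

#' Normalize contribution scores per feature
#'
#' Divides each feature channel by its maximum absolute raw score over the
#' whole evaluated split ("split" scope) or within each window ("window").
#'
#' @param raw List of score matrices (windows x (bins x features)).
#' @param scope "split" or "window".
#' @export
normalize_scores <- function(raw, scope = "split") {
  if (scope == "window") {
    return(lapply(raw, function(m) {
      mx <- apply(abs(m), 2, max)
      sweep(m, 2, pmax(mx, .Machine$double.eps), "/")
    }))
  }
  mx <- Reduce(pmax, lapply(raw, function(m) apply(abs(m), 2, max)))
  lapply(raw, function(m) sweep(m, 2, pmax(mx, .Machine$double.eps), "/"))
}

#' Bins with extreme contribution scores
#'
#' Top (positive) or bottom (negative) `pct` percent of bins for a feature,
#' restricted to bins with positive input values. Ties are broken by
#' genomic (bin) order.
#'
#' @param scores Numeric vector of per-bin normalized scores (whole split,
#'   concatenated in genomic order).
#' @param input Per-bin input values, same length.
#' @param pct Percentile (1 or 5).
#' @param tail "top" or "bottom".
#' @return Integer vector of selected bin indices (into `scores`).
#' @export
extreme_regions <- function(scores, input, pct = 5, tail = "top") {
  eligible <- which(input > 0)
  if (!length(eligible)) return(integer(0))
  k <- ceiling(pct / 100 * length(eligible))
  s <- scores[eligible]
  ord <- if (tail == "top") order(-s, eligible) else order(s, eligible)
  sort(eligible[ord[seq_len(k)]])
}

#' Annotation enrichment of a region set
#'
#' log2(observed/expected) where observed is the fraction of region bins
#' overlapping the annotation and expected the fraction of eligible bins
#' doing so. Annotations with zero expected coverage are NA.
#'
#' @param region_bins Integer indices of the selected bins.
#' @param eligible_bins Indices of all eligible bins (the universe).
#' @param annotations Named list of logical vectors (per-bin annotation
#'   membership over the whole grid) or of integer bin-index vectors.
#' @return Named numeric vector of log2 enrichments.
#' @export
enrichment <- function(region_bins, eligible_bins, annotations) {
  vapply(annotations, function(a) {
    inset <- if (is.logical(a)) function(i) a[i] else function(i) i %in% a
    exp_f <- mean(inset(eligible_bins))
    if (is.na(exp_f) || exp_f == 0) return(NA_real_)
    obs_f <- mean(inset(region_bins))
    log2(obs_f / exp_f)
  }, numeric(1))
}

#' Bins where caRNA contribution exceeds accessibility contribution
#'
#' A bin passes when |normalized caRNA score| / |normalized ATAC score|
#' exceeds `fold_thr` (ratio is +Inf at zero ATAC score) and the caRNA score
#' magnitude exceeds `score_thr`.
#'
#' @param rna_scores,atac_scores Per-bin normalized scores.
#' @param fold_thr,score_thr Thresholds (defaults 5 and 0.25).
#' @return data.frame(bin, rna_score, atac_score, fold_change, passes).
#' @export
differential_regions <- function(rna_scores, atac_scores, fold_thr = 5,
                                 score_thr = 0.25) {
  fc <- ifelse(abs(atac_scores) == 0, Inf,
               abs(rna_scores) / abs(atac_scores))
  data.frame(bin = seq_along(rna_scores), rna_score = rna_scores,
             atac_score = atac_scores, fold_change = fc,
             passes = fc > fold_thr & abs(rna_scores) > score_thr)
}

#' High-confidence RNA-DNA interactions by hypergeometric test
#'
#' For gene g and DNA bin b with k joint contacts, tests P[X >= k] with
#' X ~ Hypergeometric(N = total contacts, K = contacts of g, n = contacts
#' at b), assuming each DNA bin is equally likely to interact with any RNA.
#' Benjamini-Hochberg correction is applied across all tested (g, b) pairs
#' (those with k >= 1); pairs with q <= alpha are retained.
#'
#' @param counts data.frame(gene, bin, count) of aggregated contacts.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame(gene, bin, count, K, n, p, q, retained).
#' @export
hypergeom_interactions <- function(counts, alpha = 0.05) {
  counts <- counts[counts$count >= 1, , drop = FALSE]
  N <- sum(counts$count)
  Kg <- tapply(counts$count, counts$gene, sum)
  nb <- tapply(counts$count, counts$bin, sum)
  K <- as.numeric(Kg[as.character(counts$gene)])
  n <- as.numeric(nb[as.character(counts$bin)])
  if (any(counts$count > pmin(K, n)))
    stop("impossible input: count exceeds min(gene total, bin total)")
  p <- phyper(counts$count - 1, K, N - K, n, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  data.frame(gene = counts$gene, bin = counts$bin, count = counts$count,
             K = K, n = n, p = p, q = q, retained = q <= alpha,
             stringsAsFactors = FALSE)
}

#' Rank candidate RNAs by association with extreme-score regions
#'
#' For each gene with high-confidence interactions, counts how many land in
#' the extreme-score bins and the ratio of such interactions; genes are
#' ranked by count, ties by ratio. Genes without high-confidence
#' interactions are excluded.
#'
#' @param highconf [hypergeom_interactions()] output (retained rows used).
#' @param extreme_bins Integer vector of extreme-score bin indices.
#' @return data.frame(gene, n_extreme, n_total, ratio, rank).
#' @export
rank_candidate_rnas <- function(highconf, extreme_bins) {
  hc <- highconf[highconf$retained, , drop = FALSE]
  if (!nrow(hc)) return(data.frame(gene = character(0),
                                   n_extreme = integer(0),
                                   n_total = integer(0), ratio = numeric(0),
                                   rank = integer(0)))
  sp <- split(hc, hc$gene)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    d <- sp[[g]]
    ne <- sum(d$bin %in% extreme_bins)
    data.frame(gene = g, n_extreme = ne, n_total = nrow(d),
               ratio = ne / nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_extreme, -out$ratio, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
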