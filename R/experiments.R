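#' Simulate a desk-scale study dataset
#'
#' Builds a synthetic genome in which every chromosome is one model window,
#' plants TAD boundaries, samples DNA-DNA contacts, runs the full
#' map-preparation recipe, and (for the feature-coupled mode) plants a
#' trans-located caRNA channel whose amplitude at each boundary tracks the
#' boundary's insulation strength.
#'
#' Modes:
#' \describe{
#'   \item{sequence}{Boundary strength is `motif_beta * k` where k in
#'     `motif_counts` convergent CTCF motif copies are written into the
#'     sequence at the boundary — contact structure is predictable from
#'     sequence alone.}
#'   \item{feature}{Boundaries carry no sequence signal; strength is drawn
#'     from `strength_range` and a trans-located lncRNA (transcribed from a
#'     dedicated source chromosome) deposits ~`carna_amp * exp(strength)`
#'     reads at each boundary bin — contact structure is predictable only
#'     from the caRNA channel.}
#' }
#'
#' @param mode "sequence" or "feature".
#' @param n_windows Number of model windows (= chromosomes).
#' @param window_bp Window length (power of two, multiple of 2048).
#' @param depth_per_window DNA-DNA read pairs per window.
#' @param n_boundaries Boundaries per window (sampled from this set).
#' @param motif_counts Candidate motif copy numbers (sequence mode).
#' @param motif_beta Insulation strength per motif copy.
#' @param strength_range Boundary strength range (feature mode).
#' @param carna_amp Baseline caRNA reads per unit exp(strength).
#' @param background_reads Untargeted trans reads from the source gene.
#' @param seed RNG seed.
#' @return List: `data` (windows ready for training: onehot, features,
#'   target), `meta` (per-window boundary bins/strengths), `genome`,
#'   `grid`, `windows`, `feature_channels`.
#' @export
sim_study_data <- function(mode = c("sequence", "feature"), n_windows = 20L,
                           window_bp = 2^15, depth_per_window = 3e4,
                           n_boundaries = 1:2, motif_counts = 0:4,
                           motif_beta = 0.6, strength_range = c(0.5, 2.5),
                           carna_amp = 30, background_reads = 2000L,
                           seed = 1L) {
  mode <- match.arg(mode)
  bin <- 2048L
  n_bins <- window_bp %/% bin
  n_chroms <- n_windows + as.integer(mode == "feature")
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chroms))
    chromsizes <- stats::setNames(rep(as.integer(window_bp), n_chroms), chroms)
    bd <- NULL
    meta <- vector("list", n_windows)
    for (i in seq_len(n_windows)) {
      nb <- if (length(n_boundaries) == 1) n_boundaries else
        sample(n_boundaries, 1)
      # boundary bins in the central stretch; multiple boundaries are
      # drawn from disjoint segments so they stay well separated
      cand <- seq(max(4L, n_bins %/% 4L), n_bins - max(4L, n_bins %/% 4L))
      if (nb > 1) {
        seg <- split(cand, cut(seq_along(cand), nb))
        pos_bins <- sort(vapply(seg, function(h)
          h[sample.int(length(h), 1)], numeric(1)))
      } else {
        pos_bins <- sample(cand, nb)
      }
      if (mode == "sequence") {
        k <- sample(motif_counts, length(pos_bins), replace = TRUE)
        s <- motif_beta * k
      } else {
        k <- rep(0L, length(pos_bins))
        s <- runif(length(pos_bins), strength_range[1], strength_range[2])
      }
      bd <- rbind(bd, data.frame(chrom = chroms[i], pos = pos_bins * bin,
                                 strength = s, n_motifs = k))
      meta[[i]] <- data.frame(window = i, chrom = chroms[i],
                              bin = pos_bins + 1L, strength = s,
                              n_motifs = k)
    }
    meta <- do.call(rbind, meta)
    structure_ <- plant_structure(chromsizes, bin, boundaries = bd,
                                  decay_exponent = 1)
    gspec <- synthetic_genome_spec(n_chroms = n_chroms,
                                   chrom_length = window_bp,
                                   seed = sample.int(1e6, 1))
    genome <- make_genome(gspec, structure = structure_)
    dd <- make_dna_dna_pairs(structure_, depth = depth_per_window * n_windows,
                             seed = sample.int(1e6, 1))
    grid <- bin_grid(chromsizes, bin)
    windows <- data.frame(chrom = chroms[seq_len(n_windows)], start = 0L,
                          end = as.integer(window_bp))
    targets <- prepare_target_maps(dd, grid, windows, gaussian_sigma = 1)
    feats <- NULL
    feature_channels <- character(0)
    if (mode == "feature") {
      ids <- S4Vectors::mcols(genome$genes)$gene_id
      types <- S4Vectors::mcols(genome$genes)$gene_type
      src_ch <- chroms[n_chroms]
      on_src <- as.character(GenomicRanges::seqnames(genome$genes)) == src_ch
      src_gene <- ids[on_src & types == "lncRNA"][1]
      targeted <- data.frame(gene = src_gene,
                             dna_chrom = meta$chrom,
                             dna_pos = (meta$bin - 1L) * bin + 1L,
                             reads = round(carna_amp * exp(meta$strength)))
      cspec <- synthetic_contact_spec(
        expression = stats::setNames(background_reads, src_gene),
        cis_fraction = 0, targeted = targeted)
      rd <- make_rna_dna_pairs(cspec, genome, seed = sample.int(1e6, 1))
      contacts <- parse_rna_dna_pairs(list(records = rd$records,
                                           chromsizes = chromsizes))
      tf <- trans_filter(contacts, genome$genes)
      gt <- group_tracks(tf, genome$genes, grid)
      feats <- gt$log
      feature_channels <- colnames(feats)
    }
    data <- lapply(seq_len(n_windows), function(i) {
      oh <- encode_sequence(as.character(genome$seqs[[chroms[i]]]))
      fx <- if (is.null(feats)) NULL else
        window_features(grid, windows[i, ], channels = list(trans = feats),
                        variant = "trans")
      list(onehot = oh, features = fx, target = unclass_map(targets[[i]]),
           chrom = chroms[i])
    })
    list(data = data, meta = meta, genome = genome, grid = grid,
         windows = windows, feature_channels = feature_channels,
         structure = structure_)
  })
}

unclass_map <- function(m) {
  attr(m, "mask") <- NULL; attr(m, "window") <- NULL
  class(m) <- "matrix"
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Overfit a small model on a handful of windows
#'
#' Sanity-scale training run: a sequence-only model fit to `n_windows`
#' synthetic windows, reporting the final training-set Pearson correlation.
#'
#' @param n_windows,window_bp,depth_per_window Dataset size.
#' @param epochs,lr Training controls.
#' @param seed RNG seed.
#' @return List: `train_pearson`, `model`, `study`.
#' @export
run_overfit_experiment <- function(n_windows = 20L, window_bp = 2^17,
                                   depth_per_window = 1e5, epochs = 40L,
                                   lr = 4e-3, seed = 1L) {
  study <- sim_study_data("sequence", n_windows = n_windows,
                          window_bp = window_bp,
                          depth_per_window = depth_per_window,
                          motif_counts = 1:4, seed = seed)
  cfg <- model_config(window_bp = window_bp, seed = seed)
  model <- init_model(cfg)
  model <- train_model(model, study$data, epochs = epochs, lr = lr,
                       augment_rc = FALSE, seed = seed + 1L)
  ev <- evaluate_model(model, study$data)
  list(train_pearson = unname(ev["pearson"]), model = model, study = study)
}

#' Feature model versus sequence-only model, replicated
#'
#' On a feature-coupled dataset (targets depend on a caRNA channel, not on
#' sequence), trains `n_replicates` seeded replicates of the trans-feature
#' model and of the sequence-only model and compares validation Pearson
#' with a one-sided Mann-Whitney test (feature > sequence).
#'
#' @param n_train,n_valid,window_bp,depth_per_window Dataset size.
#' @param n_replicates,epochs,lr Training controls.
#' @param seed RNG seed.
#' @return List: `p_value`, `feature_pearson`, `sequence_pearson`,
#'   `best_feature_model`, `study`, `valid_idx`.
#' @export
run_variant_comparison <- function(n_train = 12L, n_valid = 8L,
                                   window_bp = 2^15,
                                   depth_per_window = 3e4,
                                   n_replicates = 5L, epochs = 30L,
                                   lr = 5e-3, seed = 1L) {
  n_windows <- n_train + n_valid
  study <- sim_study_data("feature", n_windows = n_windows,
                          window_bp = window_bp,
                          depth_per_window = depth_per_window, seed = seed)
  train_idx <- seq_len(n_train)
  valid_idx <- n_train + seq_len(n_valid)
  tr <- study$data[train_idx]; va <- study$data[valid_idx]
  seeds <- seed * 100L + seq_len(n_replicates)
  cfg_f <- model_config(window_bp = window_bp,
                        feature_channels = study$feature_channels,
                        seed = seed)
  rep_f <- train_replicates(cfg_f, tr, va, seeds = seeds, epochs = epochs,
                            lr = lr)
  strip <- function(w) list(onehot = w$onehot, features = NULL,
                            target = w$target)
  cfg_s <- model_config(window_bp = window_bp, seed = seed)
  rep_s <- train_replicates(cfg_s, lapply(tr, strip), lapply(va, strip),
                            seeds = seeds, epochs = epochs, lr = lr)
  fp <- rep_f$summary$valid_pearson
  sp <- rep_s$summary$valid_pearson
  p <- wilcox.test(fp, sp, alternative = "greater", exact = TRUE)$p.value
  list(p_value = p, feature_pearson = fp, sequence_pearson = sp,
       best_feature_model = rep_f$best, best_sequence_model = rep_s$best,
       study = study, valid_idx = valid_idx, train_idx = train_idx)
}

#' CaRNA-elevation response on a trained feature model
#'
#' Selects validation regions with relatively simple structure (at most
#' `max_boundaries` planted boundaries), elevates the lncRNA channel at
#' their boundary bins by the given folds and summarizes the insulation /
#' contact response.
#'
#' @param cmp A [run_variant_comparison()] result.
#' @param folds Raw-scale folds.
#' @param max_boundaries Region simplicity cutoff.
#' @return [elevation_response()] result.
#' @export
run_elevation_experiment <- function(cmp, folds = exp(c(0.5, 1, 1.5, 2)),
                                     max_boundaries = 2L) {
  study <- cmp$study
  idx <- cmp$valid_idx
  nb <- table(factor(study$meta$window, levels = seq_along(study$data)))
  simple <- idx[nb[idx] <= max_boundaries]
  data <- study$data[simple]
  bb <- lapply(simple, function(i)
    study$meta$bin[study$meta$window == i])
  elevation_response(cmp$best_feature_model, data, bb, channel = "lncRNA",
                     folds = folds)
}

#' CTCF-insertion response on a sequence-trained model
#'
#' Trains sequence-only replicates on a sequence-coupled dataset (boundary
#' insulation driven by planted convergent CTCF motif arrays of 0-4
#' copies), selects the replicate whose predicted boundary depth best
#' tracks the planted motif count on held-out windows, then measures the
#' predicted mean-contact response to inserting 1-4 motif copies into
#' fresh random sequences.
#'
#' @param n_windows,window_bp,depth_per_window Dataset size.
#' @param n_replicates,epochs,lr Training controls.
#' @param n_sequences Random sequences for the response curve.
#' @param seed RNG seed.
#' @return List: `response` ([ctcf_response()] result), `model`,
#'   `valid_pearson`, `tracking` (per-replicate selection scores).
#' @export
run_ctcf_experiment <- function(n_windows = 60L, window_bp = 2^15,
                                depth_per_window = 3e4, n_replicates = 2L,
                                epochs = 60L, lr = 4e-3, n_sequences = 100L,
                                seed = 1L) {
  study <- sim_study_data("sequence", n_windows = n_windows,
                          window_bp = window_bp,
                          depth_per_window = depth_per_window,
                          motif_counts = 0:4, motif_beta = 0.7, seed = seed)
  n_valid <- max(4L, n_windows %/% 5L)
  tr_idx <- seq_len(n_windows - n_valid)
  va_idx <- setdiff(seq_len(n_windows), tr_idx)
  # wide first-layer kernel: one filter can span the full 19-bp consensus
  models <- lapply(seq_len(n_replicates), function(r) {
    cfg <- model_config(window_bp = window_bp, trunk_kernel = 19L,
                        trunk_channels = 12L,
                        seed = seed * 10L + r)
    train_model(init_model(cfg), study$data[tr_idx],
                valid = study$data[va_idx], epochs = epochs, lr = lr,
                weight_decay = 1e-4, seed = seed * 10L + r + 500L)
  })
  tracking <- vapply(models, function(m)
    boundary_tracking(m, study, va_idx), numeric(1))
  best <- which.max(ifelse(is.na(tracking), -Inf, tracking))
  model <- models[[best]]
  resp <- ctcf_response(model, n_sequences = n_sequences, seed = seed + 2L)
  list(response = resp, model = model,
       valid_pearson = model$valid_pearson, tracking = tracking,
       study = study)
}

# How well a sequence model's predicted boundary depth tracks the planted
# boundary strength on the given windows (Spearman, pooled).
boundary_tracking <- function(model, study, idx, diamond = NULL) {
  n_bins <- model$cfg$n_bins
  if (is.null(diamond)) diamond <- max(2L, n_bins %/% 16L)
  planted <- pred <- numeric(0)
  for (i in idx) {
    w <- study$data[[i]]
    prof <- insulation_profile(forward_map(model, w$onehot), diamond)
    mm <- study$meta[study$meta$window == i, ]
    for (j in seq_len(nrow(mm))) {
      b <- mm$bin[j]
      if (b > 2L * diamond && b <= n_bins - 2L * diamond) {
        planted <- c(planted, mm$strength[j])
        pred <- c(pred, boundary_strength(prof, b, diamond))
      }
    }
  }
  if (length(planted) < 3 || sd(pred) == 0 || sd(planted) == 0)
    return(NA_real_)
  cor(planted, pred, method = "spearman")
}

#' Recovery of the planted trans-located fraction
#'
#' Generates RNA-DNA pairs with a known cis fraction, runs the MAPQ and
#' distance filters, and compares the recovered trans fraction with the
#' planted one.
#'
#' @param n_reads Total reads.
#' @param cis_fraction Planted cis fraction (trans = 1 - cis).
#' @param seed RNG seed.
#' @return List: `planted_trans`, `recovered_trans`, `n_retained`,
#'   `binomial_se`.
#' @export
run_trans_recovery <- function(n_reads = 1e5, cis_fraction = 0.6, seed = 1L) {
  gspec <- synthetic_genome_spec(n_chroms = 4L, chrom_length = 2^21,
                                 seed = seed)
  genome <- make_genome(gspec)
  ids <- S4Vectors::mcols(genome$genes)$gene_id
  types <- S4Vectors::mcols(genome$genes)$gene_type
  src <- ids[types == "lncRNA"]
  expr <- stats::setNames(rep(round(n_reads / length(src)), length(src)), src)
  cspec <- synthetic_contact_spec(expression = expr,
                                  cis_fraction = cis_fraction)
  rd <- make_rna_dna_pairs(cspec, genome, seed = seed + 1L)
  contacts <- parse_rna_dna_pairs(list(records = rd$records,
                                       chromsizes = genome$chromsizes))
  tf <- trans_filter(contacts, genome$genes)
  recovered <- nrow(tf$records) / nrow(contacts$records)
  planted <- 1 - cis_fraction
  list(planted_trans = planted, recovered_trans = recovered,
       n_retained = nrow(contacts$records),
       binomial_se = sqrt(planted * (1 - planted) / nrow(contacts$records)))
}
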