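#' Insert a convergent CTCF motif array into a sequence
#'
#' Replaces bases in place (sequence length unchanged): k forward motifs
#' upstream and k reverse-complement motifs downstream of the locus, at
#' exact `spacing`, forming a convergent pair symmetric about the boundary.
#'
#' @param seq Character scalar DNA sequence.
#' @param k Number of motif copies per side (0..4; 0 returns the input).
#' @param locus 0-based boundary position; when NULL a locus is drawn
#'   uniformly in the `locus_range` fraction of the sequence (resampled, with
#'   a message, if the array would run off the ends).
#' @param spacing Distance between consecutive motifs, bp.
#' @param locus_range Fraction range for random locus placement.
#' @param seed RNG seed for locus sampling.
#' @return List: `seq` (perturbed), `locus`, `coords` (data.frame start,
#'   end, strand per inserted copy; 1-based closed).
#' @export
insert_ctcf <- function(seq, k, locus = NULL, spacing = 500L,
                        locus_range = c(0.15, 0.85), seed = NULL) {
  L <- nchar(seq)
  stopifnot(k >= 0, k <= 4)
  w <- nchar(CTCF_CONSENSUS)
  margin <- k * spacing + w
  pick <- function() floor(runif(1, locus_range[1] * L, locus_range[2] * L))
  sample_locus <- function() {
    for (t in 1:100) {
      p <- pick()
      if (p - margin >= 0 && p + margin <= L) return(p)
      message("locus too close to edge; resampling")
    }
    stop("cannot place motif array inside the sequence")
  }
  run <- function() {
    if (is.null(locus)) locus <- sample_locus()
    if (locus - margin < 0 || locus + margin > L)
      stop("locus too close to the sequence edge for k*spacing")
    if (k == 0) return(list(seq = seq, locus = locus,
                            coords = data.frame(start = integer(0),
                                                end = integer(0),
                                                strand = character(0))))
    bases <- strsplit(seq, "")[[1]]
    bases <- write_ctcf_array(bases, locus, k, spacing)
    coords <- do.call(rbind, lapply(seq_len(k), function(i) {
      rbind(data.frame(start = locus - i * spacing + 1L,
                       end = locus - i * spacing + w, strand = "+"),
            data.frame(start = locus + i * spacing + 1L,
                       end = locus + i * spacing + w, strand = "-"))
    }))
    list(seq = paste(bases, collapse = ""), locus = locus, coords = coords)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Contact response to progressive CTCF motif insertion
#'
#' Generates random DNA sequences, inserts 1..4 convergent CTCF motif
#' copies at a random locus of each, predicts the contact map with a
#' sequence-only model, and summarizes the mean contact value and the
#' insulation strength at the perturbed locus per motif count. Consecutive
#' motif counts are compared with two-sided Mann-Whitney tests.
#'
#' @param model Trained sequence-only `carna_model`.
#' @param n_sequences Number of random sequences.
#' @param k_values Motif counts (default 1:4).
#' @param gc GC content of the random background.
#' @param diamond Insulation diamond half-width (bins).
#' @param seed RNG seed.
#' @return List: `curve` (data.frame k, mean_contact, insulation_strength,
#'   se per k), `tests` (Mann-Whitney p between consecutive k),
#'   `per_sequence` (long data.frame).
#' @export
ctcf_response <- function(model, n_sequences = 50L, k_values = 1:4,
                          gc = 0.42, diamond = NULL, seed = 1L) {
  cfg <- model$cfg
  if (cfg$n_features != 0) stop("ctcf_response requires a sequence-only model")
  if (is.null(diamond)) diamond <- max(2L, cfg$n_bins %/% 16L)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_sequences)) {
      base_seq <- paste(random_base(cfg$window_bp, gc), collapse = "")
      locus <- floor(runif(1, 0.15 * cfg$window_bp, 0.85 * cfg$window_bp))
      bbin <- locus %/% cfg$bin_bp + 1L
      bbin <- clip(bbin, 2L * diamond + 1L, cfg$n_bins - 2L * diamond)
      for (k in k_values) {
        pert <- insert_ctcf(base_seq, k, locus = locus)
        map <- forward_map(model, encode_sequence(pert$seq))
        prof <- insulation_profile(map, diamond)
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = s, k = k,
          mean_contact = mean_contact(map, cfg$diag_offset),
          insulation_strength = boundary_strength(prof, bbin, diamond))
      }
    }
    per_seq <- do.call(rbind, rows)
    curve <- do.call(rbind, lapply(k_values, function(k) {
      d <- per_seq[per_seq$k == k, ]
      data.frame(k = k, mean_contact = mean(d$mean_contact),
                 insulation_strength = mean(d$insulation_strength),
                 se_contact = sd(d$mean_contact) / sqrt(nrow(d)))
    }))
    tests <- do.call(rbind, lapply(seq_len(length(k_values) - 1), function(i) {
      a <- per_seq$mean_contact[per_seq$k == k_values[i]]
      b <- per_seq$mean_contact[per_seq$k == k_values[i + 1]]
      data.frame(k_from = k_values[i], k_to = k_values[i + 1],
                 p = wilcox.test(a, b, exact = FALSE)$p.value)
    }))
    list(curve = curve, tests = tests, per_sequence = per_seq)
  })
}

#' Elevate a caRNA feature channel at selected bins
#'
#' Multiplies the raw-scale signal (the features are log1p-transformed) at
#' the given bins by `fold` for one channel, re-applies the log transform,
#' and leaves every other channel untouched.
#'
#' @param features n_bins x n_channels log-scale feature matrix.
#' @param channel Channel name or index.
#' @param bins Bin indices to elevate.
#' @param fold Raw-scale multiplicative fold (e.g. exp(0.5) .. exp(2)).
#' @export
elevate_carna <- function(features, channel, bins, fold) {
  if (is.character(channel)) {
    ci <- match(channel, colnames(features))
    if (is.na(ci)) stop("unknown channel: ", channel)
  } else ci <- channel
  out <- features
  out[bins, ci] <- log1p(expm1(features[bins, ci]) * fold)
  out
}

#' Insulation and contact response to caRNA elevation
#'
#' For each region (window) and fold, elevates the chosen channel at the
#' region's selected boundary bins, re-predicts the map and records the
#' change in insulation strength at those boundaries and in mean contact
#' value relative to the unperturbed prediction.
#'
#' @param model Trained feature-bearing model.
#' @param data List of windows (`onehot`, `features`).
#' @param boundary_bins List (per window) of boundary bin indices (1-2
#'   each).
#' @param channel Feature channel to elevate.
#' @param folds Raw-scale folds (default exp(c(0.5, 1, 1.5, 2))).
#' @param diamond Insulation diamond half-width.
#' @return List: `curve` (per fold: mean delta insulation strength, mean
#'   delta contact), `per_region`.
#' @export
elevation_response <- function(model, data, boundary_bins, channel,
                               folds = exp(c(0.5, 1, 1.5, 2)),
                               diamond = NULL) {
  cfg <- model$cfg
  if (is.null(diamond)) diamond <- max(2L, cfg$n_bins %/% 16L)
  rows <- list()
  for (i in seq_along(data)) {
    w <- data[[i]]
    bb <- boundary_bins[[i]]
    bb <- bb[bb > 2 * diamond & bb <= cfg$n_bins - 2 * diamond]
    if (!length(bb)) next
    map0 <- forward_map(model, w$onehot, w$features)
    prof0 <- insulation_profile(map0, diamond)
    s0 <- mean(vapply(bb, function(b) boundary_strength(prof0, b, diamond),
                      numeric(1)))
    c0 <- mean_contact(map0, cfg$diag_offset)
    for (f in folds) {
      feat <- elevate_carna(w$features, channel, bb, f)
      map <- forward_map(model, w$onehot, feat)
      prof <- insulation_profile(map, diamond)
      s1 <- mean(vapply(bb, function(b) boundary_strength(prof, b, diamond),
                        numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        region = i, fold = f,
        d_insulation = s1 - s0,
        d_contact = mean_contact(map, cfg$diag_offset) - c0)
    }
  }
  per_region <- do.call(rbind, rows)
  curve <- do.call(rbind, lapply(sort(unique(per_region$fold)), function(f) {
    d <- per_region[per_region$fold == f, ]
    data.frame(fold = f, d_insulation = mean(d$d_insulation),
               d_contact = mean(d$d_contact))
  }))
  list(curve = curve, per_region = per_region)
}

#' Scan an RNA-DNA sequence pair for R-loop-forming potential
#'
#' Best gapped local alignment of the RNA sequence against the DNA sequence
#' (both strands); identity is matched bases over the RNA sequence length
#' and `max_run` the longest contiguous perfect match in the alignment. A
#' pair is a candidate when identity > 0.80 and max_run > 10 bp.
#'
#' @param rna_seq,dna_seq Character sequences (ACGTN).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @param id_thr,run_thr Candidate thresholds.
#' @return List: `identity`, `max_run`, `is_candidate`, `strand`, `score`,
#'   `alignment` (PairwiseAlignments object).
#' @export
rloop_scan <- function(rna_seq, dna_seq, match = 2, mismatch = -1,
                       gap_open = 2, gap_extend = 0.5, id_thr = 0.80,
                       run_thr = 10L) {
  if (!nchar(rna_seq) || !nchar(dna_seq)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  scan1 <- function(dna) {
    aln <- Biostrings::pairwiseAlignment(rna_seq, dna, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = gap_open,
                                         gapExtension = gap_extend)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    is_match <- pa == sa & pa != "-"
    list(aln = aln, identity = sum(is_match) / nchar(rna_seq),
         max_run = longest_run(is_match), score = Biostrings::score(aln))
  }
  fwd <- scan1(dna_seq)
  rev <- scan1(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(dna_seq))))
  best <- if (rev$identity > fwd$identity ||
              (rev$identity == fwd$identity && rev$score > fwd$score)) {
    c(rev, strand = "-")
  } else c(fwd, strand = "+")
  list(identity = best$identity, max_run = best$max_run,
       is_candidate = best$identity > id_thr & best$max_run > run_thr,
       strand = best$strand, score = best$score, alignment = best$aln)
}

#' Fraction of landmarks with R-loop candidate interactions
#'
#' For each landmark class (e.g. boundary strength/sharing classes), the
#' fraction of landmarks having at least one candidate DNA end within the
#' landmark resolution (default 5000 bp).
#'
#' @param candidates data.frame(dna_chrom, dna_pos) of candidate
#'   interactions.
#' @param landmarks data.frame(chrom, pos, class).
#' @param resolution Overlap half-window in bp.
#' @return data.frame(class, n, n_with_candidate, fraction).
#' @export
rloop_landmark_fractions <- function(candidates, landmarks,
                                     resolution = 5000L) {
  has <- vapply(seq_len(nrow(landmarks)), function(i) {
    any(candidates$dna_chrom == landmarks$chrom[i] &
          abs(candidates$dna_pos - landmarks$pos[i]) <= resolution)
  }, logical(1))
  cls <- unique(landmarks$class)
  do.call(rbind, lapply(cls, function(cl) {
    k <- landmarks$class == cl
    data.frame(class = cl, n = sum(k), n_with_candidate = sum(has[k]),
               fraction = mean(has[k]), stringsAsFactors = FALSE)
  }))
}
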