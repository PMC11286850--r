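#' Parse RNA-DNA contact pairs (iMARGI-style)
#'
#' Reads a 4DN .pairs file whose side 1 is the RNA end and side 2 the DNA
#' end, and drops low-quality mappings (MAPQ <= 30, i.e. only MAPQ > 30 is
#' retained). Provenance counters record parsed/dropped record numbers.
#'
#' @param path .pairs file path, or a [read_pairs()] result.
#' @param mapq_max Records with MAPQ <= this value are dropped (default 30).
#' @return An `rna_dna_contacts` list: `records` (rna_chrom, rna_pos,
#'   rna_strand, dna_chrom, dna_pos, dna_strand, mapq), `counters`,
#'   `chromsizes`.
#' @export
parse_rna_dna_pairs <- function(path, mapq_max = 30L) {
  p <- if (is.character(path)) read_pairs(path) else path
  rec <- p$records
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(rec))) stop("missing required .pairs columns")
  if (!"mapq" %in% names(rec)) stop("missing mapq column")
  parsed <- nrow(rec)
  ok_form <- !is.na(rec$pos1) & !is.na(rec$pos2) & rec$pos1 >= 1 & rec$pos2 >= 1
  rec <- rec[ok_form, , drop = FALSE]
  keep <- rec$mapq > mapq_max
  out <- data.frame(rna_chrom = rec$chrom1[keep], rna_pos = rec$pos1[keep],
                    rna_strand = (rec$strand1 %||% rep("+", nrow(rec)))[keep],
                    dna_chrom = rec$chrom2[keep], dna_pos = rec$pos2[keep],
                    dna_strand = (rec$strand2 %||% rep("+", nrow(rec)))[keep],
                    mapq = rec$mapq[keep], stringsAsFactors = FALSE)
  structure(list(records = out,
                 counters = c(parsed = parsed,
                              dropped_malformed = sum(!ok_form),
                              dropped_mapq = sum(!keep),
                              retained = sum(keep)),
                 chromsizes = p$chromsizes),
            class = "rna_dna_contacts")
}

#' Nascent transcription track
#'
#' Number of retained reads whose RNA end maps to each bin, at 10, 2048 or
#' 5000 bp resolution.
#'
#' @param contacts An `rna_dna_contacts` object.
#' @param chromsizes Named chromosome lengths.
#' @param resolution Bin width in bp.
#' @return data.frame(chrom, start, count), complete over the genome,
#'   0-based half-open starts.
#' @export
nascent_track <- function(contacts, chromsizes, resolution = 2048L) {
  rec <- contacts$records
  out <- do.call(rbind, lapply(names(chromsizes), function(ch) {
    n <- ceiling(chromsizes[[ch]] / resolution)
    cnt <- integer(n)
    p <- rec$rna_pos[rec$rna_chrom == ch]
    if (length(p)) {
      b <- (p - 1L) %/% resolution + 1L
      b <- b[b >= 1 & b <= n]
      tb <- tabulate(b, nbins = n)
      cnt <- tb
    }
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * resolution,
               count = cnt)
  }))
  out
}

#' Keep only trans-located RNA-DNA contacts
#'
#' Retains records on different chromosomes or with |rna_pos - dna_pos|
#' beyond `min_dist` (default 2^20), then removes self-interactions of genes
#' longer than `min_dist` (both ends inside the same such gene).
#'
#' @param contacts An `rna_dna_contacts` object.
#' @param genes GRanges with `gene_id` metadata.
#' @param min_dist Linear distance cutoff in bp.
#' @return A filtered `rna_dna_contacts` (idempotent).
#' @export
trans_filter <- function(contacts, genes = NULL, min_dist = 2^20) {
  rec <- contacts$records
  keep <- rec$rna_chrom != rec$dna_chrom |
    abs(rec$rna_pos - rec$dna_pos) > min_dist
  rec <- rec[keep, , drop = FALSE]
  if (!is.null(genes) && length(genes)) {
    long <- genes[GenomicRanges::width(genes) > min_dist]
    if (length(long)) {
      gr_r <- GenomicRanges::GRanges(rec$rna_chrom,
                                     IRanges::IRanges(rec$rna_pos, width = 1))
      gr_d <- GenomicRanges::GRanges(rec$dna_chrom,
                                     IRanges::IRanges(rec$dna_pos, width = 1))
      hr <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, long))
      hd <- suppressWarnings(GenomicRanges::findOverlaps(gr_d, long))
      both <- intersect(
        paste(S4Vectors::queryHits(hr), S4Vectors::subjectHits(hr)),
        paste(S4Vectors::queryHits(hd), S4Vectors::subjectHits(hd)))
      drop <- unique(as.integer(sub(" .*", "", both)))
      if (length(drop)) rec <- rec[-drop, , drop = FALSE]
    }
  }
  structure(list(records = rec,
                 counters = c(contacts$counters,
                              trans_retained = nrow(rec)),
                 chromsizes = contacts$chromsizes),
            class = "rna_dna_contacts")
}

#' Default biotype to RNA-group mapping
#'
#' Maps GENCODE-style gene biotypes onto the eight RNA groups; any biotype
#' absent from the table falls through to "other_gene". Config-exposed so
#' alternative annotation vocabularies can be accommodated.
#' @export
default_group_map <- function() {
  list(snRNA = "snRNA", snoRNA = "snoRNA",
       miRNA = "other_small_RNA", scaRNA = "other_small_RNA",
       sRNA = "other_small_RNA", vault_RNA = "other_small_RNA",
       Y_RNA = "other_small_RNA",
       misc_RNA = "misc_RNA",
       lncRNA = "lncRNA", lincRNA = "lncRNA",
       protein_coding = "protein_coding")
}

# Priority when one position overlaps several genes: small-RNA annotations
# beat their hosts.
GROUP_PRIORITY <- c("snRNA", "snoRNA", "other_small_RNA", "misc_RNA",
                    "lncRNA", "protein_coding", "other_gene")

#' Classify RNA-end positions into the eight RNA groups
#'
#' Positions overlapping no gene are "unannotated"; positions in a gene are
#' labelled by its biotype mapped through `group_map`, any unmapped biotype
#' becoming "other_gene". When several genes overlap, the group highest in
#' `priority` wins (small RNAs beat their hosts).
#'
#' @param chrom,pos Vectors of RNA-end positions (1-based).
#' @param genes GRanges with `gene_type` metadata.
#' @param group_map Biotype -> group list, see [default_group_map()].
#' @param priority Character vector of groups, highest priority first.
#' @return Character vector of group labels.
#' @export
classify_rna_group <- function(chrom, pos, genes,
                               group_map = default_group_map(),
                               priority = GROUP_PRIORITY) {
  grp_of_gene <- vapply(as.character(S4Vectors::mcols(genes)$gene_type),
                        function(bt) group_map[[bt]] %||% "other_gene", "")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, genes))
  out <- rep("unannotated", length(q))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    gg <- grp_of_gene[S4Vectors::subjectHits(hits)]
    pr <- match(gg, priority)
    pr[is.na(pr)] <- length(priority)
    best <- tapply(seq_along(qh), qh, function(k) k[which.min(pr[k])])
    out[as.integer(names(best))] <- gg[unlist(best)]
  }
  out
}

#' Per-group trans-located caRNA tracks
#'
#' For trans-filtered contacts, counts the DNA ends falling in each bin,
#' separately for the eight RNA groups of the RNA end. Returns raw counts
#' and the log1p-transformed model features.
#'
#' @param contacts Trans-filtered `rna_dna_contacts`.
#' @param genes GRanges with `gene_type`.
#' @param grid A [bin_grid()].
#' @return List `raw` and `log` (n_bins x 8 matrices, columns ordered as the
#'   canonical group list).
#' @export
group_tracks <- function(contacts, genes, grid) {
  rec <- contacts$records
  grp <- classify_rna_group(rec$rna_chrom, rec$rna_pos, genes)
  bi <- grid_index(grid, rec$dna_chrom, rec$dna_pos)
  ok <- !is.na(bi)
  raw <- matrix(0, grid$n_bins, length(RNA_GROUPS),
                dimnames = list(NULL, RNA_GROUPS))
  for (g in RNA_GROUPS) {
    sel <- ok & grp == g
    if (any(sel)) raw[, g] <- tabulate(bi[sel], nbins = grid$n_bins)
  }
  list(raw = raw, log = log1p(raw))
}

#' Per-bin feature from an external signal track
#'
#' Mean per-bin coverage from a bedGraph-style track, normalized to the
#' iMARGI library size (bin signal * libsize / track total), then log1p.
#'
#' @param track data.frame(chrom, start, end, value) (0-based half-open) or
#'   a bedGraph path.
#' @param grid A [bin_grid()].
#' @param libsize Total retained iMARGI read pairs.
#' @return Numeric vector of length `grid$n_bins` (log scale).
#' @export
external_signal_features <- function(track, grid, libsize) {
  if (is.character(track)) track <- read_bedgraph(track)
  bin <- grid$bin_size
  sig <- numeric(grid$n_bins)
  total <- sum(track$value * (track$end - track$start))
  for (ch in unique(track$chrom)) {
    off <- grid$offsets[ch]
    if (is.na(off)) next
    nb <- as.integer(grid$chromsizes[ch]) %/% bin
    tr <- track[track$chrom == ch, ]
    # distribute each interval's mass over the bins it overlaps
    for (i in seq_len(nrow(tr))) {
      b0 <- tr$start[i] %/% bin
      b1 <- (tr$end[i] - 1L) %/% bin
      for (b in b0:min(b1, nb - 1L)) {
        ov <- min(tr$end[i], (b + 1) * bin) - max(tr$start[i], b * bin)
        sig[off + b + 1L] <- sig[off + b + 1L] + tr$value[i] * ov / bin
      }
    }
  }
  if (total > 0) sig <- sig * libsize / total
  log1p(sig)
}

#' Trans-located proportion per gene
#'
#' Nascent transcription of a gene is the number of retained reads with RNA
#' end inside it, with reads inside nested genes attributed to the nested
#' gene (subtracted from the host); the trans abundance applies the same
#' assignment to trans-filtered contacts. The proportion is trans/nascent,
#' flagged undefined (NA) when the gene has no nascent reads.
#'
#' @param contacts `rna_dna_contacts` (MAPQ-filtered, unfiltered distances).
#' @param genes GRanges with `gene_id`.
#' @param min_dist Trans distance threshold.
#' @return data.frame(gene_id, nascent_reads, trans_reads, proportion).
#' @export
trans_proportion <- function(contacts, genes, min_dist = 2^20) {
  assign_counts <- function(rec) {
    if (!nrow(rec)) return(integer(length(genes)))
    q <- GenomicRanges::GRanges(rec$rna_chrom,
                                IRanges::IRanges(rec$rna_pos, width = 1))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, genes))
    cnt <- integer(length(genes))
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(genes)[sh]
      # innermost (smallest) gene wins: host loses reads of nested genes
      best <- tapply(seq_along(qh), qh, function(k) k[which.min(w[k])])
      tb <- table(sh[unlist(best)])
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    cnt
  }
  nas <- assign_counts(contacts$records)
  tr <- assign_counts(trans_filter(contacts, genes, min_dist)$records)
  prop <- ifelse(nas > 0, tr / nas, NA_real_)
  data.frame(gene_id = S4Vectors::mcols(genes)$gene_id,
             nascent_reads = nas, trans_reads = tr, proportion = prop,
             stringsAsFactors = FALSE)
}

#' Signal matrix around reference points
#'
#' Reference-point-mode signal matrix: for each region, mean track signal in
#' columns of width `resolution` spanning the region center +/- `flank`,
#' flipped for minus-strand regions. Columns past the chromosome edge are NA.
#'
#' @param track data.frame(chrom, start, end, value) or bedGraph path.
#' @param regions data.frame(chrom, start, end, strand?) 1-based closed, or
#'   GRanges.
#' @param flank Half-width in bp.
#' @param resolution Column width in bp.
#' @return Matrix regions x positions.
#' @export
signal_matrix <- function(track, regions, flank, resolution) {
  if (is.character(track)) track <- read_bedgraph(track)
  if (inherits(regions, "GRanges")) {
    regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                          start = GenomicRanges::start(regions),
                          end = GenomicRanges::end(regions),
                          strand = as.character(GenomicRanges::strand(regions)))
  }
  ncol_out <- 2L * (flank %/% resolution)
  chrom_max <- tapply(track$end, track$chrom, max)
  out <- matrix(NA_real_, nrow(regions), ncol_out)
  for (i in seq_len(nrow(regions))) {
    ctr <- (regions$start[i] + regions$end[i]) %/% 2L
    left <- ctr - flank
    tr <- track[track$chrom == regions$chrom[i], ]
    lim <- chrom_max[[regions$chrom[i]]] %||% NA
    for (j in seq_len(ncol_out)) {
      a <- left + (j - 1L) * resolution
      b <- a + resolution
      if (a < 0 || (!is.na(lim) && b > lim)) next
      ov <- tr[tr$end > a & tr$start < b, ]
      if (!nrow(ov)) { out[i, j] <- 0; next }
      w <- pmin(ov$end, b) - pmax(ov$start, a)
      out[i, j] <- sum(ov$value * w) / resolution
    }
    st <- regions$strand[i] %||% "+"
    if (identical(st, "-")) out[i, ] <- rev(out[i, ])
  }
  out
}

#' Assemble a per-window feature matrix
#'
#' Stacks the requested channels (already on the natural-log scale) for the
#' bins of one window, in the canonical order nascent | 8 trans groups |
#' ATAC | RNA-seq. The `random` variant draws every requested channel from a
#' standard normal with a recorded seed.
#'
#' @param grid A [bin_grid()].
#' @param window list/row with chrom, start, end.
#' @param channels Named list of full-genome per-bin vectors or matrices
#'   (e.g. `nascent`, `trans` (n_bins x 8), `atac`, `rnaseq`).
#' @param variant One of "seq", "nascent", "trans", "rnaseq", "atac",
#'   "atac+trans", "random".
#' @param random_channels,seed For the `random` variant: how many N(0,1)
#'   channels to draw and with which seed.
#' @return n_bins x n_channels matrix with channel names (0 columns for
#'   "seq").
#' @export
window_features <- function(grid, window, channels = list(),
                            variant = "trans", random_channels = 8L,
                            seed = 1L) {
  i0 <- grid_index(grid, window$chrom, window$start + 1L)
  nb <- (window$end - window$start) %/% grid$bin_size
  rows <- i0:(i0 + nb - 1L)
  take <- function(x) if (is.matrix(x)) x[rows, , drop = FALSE]
  else matrix(x[rows], ncol = 1)
  pieces <- switch(variant,
    seq = matrix(0, nb, 0),
    nascent = { m <- take(channels$nascent); colnames(m) <- "nascent"; m },
    trans = take(channels$trans),
    rnaseq = { m <- take(channels$rnaseq); colnames(m) <- "rnaseq"; m },
    atac = { m <- take(channels$atac); colnames(m) <- "atac"; m },
    `atac+trans` = {
      m <- cbind(take(channels$atac), take(channels$trans))
      colnames(m)[1] <- "atac"; m
    },
    random = with_seed(seed, {
      m <- matrix(rnorm(nb * random_channels), nb, random_channels)
      colnames(m) <- paste0("random", seq_len(random_channels)); m
    }),
    stop("unknown variant: ", variant))
  pieces
}
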