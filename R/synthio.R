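#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   DNAString reverseComplement subseq
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width
#'   strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# Canonical 19-bp CTCF consensus used for planted boundaries and in-silico
# insertions (JASPAR core motif, forward orientation).
CTCF_CONSENSUS <- "TGGCCACCAGGGGGCGCTA"

RNA_GROUPS <- c("snRNA", "snoRNA", "other_small_RNA", "lncRNA", "misc_RNA",
                "protein_coding", "other_gene", "unannotated")

# GENCODE-style biotypes emitted by the generator, one per annotated group.
BIOTYPE_BY_GROUP <- c(snRNA = "snRNA", snoRNA = "snoRNA",
                      other_small_RNA = "miRNA", lncRNA = "lncRNA",
                      misc_RNA = "misc_RNA", protein_coding = "protein_coding",
                      other_gene = "pseudogene")

#' Specification of a synthetic genome
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp; must be a multiple of
#'   `bin_size`. The default matches one ~1 Mb model window per chromosome;
#'   lengths down to 2^15 are used for fast tests.
#' @param gc_content Fraction of G+C in the random background (human-like
#'   default).
#' @param bin_size Bin size in bp.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_chroms = 4L, chrom_length = 2^20,
                                  gc_content = 0.42, bin_size = 2048L,
                                  seed = 1L) {
  if (chrom_length %% bin_size != 0)
    stop("chrom_length must be a multiple of bin_size (", bin_size, ")")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 gc_content = gc_content, bin_size = as.integer(bin_size),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

#' Planted chromatin structure for the contact generator
#'
#' Describes TAD boundaries (with a per-boundary attenuation strength and a
#' number of CTCF motif copies written into the sequence), loops, per-bin
#' open/closed labels and the contact distance-decay exponent.
#'
#' @param chromsizes Named vector of chromosome lengths.
#' @param bin_size Bin size in bp.
#' @param boundaries data.frame(chrom, pos, strength, n_motifs). `pos` must be
#'   bin-aligned (0-based multiples of `bin_size`). Crossing a boundary
#'   attenuates contacts by `exp(-strength)`.
#' @param loops data.frame(chrom, posA, posB, intensity): bin-aligned anchor
#'   positions whose bin pair is boosted by `intensity`.
#' @param open_bins data.frame(chrom, bin): bins treated as open chromatin.
#' @param decay_exponent Contact probability decays as distance^-decay_exponent.
#' @export
plant_structure <- function(chromsizes, bin_size = 2048L, boundaries = NULL,
                            loops = NULL, open_bins = NULL,
                            decay_exponent = 1) {
  empty_b <- data.frame(chrom = character(0), pos = integer(0),
                        strength = numeric(0), n_motifs = integer(0))
  empty_l <- data.frame(chrom = character(0), posA = integer(0),
                        posB = integer(0), intensity = numeric(0))
  boundaries <- boundaries %||% empty_b
  if (nrow(boundaries) && any(boundaries$pos %% bin_size != 0))
    stop("boundary positions must be bin-aligned")
  if (is.null(boundaries$n_motifs)) boundaries$n_motifs <- rep(2L, nrow(boundaries))
  structure(list(chromsizes = chromsizes, bin_size = as.integer(bin_size),
                 boundaries = boundaries, loops = loops %||% empty_l,
                 open_bins = open_bins,
                 decay_exponent = decay_exponent),
            class = "planted_structure")
}

random_base <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# Write a convergent CTCF array centred at `pos` (0-based): k forward motifs
# upstream, k reverse-complement motifs downstream, `spacing` bp apart.
# Returns the modified character vector of bases.
write_ctcf_array <- function(bases, pos, k, spacing = 500L) {
  motif <- strsplit(CTCF_CONSENSUS, "")[[1]]
  rcmot <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(CTCF_CONSENSUS))), "")[[1]]
  L <- length(bases); w <- length(motif)
  for (i in seq_len(k)) {
    s_f <- pos - i * spacing          # 0-based start of forward copy
    s_r <- pos + i * spacing
    if (s_f >= 0 && s_f + w <= L) bases[(s_f + 1):(s_f + w)] <- motif
    if (s_r >= 0 && s_r + w <= L) bases[(s_r + 1):(s_r + w)] <- rcmot
  }
  bases
}

place_genes_on_chrom <- function(chrom, len, gc_unused, min_gap = 2000L) {
  # one gene of each annotated biotype plus one snoRNA nested in the
  # protein-coding host; coordinates 1-based closed (GRanges convention)
  sizes <- c(snRNA = 160L, snoRNA = 130L, other_small_RNA = 90L,
             lncRNA = 4000L, misc_RNA = 300L,
             protein_coding = max(8000L, min(20000L, len %/% 8L)),
             other_gene = 1500L)
  sizes <- pmin(sizes, len %/% 10L)
  groups <- names(sizes)
  n <- length(groups)
  starts <- integer(n)
  # deterministic spread: genes occupy evenly spaced slots with jitter
  slot <- len %/% (n + 1L)
  for (i in seq_len(n)) {
    jit <- sample.int(max(1L, slot %/% 4L), 1L)
    starts[i] <- min(max(1L, (i - 1L) * slot + jit), len - sizes[i])
  }
  df <- data.frame(chrom = chrom, start = starts,
                   end = starts + sizes - 1L,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   group = groups, stringsAsFactors = FALSE)
  # nested small gene inside the protein-coding host
  host <- df[df$group == "protein_coding", ]
  nest_start <- host$start + (host$end - host$start) %/% 3L
  df <- rbind(df, data.frame(chrom = chrom, start = nest_start,
                             end = nest_start + 129L, strand = host$strand,
                             group = "snoRNA", stringsAsFactors = FALSE))
  df
}

#' Generate a synthetic genome with annotations
#'
#' Produces random chromosome sequences (with CTCF motif arrays written at
#' planted boundaries when a structure is supplied), a gene annotation
#' covering all eight RNA groups used downstream (including a small gene
#' nested inside a protein-coding host), and annotation interval sets
#' (CTCF peaks, chromHMM-like states, SPIN-like states, repeats).
#'
#' @param spec A [synthetic_genome_spec()].
#' @param structure Optional [plant_structure()]; boundary motif arrays are
#'   written into the sequence and CTCF peak intervals emitted at them.
#' @param outdir If non-NULL, FASTA/GTF/BED files are written there.
#' @return List with `seqs` (DNAStringSet), `genes` (GRanges with `gene_id`,
#'   `gene_type`), `beds` (list of GRanges), `chromsizes`, `spec`, `structure`.
#' @export
make_genome <- function(spec, structure = NULL, outdir = NULL) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chroms))
    chromsizes <- stats::setNames(rep(spec$chrom_length, spec$n_chroms), chroms)
    seqs <- vector("list", spec$n_chroms)
    gene_dfs <- vector("list", spec$n_chroms)
    ctcf_peaks <- NULL
    for (ci in seq_along(chroms)) {
      bases <- random_base(spec$chrom_length, spec$gc_content)
      if (!is.null(structure)) {
        bd <- structure$boundaries[structure$boundaries$chrom == chroms[ci], ]
        for (bi in seq_len(nrow(bd))) {
          if (bd$n_motifs[bi] > 0)
            bases <- write_ctcf_array(bases, bd$pos[bi], bd$n_motifs[bi])
        }
        if (nrow(bd)) {
          pk <- data.frame(chrom = chroms[ci],
                           start = pmax(1L, bd$pos - bd$n_motifs * 500L - 19L),
                           end = pmin(spec$chrom_length,
                                      bd$pos + bd$n_motifs * 500L + 19L))
          ctcf_peaks <- rbind(ctcf_peaks, pk)
        }
      }
      seqs[[ci]] <- paste(bases, collapse = "")
      gene_dfs[[ci]] <- place_genes_on_chrom(chroms[ci], spec$chrom_length)
    }
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
    names(seqs) <- chroms
    genes <- do.call(rbind, gene_dfs)
    genes$gene_id <- sprintf("SYNG%04d", seq_len(nrow(genes)))
    genes$gene_type <- BIOTYPE_BY_GROUP[genes$group]
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end),
                                 strand = genes$strand)
    S4Vectors::mcols(gr)$gene_id <- genes$gene_id
    S4Vectors::mcols(gr)$gene_type <- genes$gene_type
    beds <- synth_annotation_beds(chromsizes, spec$bin_size, structure,
                                  ctcf_peaks)
    out <- list(seqs = seqs, genes = gr, beds = beds, chromsizes = chromsizes,
                spec = spec, structure = structure)
    if (!is.null(outdir)) write_genome(out, outdir)
    out
  })
}

synth_annotation_beds <- function(chromsizes, bin_size, structure, ctcf_peaks) {
  states_chrom <- c("Tss", "Enh", "Tx", "Quies", "Het")
  states_spin <- c("Speckle", "Interior_Act1", "Interior_Repr2", "Near_Lm1",
                   "Lamina")
  tile <- function(labels, width) {
    do.call(rbind, lapply(names(chromsizes), function(ch) {
      n <- ceiling(chromsizes[[ch]] / width)
      data.frame(chrom = ch, start = (seq_len(n) - 1L) * width + 1L,
                 end = pmin(seq_len(n) * width, chromsizes[[ch]]),
                 name = sample(labels, n, replace = TRUE))
    }))
  }
  chromhmm <- tile(states_chrom, 8L * bin_size)
  spin <- tile(states_spin, 16L * bin_size)
  reps <- do.call(rbind, lapply(names(chromsizes), function(ch) {
    n <- max(3L, chromsizes[[ch]] %/% 100000L)
    s <- sort(sample.int(chromsizes[[ch]] - 400L, n))
    data.frame(chrom = ch, start = s, end = s + sample(150:350, n, TRUE),
               name = sample(c("Alu", "L1", "MIR"), n, TRUE,
                             prob = c(0.6, 0.3, 0.1)))
  }))
  compart <- do.call(rbind, lapply(names(chromsizes), function(ch) {
    n <- ceiling(chromsizes[[ch]] / (32L * bin_size))
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * 32L * bin_size + 1L,
               end = pmin(seq_len(n) * 32L * bin_size, chromsizes[[ch]]),
               name = sample(c("A", "B"), n, TRUE))
  }))
  to_gr <- function(df) {
    g <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    if (!is.null(df$name)) S4Vectors::mcols(g)$name <- df$name
    g
  }
  list(ctcf_peaks = if (is.null(ctcf_peaks))
         GenomicRanges::GRanges() else to_gr(ctcf_peaks),
       chromhmm = to_gr(chromhmm), spin = to_gr(spin),
       repeats = to_gr(reps), compartments = to_gr(compart))
}

#' Write a synthetic genome bundle to disk
#'
#' @param genome A [make_genome()] result.
#' @param outdir Output directory (created if missing).
#' @export
write_genome <- function(genome, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$seqs, file.path(outdir, "genome.fa"))
  gr <- genome$genes
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "carnafold"
  rtracklayer::export(gr, file.path(outdir, "genes.gtf"), format = "gtf")
  for (nm in names(genome$beds)) {
    b <- genome$beds[[nm]]
    if (length(b))
      rtracklayer::export(b, file.path(outdir, paste0(nm, ".bed")),
                          format = "bed")
  }
  invisible(outdir)
}

# Per-chromosome upper-triangle contact weights implied by a planted
# structure: power-law decay, boundary attenuation, loop boosts.
contact_weights <- function(structure, chrom) {
  bin <- structure$bin_size
  n <- structure$chromsizes[[chrom]] %/% bin
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- (d + 1)^(-structure$decay_exponent)
  bd <- structure$boundaries[structure$boundaries$chrom == chrom, ]
  if (nrow(bd)) {
    cum <- numeric(n)
    cum[bd$pos %/% bin + 1L] <- bd$strength
    cum <- cumsum(cum)
    w <- w * exp(-abs(outer(cum, cum, "-")))
  }
  lp <- structure$loops[structure$loops$chrom == chrom, ]
  for (i in seq_len(nrow(lp))) {
    a <- lp$posA[i] %/% bin + 1L; b <- lp$posB[i] %/% bin + 1L
    w[a, b] <- w[a, b] * lp$intensity[i]
    w[b, a] <- w[b, a] * lp$intensity[i]
  }
  w[lower.tri(w)] <- 0
  w
}

#' Sample DNA-DNA contact pairs from a planted structure
#'
#' Contact probability between bins decays as distance^-decay_exponent, is
#' attenuated by `exp(-strength)` for every planted boundary crossed and
#' boosted at planted loop anchors. Records are written in 4DN .pairs format
#' (1-based positions, sorted, with header).
#'
#' @param structure A [plant_structure()].
#' @param depth Total number of read pairs.
#' @param seed RNG seed.
#' @param path Optional output .pairs path.
#' @return data.frame of pair records (invisibly the path when written).
#' @export
make_dna_dna_pairs <- function(structure, depth, seed = 1L, path = NULL) {
  stopifnot(depth > 0)
  with_seed(seed, {
    chroms <- names(structure$chromsizes)
    sizes <- as.numeric(structure$chromsizes)
    per_chrom <- as.vector(rmultinom(1, depth, sizes / sum(sizes)))
    bin <- structure$bin_size
    recs <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      if (per_chrom[ci] == 0) next
      w <- contact_weights(structure, chroms[ci])
      idx <- which(w > 0)
      cnt <- as.vector(rmultinom(1, per_chrom[ci], w[idx] / sum(w[idx])))
      keep <- cnt > 0
      ii <- ((idx[keep] - 1L) %% nrow(w)) + 1L
      jj <- ((idx[keep] - 1L) %/% nrow(w)) + 1L
      reps <- cnt[keep]
      i_all <- rep(ii, reps); j_all <- rep(jj, reps)
      p1 <- (i_all - 1L) * bin + sample.int(bin, length(i_all), TRUE)
      p2 <- (j_all - 1L) * bin + sample.int(bin, length(j_all), TRUE)
      swap <- p1 > p2
      tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      recs[[ci]] <- data.frame(
        readID = ".", chrom1 = chroms[ci], pos1 = p1,
        chrom2 = chroms[ci], pos2 = p2,
        strand1 = sample(c("+", "-"), length(p1), TRUE),
        strand2 = sample(c("+", "-"), length(p1), TRUE),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs)
    out$readID <- sprintf("DD%08d", seq_len(nrow(out)))
    if (!is.null(path))
      write_pairs(out, path, structure$chromsizes,
                  extra_header = "genome: synthetic")
    out
  })
}

#' Specification of synthetic RNA-DNA contacts
#'
#' @param expression Named numeric vector: expected read count per gene_id.
#' @param cis_fraction Probability that a read's DNA end lies within 2^20 bp
#'   of its RNA end on the same chromosome.
#' @param trans_target_bias Multiplicative weight favouring open bins when
#'   sampling trans DNA ends (1 = unbiased).
#' @param mapq_distribution data.frame(value, prob) MAPQ values are drawn
#'   from; the default exercises the MAPQ <= 30 filter.
#' @param intergenic_reads Reads whose RNA end falls outside any gene
#'   (classified downstream as "unannotated").
#' @param targeted Optional data.frame(gene, dna_chrom, dna_pos, reads):
#'   additional trans reads sent from `gene` to a fixed DNA position (used to
#'   plant feature signal at chosen bins).
#' @export
synthetic_contact_spec <- function(expression, cis_fraction = 0.6,
                                   trans_target_bias = 1,
                                   mapq_distribution = data.frame(
                                     value = c(60L, 40L, 30L, 10L),
                                     prob = c(0.70, 0.15, 0.10, 0.05)),
                                   intergenic_reads = 0L,
                                   targeted = NULL) {
  stopifnot(all(expression >= 0), cis_fraction >= 0, cis_fraction <= 1)
  structure(list(expression = expression, cis_fraction = cis_fraction,
                 trans_target_bias = trans_target_bias,
                 mapq_distribution = mapq_distribution,
                 intergenic_reads = as.integer(intergenic_reads),
                 targeted = targeted),
            class = "synthetic_contact_spec")
}

#' Planted RNA-DNA sequence homology
#'
#' A mutated copy of part of `rna_gene`'s sequence is written at `dna_locus`,
#' with controlled alignment identity and longest perfect-match run, so the
#' R-loop scan has recoverable ground truth.
#'
#' @param rna_gene gene_id of the source gene.
#' @param dna_chrom,dna_start Target locus (1-based start).
#' @param identity Target fraction of matching bases over the copied length.
#' @param max_perfect_run Longest contiguous perfect match, bp.
#' @param length Copied length in bp.
#' @export
planted_homology <- function(rna_gene, dna_chrom, dna_start, identity = 0.9,
                             max_perfect_run = 15L, length = 100L) {
  stopifnot(identity > 0, identity <= 1, max_perfect_run <= length)
  structure(list(rna_gene = rna_gene, dna_chrom = dna_chrom,
                 dna_start = as.integer(dna_start), identity = identity,
                 max_perfect_run = as.integer(max_perfect_run),
                 length = as.integer(length)),
            class = "planted_homology")
}

other_base <- function(b) {
  swap <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  unname(swap[b])
}

# Mutate a copied subsequence so that (a) exactly round((1-identity)*L)
# bases differ and (b) the longest intact run equals max_perfect_run.
mutate_copy <- function(bases, identity, run) {
  L <- length(bases)
  n_mut <- max(1L, round((1 - identity) * L))
  pos <- run + 1L
  if (n_mut > 1L) {
    rest <- seq(from = run + 1L, to = L, length.out = n_mut + 1L)
    pos <- unique(pmin(L, round(rest[-1])))
    pos <- c(run + 1L, pos[pos > run + 1L])[seq_len(n_mut)]
    pos <- pos[!is.na(pos)]
  }
  bases[pos] <- other_base(bases[pos])
  bases
}

#' Plant RNA-DNA homologies into a genome
#'
#' @param genome A [make_genome()] result.
#' @param homologies List of [planted_homology()] objects.
#' @return The genome with modified `seqs` and a `homology_table` data.frame
#'   recording the copied RNA subsequence and its DNA locus.
#' @export
plant_homologies <- function(genome, homologies) {
  ids <- S4Vectors::mcols(genome$genes)$gene_id
  tab <- NULL
  for (h in homologies) {
    gi <- match(h$rna_gene, ids)
    if (is.na(gi)) stop("homology references absent gene: ", h$rna_gene)
    g <- genome$genes[gi]
    ch_g <- as.character(GenomicRanges::seqnames(g))
    off <- GenomicRanges::start(g)
    sub <- as.character(Biostrings::subseq(genome$seqs[[ch_g]], off,
                                           off + h$length - 1L))
    bases <- mutate_copy(strsplit(sub, "")[[1]], h$identity, h$max_perfect_run)
    tgt <- genome$seqs[[h$dna_chrom]]
    s <- h$dna_start
    genome$seqs[[h$dna_chrom]] <- Biostrings::DNAString(paste0(
      as.character(Biostrings::subseq(tgt, 1, s - 1L)),
      paste(bases, collapse = ""),
      as.character(Biostrings::subseq(tgt, s + h$length,
                                      length(tgt)))))
    tab <- rbind(tab, data.frame(
      rna_gene = h$rna_gene, rna_chrom = ch_g, rna_start = off,
      rna_seq = sub, dna_chrom = h$dna_chrom, dna_start = s,
      identity = h$identity, max_perfect_run = h$max_perfect_run,
      length = h$length, stringsAsFactors = FALSE))
  }
  genome$homology_table <- tab
  genome
}

#' Sample RNA-DNA contact pairs
#'
#' Reads are emitted per gene at its expression level; each read's RNA end is
#' uniform within the gene and its DNA end is cis (within 2^20 bp, same
#' chromosome) with probability `cis_fraction`, otherwise trans (beyond
#' 2^20 bp or on another chromosome, with optional bias toward open bins).
#' MAPQ values are drawn from the spec's distribution. The RNA end is side 1
#' and the DNA end side 2, and a truth table records each read's gene,
#' cis/trans status, group and MAPQ.
#'
#' @param spec A [synthetic_contact_spec()].
#' @param genome A [make_genome()] (optionally homology-planted) result.
#' @param seed RNG seed.
#' @param path,truth_path Optional output paths (.pairs and TSV).
#' @return List with `records` and `truth` data.frames.
#' @export
make_rna_dna_pairs <- function(spec, genome, seed = 1L, path = NULL,
                               truth_path = NULL) {
  stopifnot(inherits(spec, "synthetic_contact_spec"))
  genes <- genome$genes
  ids <- S4Vectors::mcols(genes)$gene_id
  miss <- setdiff(names(spec$expression), ids)
  if (length(miss)) stop("expression references absent genes: ",
                         paste(miss, collapse = ", "))
  chromsizes <- genome$chromsizes
  bin <- genome$spec$bin_size
  struct <- genome$structure
  with_seed(seed, {
    # global bin table for trans target sampling
    bins <- do.call(rbind, lapply(names(chromsizes), function(ch)
      data.frame(chrom = ch,
                 start = seq(0L, chromsizes[[ch]] - bin, by = bin))))
    wts <- rep(1, nrow(bins))
    if (!is.null(struct) && !is.null(struct$open_bins) &&
        spec$trans_target_bias != 1) {
      key <- paste(bins$chrom, bins$start %/% bin)
      okey <- paste(struct$open_bins$chrom, struct$open_bins$bin)
      wts[key %in% okey] <- spec$trans_target_bias
    }
    out <- list(); truth <- list(); n <- 0L
    emit <- function(gene, grp, rch, rpos, dch, dpos, cis, homology = FALSE) {
      n <<- n + 1L
      # record the geometric truth, which downstream filters see
      cis <- rch == dch & abs(rpos - dpos) <= 2^20
      mq <- sample(spec$mapq_distribution$value, length(rpos), TRUE,
                   prob = spec$mapq_distribution$prob)
      out[[n]] <<- data.frame(
        readID = ".", chrom1 = rch, pos1 = rpos, chrom2 = dch, pos2 = dpos,
        strand1 = "+", strand2 = sample(c("+", "-"), length(rpos), TRUE),
        mapq = mq, stringsAsFactors = FALSE)
      truth[[n]] <<- data.frame(
        gene = gene, group = grp, rna_chrom = rch, rna_pos = rpos,
        dna_chrom = dch, dna_pos = dpos, cis = cis, mapq = mq,
        homology = homology, stringsAsFactors = FALSE)
    }
    group_of <- stats::setNames(
      names(BIOTYPE_BY_GROUP)[match(S4Vectors::mcols(genes)$gene_type,
                                    BIOTYPE_BY_GROUP)], ids)
    for (g in names(spec$expression)) {
      ng <- spec$expression[[g]]
      if (ng <= 0) next
      gi <- match(g, ids)
      ch <- as.character(GenomicRanges::seqnames(genes[gi]))
      gs <- GenomicRanges::start(genes[gi]); ge <- GenomicRanges::end(genes[gi])
      rpos <- gs + sample.int(ge - gs + 1L, ng, TRUE) - 1L
      is_cis <- runif(ng) < spec$cis_fraction
      # cis: distance <= 2^20 on the same chromosome
      d <- pmin(round(stats::rexp(ng, rate = 1 / 5e4)), 2^20)
      sgn <- sample(c(-1L, 1L), ng, TRUE)
      dpos_cis <- clip(rpos + sgn * d, 1L, chromsizes[[ch]])
      # trans: any bin beyond 2^20 or on another chromosome, judged from the
      # gene midpoint (genes are short relative to the 2^20 cutoff)
      mid <- (gs + ge) %/% 2L
      elig <- bins$chrom != ch | abs(bins$start + bin %/% 2L - mid) > 2^20 + bin
      eidx <- which(elig)
      tb <- eidx[sample.int(length(eidx), ng, TRUE, prob = wts[eidx])]
      dpos_trans <- bins$start[tb] + sample.int(bin, ng, TRUE)
      dch_trans <- bins$chrom[tb]
      dch <- ifelse(is_cis, ch, dch_trans)
      dpos <- ifelse(is_cis, dpos_cis, dpos_trans)
      emit(g, group_of[[g]], ch, rpos, dch, as.integer(dpos), is_cis)
    }
    if (spec$intergenic_reads > 0) {
      # RNA ends in annotation gaps
      occ <- genes
      for (ch in names(chromsizes)) {
        free <- setdiff(seq(1L, chromsizes[[ch]], by = 997L),
                        unlist(lapply(seq_along(occ), function(i)
                          if (as.character(GenomicRanges::seqnames(occ[i])) == ch)
                            GenomicRanges::start(occ[i]):GenomicRanges::end(occ[i])
                          else integer(0))))
        k <- spec$intergenic_reads %/% length(chromsizes)
        if (k == 0 || !length(free)) next
        rpos <- sample(free, k, TRUE)
        tb <- sample.int(nrow(bins), k, TRUE, prob = wts)
        emit("", "unannotated", ch, rpos, bins$chrom[tb],
             bins$start[tb] + sample.int(bin, k, TRUE), cis = FALSE)
      }
    }
    if (!is.null(spec$targeted)) {
      for (i in seq_len(nrow(spec$targeted))) {
        tg <- spec$targeted[i, ]
        gi <- match(tg$gene, ids)
        if (is.na(gi)) stop("targeted contacts reference absent gene: ", tg$gene)
        ch <- as.character(GenomicRanges::seqnames(genes[gi]))
        gs <- GenomicRanges::start(genes[gi])
        ge <- GenomicRanges::end(genes[gi])
        k <- tg$reads
        if (k <= 0) next
        rpos <- gs + sample.int(ge - gs + 1L, k, TRUE) - 1L
        dpos <- tg$dna_pos + sample.int(bin, k, TRUE) - 1L
        emit(tg$gene, group_of[[tg$gene]], ch, rpos, tg$dna_chrom,
             as.integer(clip(dpos, 1L, chromsizes[[tg$dna_chrom]])),
             cis = FALSE)
      }
    }
    if (!is.null(genome$homology_table)) {
      ht <- genome$homology_table
      for (i in seq_len(nrow(ht))) {
        emit(ht$rna_gene[i], group_of[[ht$rna_gene[i]]], ht$rna_chrom[i],
             ht$rna_start[i], ht$dna_chrom[i], ht$dna_start[i],
             cis = FALSE, homology = TRUE)
      }
    }
    records <- do.call(rbind, out)
    truth <- do.call(rbind, truth)
    records$readID <- truth$readID <- sprintf("RD%08d", seq_len(nrow(records)))
    if (!is.null(path))
      write_pairs(records, path, chromsizes,
                  extra_header = "columns1: RNA end; columns2: DNA end")
    if (!is.null(truth_path))
      write.table(truth, truth_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    list(records = records, truth = truth)
  })
}

#' Generate ATAC-like and RNA-seq-like signal tracks
#'
#' Per-bin signal with a multiplicative boost at open bins (ATAC) and over
#' gene bodies (RNA-seq), with optional lognormal noise. Deterministic under
#' seed.
#'
#' @param structure A [plant_structure()] (its `open_bins` drive the ATAC
#'   boost; NULL open bins give a flat track).
#' @param genes Optional GRanges of genes (drives the RNA-seq track).
#' @param open_boost Fold elevation at open bins.
#' @param base Baseline signal value.
#' @param noise_sd SD of lognormal noise (0 = noiseless).
#' @param seed RNG seed.
#' @param outdir Optional directory for bedGraph output.
#' @return List of data.frames `atac`, `rnaseq` (chrom, start, end, value;
#'   0-based half-open starts as in bedGraph).
#' @export
make_signal_tracks <- function(structure, genes = NULL, open_boost = 10,
                               base = 1, noise_sd = 0, seed = 1L,
                               outdir = NULL) {
  bin <- structure$bin_size
  with_seed(seed, {
    mk <- function(boost_key) {
      do.call(rbind, lapply(names(structure$chromsizes), function(ch) {
        n <- structure$chromsizes[[ch]] %/% bin
        v <- rep(base, n)
        if (!is.null(boost_key)) v[boost_key[[ch]] %||% integer(0)] <- base * open_boost
        if (noise_sd > 0) v <- v * exp(rnorm(n, 0, noise_sd))
        data.frame(chrom = ch, start = (seq_len(n) - 1L) * bin,
                   end = seq_len(n) * bin, value = v)
      }))
    }
    open_key <- NULL
    if (!is.null(structure$open_bins)) {
      open_key <- split(structure$open_bins$bin + 1L, structure$open_bins$chrom)
    }
    atac <- mk(open_key)
    gene_key <- NULL
    if (!is.null(genes) && length(genes)) {
      gb <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                       bin = GenomicRanges::start(genes) %/% bin)
      gene_key <- split(gb$bin + 1L, gb$chrom)
    }
    rnaseq <- mk(gene_key)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_bedgraph(atac, file.path(outdir, "atac.bedGraph"))
      write_bedgraph(rnaseq, file.path(outdir, "rnaseq.bedGraph"))
    }
    list(atac = atac, rnaseq = rnaseq)
  })
}

#' Write / read a bedGraph track
#'
#' @param df data.frame(chrom, start, end, value), 0-based half-open.
#' @param path File path.
#' @export
write_bedgraph <- function(df, path) {
  data.table::fwrite(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- data.table::fread(path, header = FALSE, data.table = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}
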