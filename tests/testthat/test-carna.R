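mini_contacts <- function(df, cs = c(chr1 = 2^17L, chr2 = 2^17L)) {
  n <- nrow(df)
  rec <- data.frame(chrom1 = df$rc, pos1 = df$rp, chrom2 = df$dc,
                    pos2 = df$dp, strand1 = rep("+", n),
                    strand2 = rep("+", n),
                    mapq = df$mapq %||% rep(60L, n))
  carnafold::parse_rna_dna_pairs(list(records = rec, chromsizes = cs))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("MAPQ boundary is exclusive at 30", {
  c3 <- mini_contacts(data.frame(rc = "chr1", rp = c(10L, 20L, 30L),
                                 dc = "chr1", dp = c(100L, 200L, 300L),
                                 mapq = c(30L, 31L, 60L)))
  expect_equal(nrow(c3$records), 2L)
  expect_equal(unname(c3$counters["dropped_mapq"]), 1)
  expect_true(all(c3$records$mapq > 30))
})

test_that("nascent track counts RNA ends and aggregates exactly", {
  cs <- c(chr1 = 2^14L)
  c5 <- mini_contacts(data.frame(rc = "chr1", rp = rep(3000L, 5),
                                 dc = "chr1", dp = 1:5 * 100L), cs)
  tr <- nascent_track(c5, cs, resolution = 2048L)
  expect_equal(tr$count[2], 5L)
  expect_equal(sum(tr$count), 5L)
  # coarse resolution equals block-sum of a compatible finer resolution
  w <- small_world()
  fine <- nascent_track(small_contacts(), w$chromsizes, resolution = 256L)
  coarse <- nascent_track(small_contacts(), w$chromsizes, resolution = 2048L)
  for (ch in names(w$chromsizes)) {
    fc <- fine[fine$chrom == ch, ]
    agg <- rowsum(fc$count, fc$start %/% 2048L)
    expect_equal(as.vector(agg), coarse$count[coarse$chrom == ch])
  }
  empty <- mini_contacts(data.frame(rc = character(0), rp = integer(0),
                                    dc = character(0), dp = integer(0)), cs)
  expect_true(all(nascent_track(empty, cs)$count == 0))
})

test_that("trans filter applies the distance rule and long-gene removal", {
  cs <- c(chr1 = 4e6, chr2 = 4e6)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1e6, 100), c(3.2e6, 400)))
  S4Vectors::mcols(genes)$gene_id <- c("LONG", "SHORT")
  S4Vectors::mcols(genes)$gene_type <- c("protein_coding", "snRNA")
  cc <- mini_contacts(data.frame(
    rc = c("chr1", "chr1", "chr1"),
    rp = c(100L, 100L, 1500000L),
    dc = c("chr1", "chr2", "chr1"),
    dp = c(500000L, 100L, 3000000L)), cs)
  tf <- trans_filter(cc, genes)
  # within 2^20 removed; inter-chromosomal kept; 1.5 Mb apart but both
  # inside the same >1 Mb gene removed
  expect_equal(nrow(tf$records), 1L)
  expect_equal(tf$records$dna_chrom, "chr2")
  # idempotence
  tf2 <- trans_filter(tf, genes)
  expect_identical(tf$records, tf2$records)
})

test_that("RNA group classification is total with small-RNA priority", {
  w <- small_world()
  genes <- w$genome$genes
  types <- S4Vectors::mcols(genes)$gene_type
  sno <- genes[types == "snoRNA"][1]   # nested inside protein-coding host
  pos <- GenomicRanges::start(sno) + 5L
  ch <- as.character(GenomicRanges::seqnames(sno))
  expect_equal(classify_rna_group(ch, pos, genes), "snoRNA")
  expect_equal(classify_rna_group("chr1", 2^17 - 5L, genes), "unannotated")
  # totality on arbitrary positions
  got <- classify_rna_group(rep("chr1", 50), seq(1L, 2^17, length.out = 50),
                            genes)
  expect_true(all(got %in% carnafold:::RNA_GROUPS))
})

test_that("group tracks conserve trans read counts and log1p zeros", {
  w <- small_world()
  tf <- trans_filter(small_contacts(), w$genome$genes)
  gt <- group_tracks(tf, w$genome$genes, w$grid)
  expect_equal(sum(gt$raw), nrow(tf$records))
  expect_equal(gt$log[gt$raw == 0], rep(0, sum(gt$raw == 0)))
  expect_equal(dim(gt$raw), c(w$grid$n_bins, 8L))
})

test_that("external signal features scale with iMARGI library size", {
  grid <- bin_grid(c(chr1 = 2^14L))
  const <- data.frame(chrom = "chr1", start = seq(0L, 2^14 - 2048L, 2048L),
                      end = seq(2048L, 2^14, 2048L), value = 4)
  f1 <- external_signal_features(const, grid, libsize = 1e6)
  expect_true(all(abs(f1 - f1[1]) < 1e-12))
  f2 <- external_signal_features(const, grid, libsize = 2e6)
  # doubling the library size adds ~log(2) for large signals
  expect_lt(abs((f2[1] - f1[1]) - log(2)), 1e-2)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
  expect_true(all(external_signal_features(empty, grid, 1e4) == 0))
})

test_that("trans proportion handles distance, nesting and zero nascent", {
  cs <- c(chr1 = 4e6, chr2 = 4e6)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 2000, 3e6), c(10000, 2200, 3.1e6)))
  S4Vectors::mcols(genes)$gene_id <- c("HOST", "NESTED", "EMPTY")
  S4Vectors::mcols(genes)$gene_type <- c("protein_coding", "snoRNA", "lncRNA")
  # host: 12 reads, 5 inside the nested gene; 4 of the host's own 7 go trans
  rp <- c(rep(5000L, 7), rep(2100L, 5))
  dp <- c(rep(8000L, 3), rep(3.5e6, 4), rep(8000L, 5))
  cc <- mini_contacts(data.frame(rc = "chr1", rp = rp, dc = "chr1",
                                 dp = as.integer(dp)), cs)
  tp <- trans_proportion(cc, genes)
  expect_equal(tp$nascent_reads[tp$gene_id == "HOST"], 7L)
  expect_equal(tp$nascent_reads[tp$gene_id == "NESTED"], 5L)
  expect_equal(tp$proportion[tp$gene_id == "HOST"], 4 / 7)
  expect_true(is.na(tp$proportion[tp$gene_id == "EMPTY"]))
})

test_that("signal matrix matches a brute-force windowed mean", {
  cs <- c(chr1 = 2^15L)
  with_seed(21, {
    tr <- data.frame(chrom = "chr1", start = seq(0L, 2^15 - 256L, 256L),
                     end = seq(256L, 2^15, 256L),
                     value = runif(2^15 / 256))
  })
  regions <- data.frame(chrom = "chr1", start = c(8000L, 20000L),
                        end = c(8200L, 20400L), strand = c("+", "-"))
  sm <- signal_matrix(tr, regions, flank = 2048L, resolution = 512L)
  # brute force for region 1, column 1
  ctr <- (8000L + 8200L) %/% 2L
  a <- ctr - 2048L; b <- a + 512L
  ov <- tr[tr$end > a & tr$start < b, ]
  exp1 <- sum(ov$value * (pmin(ov$end, b) - pmax(ov$start, a))) / 512
  expect_equal(sm[1, 1], exp1)
  # minus strand flips
  smp <- signal_matrix(tr, transform(regions, strand = "+"),
                       flank = 2048L, resolution = 512L)
  expect_equal(sm[2, ], rev(smp[2, ]))
  # constant track gives a constant matrix
  trc <- transform(tr, value = 2)
  smc <- signal_matrix(trc, regions, flank = 2048L, resolution = 512L)
  expect_true(all(abs(smc - 2) < 1e-12))
  # delta signal at the region center hits the center column only
  trd <- transform(tr, value = 0)
  trd$value[trd$start <= ctr & trd$end > ctr] <- 1
  smd <- signal_matrix(trd, regions[1, ], flank = 1024L, resolution = 256L)
  expect_true(all(which(smd[1, ] > 0) %in% c(4L, 5L)))
})

test_that("window features honor variants and the random control", {
  w <- small_world()
  win <- data.frame(chrom = "chr1", start = 0L, end = 2^17L)
  tf <- trans_filter(small_contacts(), w$genome$genes)
  gt <- group_tracks(tf, w$genome$genes, w$grid)
  fm <- window_features(w$grid, win, channels = list(trans = gt$log),
                        variant = "trans")
  expect_equal(dim(fm), c(64L, 8L))
  expect_identical(colnames(fm), carnafold:::RNA_GROUPS)
  sq <- window_features(w$grid, win, variant = "seq")
  expect_equal(ncol(sq), 0L)
  r1 <- window_features(w$grid, win, variant = "random", seed = 5)
  r2 <- window_features(w$grid, win, variant = "random", seed = 5)
  expect_identical(r1, r2)
  expect_equal(mean(r1), 0, tolerance = 0.1)
})
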