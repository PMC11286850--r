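test_that("motif insertion replaces in place with exact geometry", {
  with_seed(71, {
    s <- paste(sample(c("A", "C", "G", "T"), 2^14, TRUE), collapse = "")
  })
  ins <- insert_ctcf(s, k = 3, locus = 8000L)
  expect_equal(nchar(ins$seq), nchar(s))
  motif <- carnafold:::CTCF_CONSENSUS
  rcmot <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  for (i in seq_len(nrow(ins$coords))) {
    found <- substr(ins$seq, ins$coords$start[i], ins$coords$end[i])
    expect_equal(found, if (ins$coords$strand[i] == "+") motif else rcmot)
  }
  # exact 500-bp spacing, symmetric about the locus
  fwd <- ins$coords[ins$coords$strand == "+", ]
  expect_equal(sort(8000L - (fwd$start - 1L)), c(500L, 1000L, 1500L))
  # untouched outside the insertion footprints
  foot <- unlist(Map(seq, ins$coords$start, ins$coords$end))
  keep <- setdiff(seq_len(nchar(s)), foot)
  expect_equal(strsplit(ins$seq, "")[[1]][keep], strsplit(s, "")[[1]][keep])
  # k = 0 is the identity
  expect_identical(insert_ctcf(s, k = 0, locus = 8000L)$seq, s)
  expect_error(insert_ctcf(s, k = 4, locus = 100L), "edge")
})

test_that("caRNA elevation acts on the raw scale of one channel only", {
  f <- matrix(log1p(c(100, 7, 3, 9)), 4, 2,
              dimnames = list(NULL, c("lncRNA", "atac")))
  e1 <- elevate_carna(f, "lncRNA", bins = 1L, fold = 1)
  expect_identical(e1, f)
  e2 <- elevate_carna(f, "lncRNA", bins = 1L, fold = exp(1))
  expect_lt(abs((e2[1, 1] - f[1, 1]) - 1), 0.01)   # log1p(100e) - log1p(100)
  expect_identical(e2[, 2], f[, 2])
  expect_identical(e2[2:4, 1], f[2:4, 1])
  expect_error(elevate_carna(f, "nope", 1L, 2), "unknown channel")
})

test_that("elevation response is zero at fold 1 and for severed channels", {
  cfg <- model_config(window_bp = 2^15, trunk_channels = 5L,
                      trunk_kernel = 7L, d_channels = 6L,
                      feature_channels = c("lncRNA", "x"), seed = 12)
  m <- init_model(cfg)
  with_seed(81, {
    data <- list(list(
      onehot = encode_sequence(paste(sample(c("A", "C", "G", "T"), 2^15,
                                            TRUE), collapse = "")),
      features = matrix(abs(rnorm(cfg$n_bins * 2)), cfg$n_bins, 2,
                        dimnames = list(NULL, c("lncRNA", "x")))))
  })
  r1 <- elevation_response(m, data, list(8L), channel = "lncRNA",
                           folds = 1, diamond = 2)
  expect_equal(r1$curve$d_insulation, 0)
  expect_equal(r1$curve$d_contact, 0)
  m0 <- m
  m0$params$proj$W[tail(cfg$trunk_channels, 1) + 1L, ] <- 0  # sever lncRNA
  r0 <- elevation_response(m0, data, list(8L), channel = "lncRNA",
                           folds = exp(c(0.5, 1)), diamond = 2)
  expect_equal(r0$curve$d_insulation, c(0, 0))
  expect_equal(r0$curve$d_contact, c(0, 0))
})

test_that("rloop scan matches string oracles on constructed pairs", {
  # identical sequences: perfect identity and run
  with_seed(91, {
    s <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  })
  sc <- rloop_scan(s, s)
  expect_equal(sc$identity, 1)
  expect_equal(sc$max_run, 20L)
  expect_true(sc$is_candidate)
  # mismatches every 8 bases cap the run below the threshold
  p8 <- make_string_pair(40, seq(8, 40, by = 8), seed = 92)
  sc8 <- rloop_scan(p8$rna, p8$dna)
  expect_false(sc8$is_candidate)
  expect_lte(sc8$max_run, 8L)
  # a perfect 15-bp island inside an overall-poor match fails the
  # identity gate
  island <- make_string_pair(50, setdiff(seq(2, 50, by = 2), 21:36),
                             seed = 93)
  sci <- rloop_scan(island$rna, island$dna)
  expect_false(sci$is_candidate)
  expect_error(rloop_scan("", "ACGT"), "empty")
})

test_that("rloop scan is strand-aware and reverse-complement symmetric", {
  p <- make_string_pair(60, c(25, 26), seed = 94)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  sc_f <- rloop_scan(p$rna, p$dna)
  sc_minus <- rloop_scan(p$rna, rc(p$dna))   # target on the minus strand
  expect_equal(sc_minus$identity, sc_f$identity)
  expect_equal(sc_minus$max_run, sc_f$max_run)
  expect_equal(sc_minus$strand, "-")
  sc_rc <- rloop_scan(rc(p$rna), rc(p$dna))
  expect_equal(sc_rc$identity, sc_f$identity, tolerance = 1e-12)
  expect_equal(sc_rc$max_run, sc_f$max_run)
})

test_that("landmark fractions count candidate overlap per class", {
  landmarks <- data.frame(chrom = "chr1",
                          pos = seq(1e5, 1e6, length.out = 10),
                          class = rep(c("strong", "weak"), 5))
  none <- rloop_landmark_fractions(
    data.frame(dna_chrom = character(0), dna_pos = integer(0)), landmarks)
  expect_true(all(none$fraction == 0))
  cand <- data.frame(dna_chrom = "chr1", dna_pos = 1e5 + 3000)
  fr <- rloop_landmark_fractions(cand, landmarks, resolution = 5000)
  expect_equal(fr$fraction[fr$class == "strong"], 1 / 5)
  expect_equal(fr$fraction[fr$class == "weak"], 0)
  # interval oracle on a random fixture
  with_seed(95, {
    cands <- data.frame(dna_chrom = "chr1",
                        dna_pos = sample.int(1e6, 30))
  })
  fr2 <- rloop_landmark_fractions(cands, landmarks, resolution = 5000)
  brute <- sapply(landmarks$pos, function(p)
    any(abs(cands$dna_pos - p) <= 5000))
  for (cl in unique(landmarks$class)) {
    expect_equal(fr2$fraction[fr2$class == cl],
                 mean(brute[landmarks$class == cl]))
  }
})

test_that("ctcf response is deterministic and flat for untrained models", {
  cfg <- model_config(window_bp = 2^15, trunk_channels = 5L,
                      trunk_kernel = 7L, d_channels = 6L, seed = 33)
  m <- init_model(cfg)
  r1 <- ctcf_response(m, n_sequences = 4, k_values = 1:2, diamond = 2,
                      seed = 44)
  r2 <- ctcf_response(m, n_sequences = 4, k_values = 1:2, diamond = 2,
                      seed = 44)
  expect_identical(r1$curve, r2$curve)
  # untrained weights: no systematic response beyond noise
  expect_gt(r1$tests$p, 0.01)
})
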