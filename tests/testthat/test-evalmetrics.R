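rand_map <- function(n, seed) with_seed(seed, {
  m <- matrix(rnorm(n * n), n, n)
  (m + t(m)) / 2
})

test_that("map scores are exact on identical maps and handle constants", {
  a <- rand_map(20, 1)
  s <- score_maps(a, a)
  expect_equal(unname(s[c("pearson", "spearman", "scc", "ssim")]),
               rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(s["mse"]), 0)
  sc <- score_maps(matrix(1, 10, 10), rand_map(10, 2))
  expect_true(is.na(sc["pearson"]))
})

test_that("pearson matches the brute-force formula on a 5x5 matrix", {
  a <- rand_map(5, 3); b <- rand_map(5, 4)
  idx <- which(col(a) - row(a) >= 2)
  av <- a[idx]; bv <- b[idx]
  brute <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(unname(score_maps(a, b)["pearson"]), brute, tolerance = 1e-12)
})

test_that("metrics degrade monotonically with added noise", {
  a <- rand_map(24, 5)
  eps_grid <- c(0.05, 0.3, 1, 3)
  res <- sapply(eps_grid, function(e) {
    vals <- sapply(1:8, function(s) {
      b <- a + e * rand_map(24, 100 + 10 * s + round(100 * e))
      sc <- score_maps(a, b)
      c(sc["pearson"], sc["scc"], sc["ssim"], sc["mse"])
    })
    rowMeans(vals)
  })
  for (k in 1:3) expect_true(all(diff(res[k, ]) < 0))  # correlations fall
  expect_true(all(diff(res[4, ]) > 0))                 # mse rises
})

test_that("scc equals an independent per-stratum computation", {
  a <- rand_map(16, 6); b <- a + 0.5 * rand_map(16, 7)
  # independent oracle: explicit loop over diagonals
  rs <- ws_h <- c()
  for (d in 2:15) {
    i <- seq_len(16 - d)
    av <- a[cbind(i, i + d)]; bv <- b[cbind(i, i + d)]
    if (length(av) < 2 || sd(av) == 0 || sd(bv) == 0) next
    rs <- c(rs, cor(av, bv))
    ws_h <- c(ws_h, length(av) * sqrt(var(rank(av)) * var(rank(bv))))
  }
  expect_equal(scc(a, b), sum(rs * ws_h) / sum(ws_h), tolerance = 1e-12)
  expect_equal(scc(a, b, weights = "equal"), mean(rs), tolerance = 1e-12)
  # degenerate strata are skipped without crashing
  cst <- outer(1:10, 1:10, function(i, j) abs(i - j))
  expect_true(is.na(scc(cst, cst + 0)))  # every stratum constant
})

test_that("insulation equals the brute-force diamond mean", {
  m <- rand_map(32, 8)
  prof <- insulation_profile(m, diamond = 5)
  for (i in 6:27) {
    expect_equal(prof[i], mean(m[(i - 5):(i - 1), (i + 1):(i + 5)]))
  }
  expect_true(all(is.na(prof[c(1:5, 28:32)])))
  expect_true(all(insulation_profile(matrix(2, 12, 12), 3) %in% c(2, NA)))
  expect_error(insulation_profile(m, diamond = 16), "larger than half")
  expect_error(insulation_profile(m, diamond = 0), ">= 1")
})

test_that("insulation correlation is 1 for identical/shifted profiles", {
  a <- rand_map(24, 9); b <- a + 0.7   # constant shift
  expect_equal(unname(insulation_correlation(list(a, a), list(a, b),
                                             diamond = 4)),
               c(1, 1), tolerance = 1e-9)
  # independent random maps decorrelate on average
  rs <- insulation_correlation(lapply(1:30, function(s) rand_map(24, s)),
                               lapply(1:30, function(s) rand_map(24, 500 + s)),
                               diamond = 4)
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.2)
})

test_that("boundary classification applies strength, sharing and fold rules", {
  a <- data.frame(chrom = "chr1", pos = c(1e6, 2e6, 3e6),
                  strength = c(0.6, 0.25, 0.4))
  b <- data.frame(chrom = "chr1", pos = c(1e6 + 15000, 2e6 + 25000,
                                          3e6 + 5000),
                  strength = c(0.6, 0.3, 0.9))
  cl <- classify_boundaries(a, b)
  expect_equal(cl$strength_class, c("strong", "weak", "weak"))
  expect_equal(cl$sharing, c("shared", "unique", "shared"))
  expect_equal(cl$shared_subclass[1], "stable")
  # log2(0.9/0.4) = 1.17 > 1 -> higher insulation in the other cell type
  expect_equal(cl$shared_subclass[3], "higher_in_B")
  # symmetry: swapping cell types maps higher_in_A <-> higher_in_B
  cl_rev <- classify_boundaries(b, a)
  expect_equal(cl_rev$sharing[c(1, 3)], c("shared", "shared"))
  expect_equal(cl_rev$shared_subclass[3], "higher_in_A")
})

test_that("loop anchors share by the 20 Kb mutual-nearest rule", {
  a <- data.frame(chrom = "chr1", pos = c(1e6, 5e6))
  b <- data.frame(chrom = "chr1", pos = c(1e6 + 19000, 5e6 + 21000))
  cl <- classify_loop_anchors(a, b)
  expect_equal(cl$sharing, c("shared", "unique"))
  # brute-force nearest-neighbor agreement on a random fixture
  with_seed(10, {
    pa <- sort(sample.int(1e7, 12)); pb <- sort(sample.int(1e7, 12))
  })
  cl2 <- classify_loop_anchors(data.frame(chrom = "chr1", pos = pa),
                               data.frame(chrom = "chr1", pos = pb))
  brute <- sapply(pa, function(p) min(abs(pb - p)) <= 20000)
  # a mutual-nearest match implies a nearest neighbor within range
  expect_true(all(brute[cl2$sharing == "shared"]))
  expect_true(all(cl2$sharing[!brute] == "unique"))
})

test_that("cell-type-specific subset selection nests and filters", {
  scores <- data.frame(mse = c(0.5, 0.1, 0.2, 0.4),
                       scc = c(0.9, 0.1, 0.8, 0.9),
                       ssim = c(0.5, 0.5, 0.05, 0.5))
  ss <- select_celltype_specific(scores)
  expect_equal(ss$subset1, c(1L, 4L))
  expect_equal(ss$subset2, c(1L, 2L, 3L, 4L))
  expect_true(all(ss$subset1 %in% ss$subset2))
  ident <- data.frame(mse = rep(0, 3), scc = rep(1, 3), ssim = rep(1, 3))
  s0 <- select_celltype_specific(ident)
  expect_length(s0$subset1, 0L)
  expect_length(s0$subset2, 0L)
  st <- select_celltype_specific(scores, transition = "B->A",
                                 comp_a = c("B", "B", "A", "A"),
                                 comp_b = c("A", "A", "A", "A"))
  expect_equal(st$subset1, 1L)
  expect_error(select_celltype_specific(scores, transition = "A->B"),
               "compartment labels")
})

test_that("window compartment labels take the majority overlap", {
  comp <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 60001), c(60000, 2e5)))
  S4Vectors::mcols(comp)$name <- c("A", "B")
  wins <- data.frame(chrom = "chr1", start = c(0L, 100000L),
                     end = c(100000L, 200000L))
  expect_equal(window_compartments(wins, comp), c("A", "B"))
})
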