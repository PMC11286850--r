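test_that("expected gradients recover the closed form for linear models", {
  with_seed(31, {
    n <- 12; p <- 3
    W <- matrix(rnorm(n * p), n, p)
    x <- matrix(rnorm(n * p), n, p)
    bgs <- lapply(1:5, function(i) matrix(rnorm(n * p), n, p))
  })
  fgrad <- function(z) list(value = sum(W * z), grad = W)
  sc <- expected_gradients(fgrad, x, bgs, steps = 4)
  xbar <- Reduce(`+`, bgs) / length(bgs)
  expect_equal(unclass_m(sc), W * (x - xbar), tolerance = 1e-10)
  comp <- attr(sc, "completeness")
  expect_equal(unname(comp["sum_scores"]), unname(comp["delta_f"]),
               tolerance = 1e-10)
  expect_error(expected_gradients(fgrad, x, list()), "empty")
})

test_that("background scheme follows the split rules deterministically", {
  labels <- c(rep("train", 30), rep("valid", 4), rep("test", 4))
  bg1 <- background_scheme(labels, n = 20, seed = 5)
  bg2 <- background_scheme(labels, n = 20, seed = 5)
  expect_identical(bg1, bg2)
  train_idx <- which(labels == "train")
  for (i in 31:38) {
    expect_length(bg1[[i]], 20L)
    expect_true(all(bg1[[i]] %in% train_idx))
  }
  # training windows draw from the opposite half only
  halves <- lapply(train_idx, function(i) bg1[[i]])
  for (i in train_idx) expect_false(i %in% bg1[[i]])
  # the two halves are disjoint pools
  pools <- unique(lapply(halves, function(h) paste(sort(unique(h)),
                                                   collapse = ",")))
  expect_lte(length(pools), 2L)
})

test_that("model contribution scores vanish for disconnected channels", {
  cfg <- model_config(window_bp = 2^14, trunk_channels = 5L,
                      trunk_kernel = 7L, d_channels = 6L,
                      feature_channels = c("f1", "f2"), seed = 4)
  m <- init_model(cfg)
  # sever channel 2: zero the proj rows that read it
  ct <- tail(cfg$trunk_channels, 1)
  m$params$proj$W[ct + 2L, ] <- 0
  data <- lapply(1:6, function(s) {
    with_seed(s, list(
      onehot = encode_sequence(paste(sample(c("A", "C", "G", "T"), 2^14,
                                            TRUE), collapse = "")),
      features = matrix(rnorm(cfg$n_bins * 2), cfg$n_bins, 2)))
  })
  cs <- contribution_scores(m, data, split_labels = rep("train", 6),
                            n_background = 2, seed = 1, steps = 3)
  for (r in cs$raw) expect_equal(unname(r[, 2]), rep(0, cfg$n_bins))
  # determinism
  cs2 <- contribution_scores(m, data, split_labels = rep("train", 6),
                             n_background = 2, seed = 1, steps = 3)
  expect_equal(cs$raw, cs2$raw)
  # normalization bounds with the sign preserved
  for (i in seq_along(cs$normalized)) {
    expect_true(all(abs(cs$normalized[[i]]) <= 1 + 1e-12))
    expect_equal(sign(cs$normalized[[i]]), sign(cs$raw[[i]]))
  }
  allmax <- apply(abs(do.call(rbind, cs$normalized)), 2, max)
  expect_equal(unname(allmax[1]), 1)  # scope-wide max attains 1
})

test_that("extreme regions respect eligibility, size and tie rules", {
  with_seed(41, {
    scores <- rnorm(200)
    input <- c(rep(1, 100), rep(0, 100))   # only first half eligible
  })
  top1 <- extreme_regions(scores, input, pct = 1, tail = "top")
  expect_equal(top1, which.max(replace(scores, 101:200, -Inf)))
  top5 <- extreme_regions(scores, input, pct = 5, tail = "top")
  expect_length(top5, 5L)
  expect_true(all(top5 <= 100))
  # brute-force sort oracle
  ord <- order(-scores[1:100])
  expect_setequal(top5, ord[1:5])
  bot5 <- extreme_regions(scores, input, pct = 5, tail = "bottom")
  expect_setequal(bot5, order(scores[1:100])[1:5])
  # all-equal scores: deterministic genomic-order tie break
  ties <- extreme_regions(rep(0.5, 200), input, pct = 5, tail = "top")
  expect_equal(ties, 1:5)
})

test_that("enrichment is log2(observed/expected) with a centered null", {
  eligible <- 1:200
  ann_all <- rep(TRUE, 500)
  ann_quarter <- c(rep(TRUE, 50), rep(FALSE, 450))   # 25% of eligible
  regions_in <- 1:20                                  # fully inside
  e <- enrichment(regions_in, eligible,
                  list(all = ann_all, quarter = ann_quarter))
  expect_equal(unname(e["all"]), 0)
  expect_equal(unname(e["quarter"]), 2)               # log2(1/0.25)
  expect_true(is.na(enrichment(regions_in, eligible,
                               list(none = rep(FALSE, 500)))))
  # permutation null is centered near zero
  with_seed(51, {
    ann <- sample(c(TRUE, FALSE), 500, TRUE)
    vals <- sapply(1:100, function(i)
      enrichment(sample(eligible, 40), eligible, list(a = ann)))
  })
  expect_lt(mean(abs(vals)), 0.25)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("differential regions gate on fold change and magnitude", {
  d <- differential_regions(rna_scores = c(0.3, 0.3, 0.2, -0.3),
                            atac_scores = c(0.05, 0.1, 0.01, 0))
  expect_equal(d$passes, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(d$fold_change[1], 6)
  expect_equal(d$fold_change[4], Inf)   # zero accessibility score
})

test_that("hypergeometric p equals exact enumeration and BH is monotone", {
  # N=20, K=5, n=4, k=3: P[X >= 3] by direct enumeration
  exact <- sum(sapply(3:4, function(i)
    choose(5, i) * choose(15, 4 - i))) / choose(20, 4)
  counts <- data.frame(
    gene = c(rep("g1", 2), "g2"),
    bin = c(1L, 2L, 1L),
    count = c(3L, 2L, 3L))
  # construct totals: g1 K=5, bin1 n=4 (single extra gene g2 tuned below)
  hc <- hypergeom_interactions(data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    bin = c(1L, 2L, 1L, 3L),
    count = c(3L, 2L, 1L, 14L)))
  row <- hc[hc$gene == "g1" & hc$bin == 1L, ]
  expect_equal(row$K, 5); expect_equal(row$n, 4)
  expect_equal(row$p, exact, tolerance = 1e-12)
  # BH: q is a monotone transform of p; retained set grows with alpha
  expect_true(all(diff(hc$q[order(hc$p)]) >= -1e-12))
  expect_true(all(hc$retained == (hc$q <= 0.05)))
  loose <- hypergeom_interactions(data.frame(
    gene = c("g1", "g1", "g2", "g3"), bin = c(1L, 2L, 1L, 3L),
    count = c(3L, 2L, 1L, 14L)), alpha = 0.5)
  expect_true(all(hc$retained <= loose$retained[match(
    paste(hc$gene, hc$bin), paste(loose$gene, loose$bin))]))
})

test_that("planted enriched gene-bin pairs are retained at FDR 0.05", {
  with_seed(61, {
    genes <- paste0("g", 1:8)
    counts <- expand.grid(gene = genes, bin = 1:40,
                          stringsAsFactors = FALSE)
    counts$count <- rpois(nrow(counts), 2)
    counts$count[counts$gene == "g1" & counts$bin == 7] <- 60
  })
  hc <- hypergeom_interactions(counts[counts$count > 0, ])
  planted <- hc[hc$gene == "g1" & hc$bin == 7, ]
  expect_true(planted$retained)
  others <- hc[!(hc$gene == "g1" & hc$bin == 7), ]
  expect_lt(mean(others$retained), 0.05)
})

test_that("candidate ranking counts extreme-region interactions", {
  hc <- data.frame(gene = c("a", "a", "a", "b", "b", "c", "d"),
                   bin = c(1, 2, 3, 1, 9, 9, 5),
                   count = 5, K = 10, n = 10, p = 0.001, q = 0.01,
                   retained = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  rk <- rank_candidate_rnas(hc, extreme_bins = c(1, 2))
  expect_equal(rk$gene[1], "a")          # 2 extreme interactions
  expect_equal(rk$n_extreme[rk$gene == "a"], 2L)
  expect_equal(rk$ratio[rk$gene == "b"], 0.5)
  expect_false("d" %in% rk$gene)         # no retained interactions
  # gene interacting only with extreme bins has ratio 1
  expect_equal(rk$ratio[rk$gene == "a"], 2 / 3)
  rk2 <- rank_candidate_rnas(hc[hc$gene == "b", ][1, ], extreme_bins = 1)
  expect_equal(rk2$ratio, 1)
  # brute-force recomputation on the fixture
  brute <- sapply(c("a", "b", "c"), function(g) {
    d <- hc[hc$retained & hc$gene == g, ]
    sum(d$bin %in% c(1, 2))
  })
  expect_equal(stats::setNames(rk$n_extreme, rk$gene)[names(brute)],
               brute[names(brute)], ignore_attr = TRUE)
})
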