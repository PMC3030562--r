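lens1 <- c(chr1 = 1000L)

test_that("strand-specific extension follows the fragment model", {
  tg <- tibble::tibble(chrom = "chr1",
                       pos = c(100L, 500L, 50L),
                       strand = c("+", "-", "-"))
  iv <- extend_tags(tg, 200, lens1)
  expect_equal(iv$start, c(100L, 301L, 0L))
  expect_equal(iv$end, c(300L, 501L, 51L))
  # forward tag near the right edge is clipped too
  iv2 <- extend_tags(tibble::tibble(chrom = "chr1", pos = 950L, strand = "+"),
                     200, lens1)
  expect_equal(c(iv2$start, iv2$end), c(950L, 1000L))
})

test_that("coverage equals per-base interval membership", {
  tg <- tibble::tibble(chrom = "chr1", pos = c(0L, 100L),
                       strand = c("+", "+"))
  cov <- build_coverage(extend_tags(tg, 200, c(chr1 = 300L)),
                        c(chr1 = 300L))
  expect_equal(sum(cov$chr1), 400)
  expect_true(all(cov$chr1[101:200] == 2))
  expect_true(all(cov$chr1[1:100] == 1))

  empty <- build_coverage(tibble::tibble(chrom = character(),
                                         start = integer(), end = integer()),
                          lens1)
  expect_true(all(empty$chr1 == 0))

  tg3 <- random_tags(500, 5000, seed = 21)
  iv <- extend_tags(tg3, 200, c(chr1 = 5000L))
  expect_equal(unclass(build_coverage(iv, c(chr1 = 5000L)))$chr1,
               oracle_coverage(iv, c(chr1 = 5000L))$chr1)
})

test_that("coverage mass equals the clipped extension lengths exactly", {
  for (seed in 22:24) {
    tg <- random_tags(300, 2000, seed = seed)
    iv <- extend_tags(tg, 150, c(chr1 = 2000L))
    cov <- build_coverage(iv, c(chr1 = 2000L))
    expect_identical(sum(cov$chr1), as.integer(sum(iv$end - iv$start)))
  }
})

test_that("mirrored strands give the mirrored coverage track", {
  G <- 2000L
  tg <- random_tags(400, G, seed = 25)
  cov <- build_coverage(extend_tags(tg, 100, c(chr1 = G)), c(chr1 = G))
  mirror <- tibble::tibble(
    chrom = "chr1",
    pos = G - 1L - tg$pos,
    strand = ifelse(tg$strand == "+", "-", "+"))
  cov_m <- build_coverage(extend_tags(mirror, 100, c(chr1 = G)), c(chr1 = G))
  expect_equal(cov_m$chr1, rev(cov$chr1))
})

test_that("the Poisson height threshold matches an exhaustive tail-sum search", {
  G <- 2e5; n <- 2000; L <- 200
  tg <- random_tags(n, G, seed = 31)
  cov <- build_coverage(extend_tags(tg, L, c(chr1 = G)), c(chr1 = G))
  h <- height_threshold(cov, n, G, L, peak_fdr = 0.05)

  # independent search: exact Poisson tail sums over every candidate height,
  # observed peak counts from run-length encoding of the coverage array
  lambda <- n * L / G
  covv <- cov$chr1
  fdr_at <- sapply(1:(max(covv) + 1), function(hh) {
    r <- rle(covv >= hh)
    obs <- sum(r$values)
    expf <- (G / L) * sum(dpois(hh:1000, lambda))
    min(1, expf / max(1, obs))
  })
  expect_equal(h, which(fdr_at <= 0.05)[1])
})

test_that("peak_fdr = 1 accepts height one and thresholds rise as fdr falls", {
  G <- 1e5; n <- 2000
  tg <- random_tags(n, G, seed = 32)
  cov <- build_coverage(extend_tags(tg, 200, c(chr1 = G)), c(chr1 = G))
  expect_equal(height_threshold(cov, n, G, 200, peak_fdr = 1), 1L)
  hs <- sapply(c(0.5, 0.2, 0.05, 0.01),
               function(f) height_threshold(cov, n, G, 200, peak_fdr = f))
  expect_true(all(diff(hs) >= 0))
})

test_that("Monte-Carlo and Poisson nulls agree in the sparse-tag regime", {
  # sparse background (mean coverage << 1) is the regime peak calling
  # operates in; there, false runs and false windows coincide
  G <- 1e6; n <- 2000
  g <- generate_genome(1, G, 0.42, seed = 36)
  pl <- plant_regions(g, 10, 400, base_enrichment = 20, seed = 37)
  d <- sample_design(conditions = c("x", "y"), group_b = "y",
                     chip_replicates = 1)
  tg <- simulate_chip_tags(pl$genome, pl$regions, d, depth = n, seed = 38)
  one <- tg[tg$sample_id == "x_R1", ]
  cov <- build_coverage(extend_tags(one, 200, c(chr1 = G)), c(chr1 = G))
  hp <- height_threshold(cov, n, G, 200, 0.05, "poisson")
  hm <- height_threshold(cov, n, G, 200, 0.05, "montecarlo",
                         mc_iterations = 200, seed = 34)
  expect_lte(abs(hp - hm), 1)
})

test_that("peaks are maximal runs with leftmost summits", {
  # plateau of height 2 on [100, 200)
  tg <- tibble::tibble(chrom = "chr1", pos = c(0L, 100L), strand = c("+", "+"))
  pk <- call_peaks(tg, c(chr1 = 300L), L = 200, min_height = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 200L)
  expect_equal(pk$summit, 100L)
  expect_equal(pk$height, 2L)

  expect_equal(nrow(call_peaks(tg, c(chr1 = 300L), L = 200,
                               min_height = 99)), 0)
  expect_equal(nrow(call_peaks(tg[0, ], c(chr1 = 300L), L = 200)), 0)
})

test_that("peak calling equals a brute-force scan of the coverage array", {
  G <- 20000L
  tg <- random_tags(800, G, seed = 35)
  covv <- unclass(build_coverage(extend_tags(tg, 200, c(chr1 = G)),
                                 c(chr1 = G)))$chr1
  for (h in c(5, 10, 15)) {
    pk <- call_peaks(tg, c(chr1 = G), L = 200, min_height = h)
    bf <- oracle_peaks(covv, h)
    if (is.null(bf)) {
      expect_equal(nrow(pk), 0)
    } else {
      expect_equal(pk$start, bf$start)
      expect_equal(pk$end, bf$end)
      expect_equal(pk$summit, bf$summit)
      expect_equal(pk$height, bf$height)
    }
  }
})

test_that("planted regions are recovered by FDR-thresholded peak calling", {
  g <- generate_genome(1, 1e6, 0.42, seed = 41)
  pl <- plant_regions(g, 50, width = 400, base_enrichment = 10, seed = 42)
  d <- sample_design(conditions = c("X", "Y"), group_b = "Y",
                     chip_replicates = 1)
  tags <- simulate_chip_tags(pl$genome, pl$regions, d, depth = 1e5, seed = 43)
  one <- tags[tags$sample_id == "X_R1", ]
  pk <- call_peaks(one, genome_lengths(g), L = 200, peak_fdr = 0.05)
  hit <- vapply(seq_len(nrow(pl$regions)), function(r) {
    any(pk$chrom == pl$regions$chrom[r] &
          pk$start < pl$regions$end[r] &
          pl$regions$start[r] < pk$end)
  }, logical(1))
  expect_gte(sum(hit), 45)
})
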