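test_that("IUPAC scanning counts both strands, palindromes once", {
  # forward match "AGATAA" at offset 2; reverse-complement "YTATCW" absent
  expect_equal(scan_sequence("TTAGATAAGG", "WGATAR"), 1L)
  expect_equal(scan_sequence(strrep("C", 50), "AAAAAAAAAA"), 0L)
  expect_equal(scan_sequence("ACG", "WGATAR"), 0L)  # motif longer than seq

  # palindromic consensus: single-strand count, no double counting
  s <- random_seq(2000, seed = 71)
  expect_equal(scan_sequence(s, "CAGCTG"), oracle_iupac_hits(s, "CAGCTG"))

  # random sequences match the brute-force double-strand oracle
  for (seed in 72:74) {
    s <- random_seq(500, seed = seed)
    for (m in c("WGATAR", "TTGCGCAA", "RGAGGAAGTR", "NCANNTGN")) {
      expect_equal(scan_sequence(s, m), oracle_scan(s, m))
    }
  }
  expect_error(scan_sequence("ACGT", "WXZ"), "IUPAC")
})

make_motif_fixture <- function(seed = 75) {
  g <- generate_genome(1, 60000, 0.42, seed = seed)
  spec <- tibble::tibble(motif_id = c("Gata2", "Cebpa"),
                         iupac = c("WGATAR", "TTGCGCAA"),
                         rate_deprived = c(3, 1), rate_other = c(1, 1))
  pl <- plant_regions(g, 40, width = 400, motif_spec = spec,
                      fraction_group_effect = 0.5, effect_fold = 0.25,
                      seed = seed + 1)
  at <- build_atlas(tibble::tibble(
    chrom = pl$regions$chrom, start = pl$regions$start,
    end = pl$regions$end, sample_id = "s1",
    summit = pl$regions$center, height = 10L))
  list(genome = pl$genome, regions = pl$regions, atlas = at)
}

test_that("observed counts are additive and recover planted instances", {
  fx <- make_motif_fixture()
  motifs <- consensus_motifs()
  expect_equal(observed_counts(character(0), fx$atlas, fx$genome,
                               motifs)$observed,
               rep(0L, nrow(motifs)))
  ids <- fx$atlas$region_id
  all_counts <- observed_counts(ids, fx$atlas, fx$genome, motifs)
  half1 <- observed_counts(ids[1:20], fx$atlas, fx$genome, motifs)
  half2 <- observed_counts(ids[21:40], fx$atlas, fx$genome, motifs)
  expect_equal(all_counts$observed, half1$observed + half2$observed)
  expect_error(observed_counts("nope", fx$atlas, fx$genome, motifs),
               "present in the atlas")

  # deprived truth regions contain >= 3 Gata2 matches each
  dep <- fx$regions[fx$regions$group_effect < 1, ]
  dep_ids <- fx$atlas$region_id[fx$atlas$start %in% dep$start]
  per_region <- vapply(dep_ids, function(id) {
    observed_counts(id, fx$atlas, fx$genome,
                    motifs[motifs$motif_id == "Gata2", ])$observed
  }, integer(1))
  expect_true(all(per_region >= 3))
})

test_that("motif counts are invariant to reverse-complementing the sequence", {
  fx <- make_motif_fixture(seed = 78)
  seqs <- as.character(region_sequences(fx$genome, fx$atlas))
  for (m in c("WGATAR", "TTGCGCAA", "CAGCTG")) {
    fwd <- vapply(seqs, scan_sequence, integer(1), iupac = m)
    rc <- vapply(seqs, function(s) {
      scan_sequence(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s))), m)
    }, integer(1))
    expect_equal(unname(rc), unname(fwd))
  }
})

test_that("bootstrap nulls have the analytic mean and are seed-deterministic", {
  fx <- make_motif_fixture(seed = 80)
  motifs <- consensus_motifs()[1:2, ]
  nul <- bootstrap_null(fx$atlas, fx$genome, motifs, set_size = 15,
                        B = 1000, seed = 81)
  nul2 <- bootstrap_null(fx$atlas, fx$genome, motifs, set_size = 15,
                         B = 1000, seed = 81)
  expect_identical(nul, nul2)

  # E[total] = set_size * atlas mean; check within 3 SE of the bootstrap
  all_counts <- observed_counts(fx$atlas$region_id, fx$atlas, fx$genome,
                                motifs)
  expected <- 15 * all_counts$observed / nrow(fx$atlas)
  se <- nul$expected_sd / sqrt(1000)
  expect_true(all(abs(nul$expected_mean - expected) <= 3 * se + 1e-9))
})

test_that("a pool of identical regions gives a degenerate null", {
  g <- new_genome_for_test(strrep("ACGT", 2500))
  starts <- as.integer(seq(0, 9900, by = 100))[1:20]
  at <- build_atlas(tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 40L, sample_id = "s",
    summit = starts + 20L, height = 5L))
  motifs <- tibble::tibble(motif_id = "m", iupac = "ACGTACGT")
  nul <- bootstrap_null(at, g, motifs, set_size = 4, B = 100, seed = 82)
  per_region <- observed_counts(at$region_id[1], at, g, motifs)$observed
  expect_equal(nul$expected_sd, 0)
  expect_equal(nul$expected_mean, 4 * per_region)
})

test_that("Z-scores call over/under at the inclusive threshold", {
  obs <- tibble::tibble(motif_id = c("a", "b", "c", "d"),
                        observed = c(30L, 20L, 5L, 10L))
  nul <- tibble::tibble(motif_id = c("a", "b", "c", "d"),
                        expected_mean = c(20, 20, 20, 10),
                        expected_sd = c(5, 5, 5, 0),
                        set_size = 10L, B = 100L)
  z <- motif_z_scores(obs, nul, z_threshold = 3)
  expect_equal(z$z, c(2, 0, -3, 0))
  expect_equal(z$call, c("ns", "ns", "under", "ns"))
  expect_false(any(z$degenerate[1:3]))
  expect_true(z$degenerate[4])

  # degenerate null with a discrepant observation flags a signed sentinel
  nul$expected_mean[4] <- 8
  z2 <- motif_z_scores(obs, nul)
  expect_equal(z2$z[4], Inf)
  expect_equal(z2$call[4], "over")
})
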