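# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately naive: per-base / per-pair loops and a
# hand-rolled IUPAC matcher, kept free of any package internals.

oracle_coverage <- function(intervals, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch) {
    v <- integer(chrom_lengths[[ch]])
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      if (iv$end[i] > iv$start[i]) {
        idx <- (iv$start[i] + 1L):iv$end[i]
        v[idx] <- v[idx] + 1L
      }
    }
    v
  })
  setNames(out, names(chrom_lengths))
}

# raw region x sample counts by double loop over (region, extended tag)
oracle_region_counts <- function(regions, intervals, mode = "overlap") {
  vapply(seq_len(nrow(regions)), function(r) {
    same <- intervals$chrom == regions$chrom[r]
    if (mode == "overlap") {
      sum(same &
            intervals$start < regions$end[r] &
            regions$start[r] < intervals$end)
    } else {
      sum(same &
            intervals$start >= regions$start[r] &
            intervals$end <= regions$end[r])
    }
  }, numeric(1))
}

# maximal runs of coverage >= h with leftmost-maximum summit
oracle_peaks <- function(cov, h) {
  res <- NULL
  i <- 1L
  n <- length(cov)
  while (i <= n) {
    if (cov[i] >= h) {
      j <- i
      while (j < n && cov[j + 1L] >= h) j <- j + 1L
      seg <- cov[i:j]
      res <- rbind(res, data.frame(
        start = i - 1L, end = j,
        summit = i - 1L + which.max(seg) - 1L,
        height = max(seg)))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  res
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_hits <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  if (k > length(s)) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[i + j - 1L] %in% IUPAC_SETS[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# double-strand occurrence count, palindromes counted once
oracle_scan <- function(seq, motif) {
  rc <- oracle_revcomp(motif)
  n <- oracle_iupac_hits(seq, motif)
  if (rc != motif) n <- n + oracle_iupac_hits(seq, rc)
  n
}

# windowed background variance by explicit rank-and-average loop
oracle_bg_var <- function(mat, w) {
  n <- nrow(mat)
  means <- rowMeans(mat)
  vars <- apply(mat, 1, var)
  ord <- order(means)
  rank_of <- match(seq_len(n), ord)
  k <- (w - 1) / 2
  sapply(seq_len(n), function(i) {
    r <- rank_of[i]
    win <- ord[max(1, r - k):min(n, r + k)]
    mean(vars[win])
  })
}

random_tags <- function(n, G, seed, chrom = "chr1") {
  set.seed(seed)
  tibble::tibble(
    chrom = chrom,
    pos = as.integer(floor(runif(n) * G)),
    strand = sample(c("+", "-"), n, replace = TRUE))
}

new_genome_for_test <- function(seq, chrom = "chr1") {
  acetatlas:::new_genome(tibble::tibble(
    chrom = chrom, length = nchar(seq), sequence = seq))
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
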