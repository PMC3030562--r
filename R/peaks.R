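#' Extend tags strand-specifically into fragment-length intervals
#'
#' Each mapped tag (a 5' end plus strand) is extended to `L` bp in its
#' sequencing direction: a forward tag at `p` becomes `[p, p + L)` and a
#' reverse tag at `p` becomes `[p - L + 1, p + 1)`, clipped to chromosome
#' bounds. Coordinates are 0-based half-open throughout.
#'
#' @param tags Tag tibble with columns `chrom`, `pos`, `strand` (and
#'   optionally `sample_id`, preserved).
#' @param L Extension length in bp (default 200).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Tibble of intervals with columns `chrom`, `start`, `end` (plus
#'   `sample_id`/`strand` when present in the input).
#' @export
extend_tags <- function(tags, L = 200, chrom_lengths) {
  assert_count(L, "L", min = 1)
  if (any(!tags$strand %in% c("+", "-"))) abort("`strand` must be '+' or '-'.")
  len <- chrom_lengths[tags$chrom]
  if (anyNA(len)) abort("Tags reference chromosomes absent from `chrom_lengths`.")
  start <- ifelse(tags$strand == "+", tags$pos, tags$pos - L + 1L)
  end <- ifelse(tags$strand == "+", tags$pos + L, tags$pos + 1L)
  out <- tibble(chrom = tags$chrom,
                start = pmax(as.integer(start), 0L),
                end = pmin(as.integer(end), as.integer(len)))
  if ("sample_id" %in% names(tags)) out$sample_id <- tags$sample_id
  out$strand <- tags$strand
  out
}

#' Build a per-base coverage track from extended intervals
#'
#' Height at base `b` is the number of intervals containing `b`.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`), 0-based
#'   half-open, within bounds.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Named list of integer vectors (one per chromosome, length =
#'   chromosome length), class `coverage_track`.
#' @export
build_coverage <- function(intervals, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch) {
    n <- as.integer(chrom_lengths[[ch]])
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    delta <- integer(n + 1L)
    if (nrow(iv)) {
      if (any(iv$start < 0 | iv$end > n | iv$start > iv$end)) {
        abort("Interval out of chromosome bounds.")
      }
      add <- tabulate(iv$start + 1L, nbins = n + 1L)
      sub <- tabulate(iv$end + 1L, nbins = n + 1L)
      delta <- add - sub
    }
    cumsum(delta)[seq_len(n)]
  })
  structure(setNames(out, names(chrom_lengths)), class = "coverage_track")
}

# Number of peaks (maximal runs of coverage >= h) at every height h,
# via level upcrossings; counts[h] is the peak count at threshold h.
peak_counts_by_height <- function(coverage) {
  maxh <- max(0L, vapply(coverage, function(v) if (length(v)) max(v) else 0L,
                         numeric(1)))
  if (maxh == 0L) return(integer(0))
  counts <- integer(maxh)
  for (v in coverage) {
    if (!length(v)) next
    prev <- c(0L, v[-length(v)])
    rise <- which(v > prev)
    if (!length(rise)) next
    lo <- prev[rise] + 1L
    hi <- v[rise]
    lv <- sequence(hi - lo + 1L, from = lo)
    counts <- counts + tabulate(lv, nbins = maxh)
  }
  counts
}

#' Minimal peak height at a target empirical FDR
#'
#' Chooses the smallest coverage height `h` whose estimated false discovery
#' rate is at or below `peak_fdr`. The FDR at height `h` is the expected
#' number of false peaks under a uniform-tag null divided by the observed
#' peak count at `h` (capped at 1). Two nulls are available:
#' `"poisson"` computes the expected false peaks analytically as
#' `(G / L) * P(Poisson(lambda) >= h)` with `lambda = library_size * L / G`
#' (coverage in non-overlapping L-bp windows); `"montecarlo"` simulates
#' `mc_iterations` uniform tag sets of the same library size and averages
#' their peak counts at each height. Because run counts are uninformative
#' below the mean coverage, the Monte-Carlo mode additionally requires the
#' FDR criterion to hold at every height above the chosen one.
#'
#' @param coverage Observed `coverage_track` (supplies observed peak counts).
#' @param library_size Number of tags in the sample.
#' @param genome_length Total genome length G in bp; must exceed `L`.
#' @param L Extension length in bp.
#' @param peak_fdr Target FDR in (0, 1].
#' @param null_mode `"poisson"` or `"montecarlo"`.
#' @param mc_iterations Simulations for the Monte-Carlo null.
#' @param seed Seed for the Monte-Carlo null.
#' @return Integer threshold height `h >= 1`.
#' @export
height_threshold <- function(coverage, library_size, genome_length, L = 200,
                             peak_fdr = 0.05,
                             null_mode = c("poisson", "montecarlo"),
                             mc_iterations = 200, seed = NULL) {
  null_mode <- match.arg(null_mode)
  assert_count(library_size, "library_size", min = 1)
  if (genome_length <= L) abort("`genome_length` must exceed `L`.")
  if (!is.numeric(peak_fdr) || peak_fdr <= 0 || peak_fdr > 1) {
    abort("`peak_fdr` must be in (0, 1].")
  }
  obs <- peak_counts_by_height(coverage)
  maxh <- length(obs)
  if (maxh == 0L) return(1L)
  heights <- seq_len(maxh + 1L)
  obs_at <- c(obs, 0L)

  if (null_mode == "poisson") {
    lambda <- library_size * L / genome_length
    exp_false <- (genome_length / L) * ppois(heights - 1L, lambda,
                                             lower.tail = FALSE)
  } else {
    exp_false <- numeric(maxh + 1L)
    sims <- with_seed(seed, {
      lapply(seq_len(mc_iterations), function(b) {
        pos <- as.integer(floor(runif(library_size) * genome_length))
        strand <- sample(c("+", "-"), library_size, replace = TRUE)
        tg <- tibble(chrom = "null", pos = pos, strand = strand)
        cv <- build_coverage(extend_tags(tg, L, c(null = genome_length)),
                             c(null = genome_length))
        peak_counts_by_height(cv)
      })
    })
    for (cts in sims) {
      k <- min(length(cts), maxh + 1L)
      if (k > 0) exp_false[seq_len(k)] <- exp_false[seq_len(k)] + cts[seq_len(k)]
    }
    exp_false <- exp_false / mc_iterations
  }
  fdr_hat <- pmin(1, exp_false / pmax(1, obs_at))
  if (null_mode == "poisson") {
    h <- heights[which(fdr_hat <= peak_fdr)[1]]
  } else {
    # run-count FDR estimates are uninformative below the mean coverage
    # (everything merges into a few runs), so require the criterion to
    # hold at the chosen height and every height above it
    ok_above <- rev(cumprod(rev(fdr_hat <= peak_fdr))) > 0
    h <- heights[which(ok_above)[1]]
  }
  if (is.na(h)) h <- maxh + 1L
  as.integer(h)
}

#' Call peaks as maximal runs of coverage above an FDR-controlled height
#'
#' For each sample, tags are extended strand-specifically, per-base coverage
#' is built, a minimal height is chosen at the target empirical FDR, and
#' peaks are reported as maximal runs of coverage at or above that height.
#' The summit is the leftmost base attaining the run maximum.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`, optional `sample_id`;
#'   multiple samples are called independently).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param L Extension length in bp (default 200).
#' @param peak_fdr Target FDR (default 0.05).
#' @param null_mode,mc_iterations,seed Passed to [height_threshold()].
#' @param min_height Optional fixed threshold overriding the FDR calculation.
#' @return Tibble of peaks sorted by (`sample_id`, `chrom`, `start`) with
#'   columns `sample_id`, `chrom`, `start`, `end`, `summit`, `height`,
#'   `threshold`.
#' @export
call_peaks <- function(tags, chrom_lengths, L = 200, peak_fdr = 0.05,
                       null_mode = c("poisson", "montecarlo"),
                       mc_iterations = 200, seed = NULL, min_height = NULL) {
  null_mode <- match.arg(null_mode)
  if (!"sample_id" %in% names(tags)) tags$sample_id <- "sample"
  empty <- tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer(),
                  height = integer(), threshold = integer())
  if (nrow(tags) == 0) return(empty)
  out <- lapply(split(tags, tags$sample_id), function(tg) {
    cov <- build_coverage(extend_tags(tg, L, chrom_lengths), chrom_lengths)
    h <- min_height %||%
      height_threshold(cov, nrow(tg), sum(as.numeric(chrom_lengths)), L,
                       peak_fdr, null_mode, mc_iterations, seed)
    peaks <- coverage_peaks(cov, h)
    if (nrow(peaks)) {
      peaks$sample_id <- tg$sample_id[1]
      peaks$threshold <- as.integer(h)
    }
    peaks
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res %>%
    dplyr::select(dplyr::all_of(names(empty))) %>%
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start)
}

# Maximal runs of coverage >= h, with leftmost-maximum summits.
coverage_peaks <- function(coverage, h) {
  rows <- lapply(names(coverage), function(ch) {
    v <- coverage[[ch]]
    above <- v >= h
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    do.call(rbind, lapply(keep, function(k) {
      seg <- v[starts[k]:ends[k]]
      sm <- starts[k] + which.max(seg) - 1L
      data.frame(chrom = ch, start = starts[k] - 1L, end = ends[k],
                 summit = sm - 1L, height = max(seg))
    }))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), height = integer()))
  }
  as_tibble(do.call(rbind, rows))
}

#' Write peaks as BED
#'
#' Columns: chrom, start, end, name, height, strand ("."), summit (a
#' documented seventh-column extension).
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  readr::write_tsv(
    tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
           name = sprintf("%s_peak%05d", peaks$sample_id,
                          seq_len(nrow(peaks))),
           score = peaks$height, strand = ".", summit = peaks$summit),
    path, col_names = FALSE)
  invisible(path)
}
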