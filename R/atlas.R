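#' Fixed-width candidate windows around peak summits
#'
#' Each peak contributes one window of width `W` centered on its summit,
#' `[summit - W/2, summit + W/2)`, clipped at chromosome ends. Windows keep
#' their provenance (source sample, summit, height) for the redundancy
#' removal step.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param W Window width in bp; even and >= 2 (default 400).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Tibble with columns `chrom`, `start`, `end`, `sample_id`,
#'   `summit`, `height`.
#' @export
summit_windows <- function(peaks, W = 400, chrom_lengths) {
  assert_count(W, "W", min = 2)
  if (W %% 2 != 0) abort("`W` must be even.")
  len <- chrom_lengths[peaks$chrom]
  if (anyNA(len)) abort("Peaks reference chromosomes absent from `chrom_lengths`.")
  tibble(
    chrom = peaks$chrom,
    start = pmax(as.integer(peaks$summit - W %/% 2), 0L),
    end = pmin(as.integer(peaks$summit + W %/% 2), as.integer(len)),
    sample_id = peaks$sample_id %||% "sample",
    summit = as.integer(peaks$summit),
    height = as.integer(peaks$height)
  )
}

#' Build a non-redundant region atlas from per-sample candidate windows
#'
#' Combines the candidate windows of all samples into one genome-wide,
#' non-overlapping atlas by greedy height-ranked selection: windows are
#' sorted by decreasing source peak height (ties broken by chromosome,
#' start, then sample id) and accepted if they overlap no already-accepted
#' window by >= 1 bp. Every rejected window overlaps at least one accepted
#' one, so the atlas covers each candidate locus exactly once while keeping
#' the fixed width needed for unbiased motif counting.
#'
#' @param windows Window tibble from [summit_windows()], any number of
#'   samples bound together.
#' @param W Nominal region width (recorded as an attribute).
#' @return Tibble of class `region_atlas`, sorted by (`chrom`, `start`),
#'   with columns `region_id`, `chrom`, `start`, `end`, `source_sample`,
#'   `source_summit`, `source_height`.
#' @export
build_atlas <- function(windows, W = 400) {
  if (nrow(windows) == 0) {
    out <- tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  source_sample = character(), source_summit = integer(),
                  source_height = integer())
    return(structure(out, class = c("region_atlas", class(out)), width = W))
  }
  ord <- order(-windows$height, windows$chrom, windows$start,
               windows$sample_id)
  w <- windows[ord, ]
  accepted <- logical(nrow(w))
  occ <- split(seq_len(nrow(w)), w$chrom)
  acc_by_chrom <- lapply(occ, function(...) {
    list(start = integer(), end = integer())
  })
  for (i in seq_len(nrow(w))) {
    ch <- w$chrom[i]
    a <- acc_by_chrom[[ch]]
    if (!length(a$start) ||
        !any(w$start[i] < a$end & a$start < w$end[i])) {
      accepted[i] <- TRUE
      acc_by_chrom[[ch]]$start <- c(a$start, w$start[i])
      acc_by_chrom[[ch]]$end <- c(a$end, w$end[i])
    }
  }
  out <- w[accepted, ] %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::transmute(
      region_id = sprintf("R%06d", dplyr::row_number()),
      chrom = .data$chrom, start = .data$start, end = .data$end,
      source_sample = .data$sample_id,
      source_summit = .data$summit,
      source_height = .data$height)
  structure(out, class = c("region_atlas", class(out)), width = W)
}

#' Score atlas regions in every sample
#'
#' A region's raw score in a sample is the number of `L`-bp extended tags
#' whose interval overlaps the region (by >= 1 bp by default, or fully
#' contained with `mode = "within"`). Raw counts are normalized to the
#' sample's total tag count as reads per million (RPM).
#'
#' @param atlas A `region_atlas` tibble.
#' @param tags Tag tibble covering every sample to score.
#' @param L Extension length in bp (default 200).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param mode Overlap rule: `"overlap"` (>= 1 bp, default) or `"within"`
#'   (extended tag fully contained in the region).
#' @return Long tibble of class `region_scores` with columns `region_id`,
#'   `sample_id`, `raw`, `rpm`; library sizes in `attr(, "library_sizes")`.
#' @export
score_regions <- function(atlas, tags, L = 200, chrom_lengths,
                          mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  if (nrow(atlas) == 0) abort("`atlas` must contain at least one region.")
  if (!"sample_id" %in% names(tags)) tags$sample_id <- "sample"
  libs <- library_sizes(tags)
  if (any(libs < 1)) abort("Every sample must have library size >= 1.")
  reg_gr <- GenomicRanges::GRanges(
    atlas$chrom, IRanges::IRanges(atlas$start + 1L, atlas$end))
  ext <- extend_tags(tags, L, chrom_lengths)
  out <- lapply(names(libs), function(smp) {
    iv <- ext[ext$sample_id == smp, , drop = FALSE]
    tag_gr <- GenomicRanges::GRanges(
      iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
    raw <- if (mode == "overlap") {
      GenomicRanges::countOverlaps(reg_gr, tag_gr)
    } else {
      hits <- GenomicRanges::findOverlaps(tag_gr, reg_gr, type = "within")
      tabulate(S4Vectors::subjectHits(hits), nbins = length(reg_gr))
    }
    tibble(region_id = atlas$region_id, sample_id = smp,
           raw = as.integer(raw),
           rpm = as.integer(raw) / libs[[smp]] * 1e6)
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("region_scores", class(res)),
            library_sizes = libs)
}

#' Region scores as a matrix
#'
#' @param scores A `region_scores` tibble.
#' @param value `"rpm"` (default) or `"raw"`.
#' @return Numeric matrix, regions x samples.
#' @export
scores_matrix <- function(scores, value = c("rpm", "raw")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    as_tibble(scores)[, c("region_id", "sample_id", value)],
    names_from = "sample_id", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$region_id
  m
}

#' Write an atlas as BED
#'
#' @param atlas A `region_atlas` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas_bed <- function(atlas, path) {
  readr::write_tsv(
    tibble(chrom = atlas$chrom, start = atlas$start, end = atlas$end,
           name = atlas$region_id, score = atlas$source_height,
           strand = "."),
    path, col_names = FALSE)
  invisible(path)
}

#' Write a region score matrix as TSV
#'
#' One row per region, one column per sample.
#'
#' @param scores A `region_scores` tibble.
#' @param path Output path.
#' @param value `"rpm"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path, value = c("rpm", "raw")) {
  value <- match.arg(value)
  m <- scores_matrix(scores, value)
  readr::write_tsv(dplyr::bind_cols(tibble(region_id = rownames(m)),
                                    as_tibble(m)), path)
  invisible(path)
}
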