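# IUPAC degenerate nucleotide alphabet.
iupac_table <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Default consensus motif set
#'
#' IUPAC consensus stand-ins for six haematopoietic stem/progenitor-cell
#' transcription factors: Gata2, Gfi1, Lyl1 and Sfpi1/Pu.1 (differentially
#' expressed across the leukaemic partition) plus Cebpa and Meis1 as
#' expression-stable controls. These strings are editable placeholders in
#' the style of UniProbe/Jaspar consensus calls, not authoritative database
#' exports; replace them with curated motifs for real analyses.
#'
#' @return Tibble with columns `motif_id`, `iupac`.
#' @export
consensus_motifs <- function() {
  tibble(
    motif_id = c("Gata2", "Gfi1", "Lyl1", "Sfpi1", "Cebpa", "Meis1"),
    iupac = c("WGATAR", "AAATCACWGC", "CAGCTG", "RGAGGAAGTR",
              "TTGCGCAA", "TGACAG")
  )
}

validate_iupac <- function(iupac) {
  if (!nzchar(iupac)) abort("Motif must be non-empty.")
  letters <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(letters, names(iupac_table()))
  if (length(bad)) {
    abort(sprintf("Invalid IUPAC code(s): %s", paste(bad, collapse = ", ")))
  }
  paste(letters, collapse = "")
}

iupac_revcomp <- function(iupac) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
}

#' Count consensus motif occurrences in a sequence
#'
#' Counts positions where the IUPAC pattern matches the forward strand,
#' plus positions where its reverse complement matches the forward strand
#' (i.e. matches of the motif on the reverse strand). Overlapping matches
#' are all counted. A pattern equal to its own reverse complement
#' (palindromic consensus) is counted once per position.
#'
#' @param sequence Nucleotide string over A/C/G/T (or a
#'   [Biostrings::DNAString]).
#' @param iupac IUPAC consensus string.
#' @return Integer occurrence count (0 when the motif is longer than the
#'   sequence).
#' @export
scan_sequence <- function(sequence, iupac) {
  iupac <- validate_iupac(iupac)
  seq <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(sequence))
  if (nchar(iupac) > length(seq)) return(0L)
  fwd <- Biostrings::countPattern(iupac, seq, fixed = "subject")
  rc <- iupac_revcomp(iupac)
  if (rc == iupac) return(as.integer(fwd))
  as.integer(fwd + Biostrings::countPattern(rc, seq, fixed = "subject"))
}

# Per-region x per-motif occurrence count matrix for an atlas.
motif_count_matrix <- function(atlas, genome, motifs) {
  seqs <- region_sequences(genome, atlas)
  m <- vapply(seq_len(nrow(motifs)), function(j) {
    pat <- validate_iupac(motifs$iupac[j])
    cnt <- Biostrings::vcountPattern(pat, seqs, fixed = "subject")
    rc <- iupac_revcomp(pat)
    if (rc != pat) {
      cnt <- cnt + Biostrings::vcountPattern(rc, seqs, fixed = "subject")
    }
    as.integer(cnt)
  }, integer(length(seqs)))
  m <- matrix(m, nrow = length(seqs), ncol = nrow(motifs),
              dimnames = list(atlas$region_id, motifs$motif_id))
  m
}

#' Observed motif occurrences in a region set
#'
#' @param region_ids Regions of interest (subset of `atlas$region_id`).
#' @param atlas A `region_atlas` tibble.
#' @param genome A `genome_seq` tibble.
#' @param motifs Motif tibble (`motif_id`, `iupac`), default
#'   [consensus_motifs()].
#' @param count_mode `"occurrences"` (total match count, default) or
#'   `"regions"` (number of regions with >= 1 match).
#' @return Tibble with columns `motif_id`, `observed`.
#' @export
observed_counts <- function(region_ids, atlas, genome,
                            motifs = consensus_motifs(),
                            count_mode = c("occurrences", "regions")) {
  count_mode <- match.arg(count_mode)
  if (!all(region_ids %in% atlas$region_id)) {
    abort("`region_ids` must all be present in the atlas.")
  }
  sub <- atlas[match(region_ids, atlas$region_id), , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble(motif_id = motifs$motif_id, observed = 0L))
  }
  cm <- motif_count_matrix(sub, genome, motifs)
  if (count_mode == "regions") cm <- (cm > 0) + 0L
  tibble(motif_id = motifs$motif_id, observed = as.integer(colSums(cm)))
}

#' Bootstrap null distribution of motif occurrences
#'
#' Draws `B` random region sets of size `set_size` from the full atlas
#' (with replacement by default) and records total motif occurrences per
#' set, giving the expected occurrence distribution for a region set of
#' that size under no association with the atlas partition.
#'
#' @inheritParams observed_counts
#' @param set_size Regions per resample (the target set's cardinality).
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param replace Sample with replacement (default TRUE); `FALSE` gives a
#'   subsampling null instead.
#' @return Tibble with columns `motif_id`, `expected_mean`, `expected_sd`,
#'   `set_size`, `B` (SD uses denominator `B - 1`).
#' @export
bootstrap_null <- function(atlas, genome, motifs = consensus_motifs(),
                           set_size, B = 1000, seed = NULL, replace = TRUE,
                           count_mode = c("occurrences", "regions")) {
  count_mode <- match.arg(count_mode)
  if (nrow(atlas) == 0) abort("`atlas` must be non-empty.")
  assert_count(B, "B", min = 2)
  assert_count(set_size, "set_size", min = 1)
  if (!replace && set_size > nrow(atlas)) {
    abort("`set_size` exceeds atlas size for subsampling without replacement.")
  }
  cm <- motif_count_matrix(atlas, genome, motifs)
  if (count_mode == "regions") cm <- (cm > 0) + 0L
  totals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(cm), set_size, replace = replace)
      colSums(cm[idx, , drop = FALSE])
    }, numeric(ncol(cm)))
  })
  # vapply drops to a vector for a single motif; keep B x motifs shape
  totals <- if (is.null(dim(totals))) matrix(totals, ncol = 1) else t(totals)
  tibble(
    motif_id = motifs$motif_id,
    expected_mean = colMeans(totals),
    expected_sd = apply(totals, 2, sd),
    set_size = as.integer(set_size),
    B = as.integer(B)
  )
}

#' Z-scores and significance calls for motif representation
#'
#' `z = (observed - expected_mean) / expected_sd`; calls are `over` at
#' `z >= +z_threshold`, `under` at `z <= -z_threshold` (both inclusive),
#' otherwise `ns`. A degenerate null (`sd = 0`) yields `z = 0` when the
#' observation equals the mean and a signed infinite sentinel (flagged in
#' `degenerate`) otherwise.
#'
#' @param observed Tibble from [observed_counts()].
#' @param nulls Tibble from [bootstrap_null()] over the same motifs.
#' @param z_threshold Significance threshold on |z| (default 3).
#' @return Tibble of class `motif_enrichment_result` with columns
#'   `motif_id`, `observed`, `expected_mean`, `expected_sd`, `z`, `call`,
#'   `degenerate`.
#' @export
motif_z_scores <- function(observed, nulls, z_threshold = 3) {
  if (!setequal(observed$motif_id, nulls$motif_id)) {
    abort("`observed` and `nulls` must cover the same motifs.")
  }
  res <- dplyr::left_join(observed, nulls, by = "motif_id") %>%
    dplyr::mutate(
      degenerate = .data$expected_sd == 0,
      z = dplyr::case_when(
        .data$expected_sd > 0 ~
          (.data$observed - .data$expected_mean) / .data$expected_sd,
        .data$observed == .data$expected_mean ~ 0,
        .data$observed > .data$expected_mean ~ Inf,
        TRUE ~ -Inf),
      call = dplyr::case_when(
        .data$z >= z_threshold ~ "over",
        .data$z <= -z_threshold ~ "under",
        TRUE ~ "ns")
    ) %>%
    dplyr::select(dplyr::all_of(c("motif_id", "observed", "expected_mean",
                                  "expected_sd", "z", "call", "degenerate")))
  structure(res, class = c("motif_enrichment_result", class(res)),
            z_threshold = z_threshold)
}

#' Motif over/under-representation in a target region set
#'
#' Convenience wrapper: counts observed occurrences in the target set,
#' builds the bootstrap null from the full atlas at the target's
#' cardinality, and returns Z-scored calls.
#'
#' @inheritParams observed_counts
#' @inheritParams bootstrap_null
#' @inheritParams motif_z_scores
#' @return A `motif_enrichment_result` tibble (see [motif_z_scores()]).
#' @examples
#' \dontrun{
#' enr <- motif_enrichment(deprived_ids, atlas, genome, seed = 1)
#' }
#' @export
motif_enrichment <- function(region_ids, atlas, genome,
                             motifs = consensus_motifs(), B = 1000,
                             seed = NULL, z_threshold = 3, replace = TRUE,
                             count_mode = c("occurrences", "regions")) {
  count_mode <- match.arg(count_mode)
  obs <- observed_counts(region_ids, atlas, genome, motifs, count_mode)
  nulls <- bootstrap_null(atlas, genome, motifs,
                          set_size = length(region_ids), B = B, seed = seed,
                          replace = replace, count_mode = count_mode)
  motif_z_scores(obs, nulls, z_threshold)
}
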