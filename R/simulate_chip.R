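#' Plant candidate regulatory regions (and their motifs) into a genome
#'
#' Chooses `n_regions` non-overlapping fixed-width intervals, marks a fraction
#' of them with a group-B acetylation effect, and writes concrete motif
#' instances into the genome sequence at recorded positions. Regions with a
#' group effect below 1 model "deprived" regions (acetylation lost in the
#' leukaemic group); motifs can be planted at a higher per-region rate in
#' those regions, which is the signal the bootstrap Z-score is designed to
#' detect.
#'
#' @param genome A `genome_seq` tibble; modified copy is returned.
#' @param n_regions Number of regions to place.
#' @param width Region width in bp (> 0).
#' @param motif_spec `NULL`, or a data frame with columns `motif_id`, `iupac`,
#'   `rate_deprived`, `rate_other`: mean number of planted instances per
#'   region, in regions with `group_effect < 1` versus all other regions.
#'   Non-integer rates are realized as floor + Bernoulli(fractional part).
#' @param fraction_group_effect Fraction of regions that carry the group
#'   effect (rounded to the nearest count).
#' @param effect_fold Multiplicative fold applied to the enrichment of
#'   affected regions in group-B samples; < 1 models deprived regions,
#'   > 1 enriched ones. Must be > 0.
#' @param base_enrichment Tag-density fold of a region over background in
#'   unaffected samples (>= 1).
#' @param seed Integer seed.
#' @param max_tries Placement retries before giving up.
#'
#' @return List with elements `genome` (motifs written in), `regions`
#'   (tibble: `region_label`, `chrom`, `start`, `end`, `center`, `width`,
#'   `base_enrichment`, `group_effect`) and `motif_placements` (tibble:
#'   `region_label`, `motif_id`, `chrom`, `start`, `instance`).
#' @export
plant_regions <- function(genome, n_regions, width = 400, motif_spec = NULL,
                          fraction_group_effect = 0, effect_fold = 1,
                          base_enrichment = 10, seed = NULL,
                          max_tries = 200L * max(1L, n_regions)) {
  assert_count(n_regions, "n_regions", min = 0)
  assert_count(width, "width", min = 1)
  if (!is.numeric(effect_fold) || effect_fold <= 0) {
    abort("`effect_fold` must be > 0.")
  }
  if (base_enrichment < 1) abort("`base_enrichment` must be >= 1.")
  assert_fraction(fraction_group_effect, "fraction_group_effect", open = FALSE)
  empty_regions <- tibble(
    region_label = character(), chrom = character(), start = integer(),
    end = integer(), center = integer(), width = integer(),
    base_enrichment = numeric(), group_effect = numeric())
  empty_motifs <- tibble(region_label = character(), motif_id = character(),
                         chrom = character(), start = integer(),
                         instance = character())
  if (n_regions == 0) {
    return(list(genome = genome, regions = empty_regions,
                motif_placements = empty_motifs))
  }
  lens <- genome_lengths(genome)
  if (all(lens < width)) abort("placement-failure: regions wider than genome.")

  with_seed(seed, {
    # rejection-sample non-overlapping placements, bounded retries
    placed <- vector("list", n_regions)
    occupied <- lapply(lens, function(...) cbind(start = integer(), end = integer()))
    k <- 0L; tries <- 0L
    while (k < n_regions && tries < max_tries) {
      tries <- tries + 1L
      ci <- sample(length(lens), 1L, prob = as.numeric(lens))
      if (lens[ci] < width) next
      s <- sample.int(lens[ci] - width + 1L, 1L) - 1L
      e <- s + width
      occ <- occupied[[ci]]
      if (nrow(occ) && any(s < occ[, "end"] & occ[, "start"] < e)) next
      k <- k + 1L
      occupied[[ci]] <- rbind(occ, cbind(start = s, end = e))
      placed[[k]] <- tibble(chrom = names(lens)[ci], start = s, end = e)
    }
    if (k < n_regions) {
      abort("placement-failure: could not place all regions without overlap.")
    }
    regions <- dplyr::bind_rows(placed) %>%
      dplyr::arrange(.data$chrom, .data$start) %>%
      dplyr::mutate(
        region_label = sprintf("planted_%03d", dplyr::row_number()),
        center = .data$start + as.integer(width %/% 2),
        width = as.integer(width),
        base_enrichment = base_enrichment,
        group_effect = 1
      ) %>%
      dplyr::select(dplyr::all_of(names(empty_regions)))
    n_eff <- round(fraction_group_effect * n_regions)
    if (n_eff > 0) {
      idx <- sample.int(n_regions, n_eff)
      regions$group_effect[idx] <- effect_fold
    }

    placements <- empty_motifs
    if (!is.null(motif_spec) && nrow(motif_spec) > 0) {
      seqs <- setNames(genome$sequence, genome$chrom)
      rows <- list()
      for (r in seq_len(nrow(regions))) {
        deprived <- regions$group_effect[r] < 1
        # motif instances within one region must not overwrite one another
        taken <- cbind(start = integer(), end = integer())
        for (m in seq_len(nrow(motif_spec))) {
          rate <- if (deprived) motif_spec$rate_deprived[m] else motif_spec$rate_other[m]
          n_inst <- floor(rate) + rbinom(1L, 1L, rate - floor(rate))
          if (n_inst == 0) next
          mw <- nchar(motif_spec$iupac[m])
          for (j in seq_len(n_inst)) {
            for (try in 1:100) {
              pos <- regions$start[r] +
                sample.int(regions$width[r] - mw + 1L, 1L) - 1L
              if (!nrow(taken) ||
                  !any(pos < taken[, "end"] & taken[, "start"] < pos + mw)) break
              pos <- NA_integer_
            }
            if (is.na(pos)) next
            taken <- rbind(taken, cbind(start = pos, end = pos + mw))
            inst <- realize_iupac(motif_spec$iupac[m])
            ch <- regions$chrom[r]
            substr(seqs[[ch]], pos + 1L, pos + mw) <- inst
            rows[[length(rows) + 1L]] <- tibble(
              region_label = regions$region_label[r],
              motif_id = motif_spec$motif_id[m],
              chrom = ch, start = pos, instance = inst)
          }
        }
      }
      if (length(rows)) placements <- dplyr::bind_rows(rows)
      genome$sequence <- unname(seqs[genome$chrom])
      genome <- new_genome(genome)
    }
    list(genome = genome, regions = regions, motif_placements = placements)
  })
}

# Sample a concrete A/C/G/T instance of an IUPAC consensus string.
realize_iupac <- function(iupac) {
  letters <- strsplit(toupper(iupac), "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- iupac_table()[[l]]
    if (is.null(opts)) abort(sprintf("Invalid IUPAC code '%s'.", l))
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Simulate ChIP-seq tag sets for every sample of a design
#'
#' Draws `depth` sequenced-fragment 5' ends per sample: a uniform background
#' plus enriched tags whose fragment midpoints are Gaussian around planted
#' region centers. Forward-strand tags sit upstream of the midpoint and
#' reverse-strand tags downstream, offset by half the fragment length, which
#' reproduces the strand asymmetry that in-silico 200 bp extension corrects.
#' The enrichment rate of a region is `base_enrichment`, multiplied by its
#' `group_effect` for samples whose condition is in group B.
#'
#' @param genome A `genome_seq` tibble.
#' @param regions Planted-region tibble from [plant_regions()] (may be empty).
#' @param design A [sample_design()].
#' @param depth Tags per sample; every returned sample has exactly this many.
#' @param fragment_len Modelled fragment length in bp (default 200).
#' @param seed Master seed; per-sample streams are derived deterministically.
#'
#' @return Tibble of tags with columns `sample_id`, `condition`, `replicate`,
#'   `group`, `chrom`, `pos` (0-based 5' end), `strand` ("+"/"-").
#' @export
simulate_chip_tags <- function(genome, regions, design, depth = 1e5,
                               fragment_len = 200, seed = NULL) {
  assert_count(depth, "depth", min = 1)
  lens <- genome_lengths(genome)
  total_len <- sum(as.numeric(lens))
  samples <- chip_samples(design)
  has_regions <- !is.null(regions) && nrow(regions) > 0

  out <- lapply(seq_len(nrow(samples)), function(i) {
    smp <- samples[i, ]
    with_seed(derive_seed(seed, i), {
      if (has_regions) {
        eff <- regions$base_enrichment *
          (if (smp$group == "B") regions$group_effect else rep(1, nrow(regions)))
        extra_w <- pmax(0, eff - 1) * regions$width
      } else {
        extra_w <- numeric(0)
      }
      counts <- as.vector(rmultinom(1L, depth, c(total_len, extra_w)))
      n_bg <- counts[1]
      # background: uniform 5' ends, random strand
      ci <- sample(length(lens), n_bg, replace = TRUE, prob = as.numeric(lens))
      bg <- tibble(
        chrom = names(lens)[ci],
        pos = as.integer(floor(runif(n_bg) * lens[ci])),
        strand = sample(c("+", "-"), n_bg, replace = TRUE)
      )
      parts <- list(bg)
      if (has_regions) {
        for (r in which(counts[-1] > 0)) {
          n_r <- counts[r + 1L]
          mid <- round(rnorm(n_r, regions$center[r], regions$width[r] / 4))
          strand <- sample(c("+", "-"), n_r, replace = TRUE)
          off <- as.integer(round(fragment_len / 2))
          pos <- ifelse(strand == "+", mid - off, mid + off - 1L)
          pos <- pmin(pmax(as.integer(pos), 0L),
                      lens[[regions$chrom[r]]] - 1L)
          parts[[length(parts) + 1L]] <- tibble(
            chrom = regions$chrom[r], pos = pos, strand = strand)
        }
      }
      dplyr::bind_rows(parts) %>%
        dplyr::mutate(sample_id = smp$sample_id, condition = smp$condition,
                      replicate = smp$replicate, group = smp$group,
                      .before = 1)
    })
  })
  dplyr::bind_rows(out)
}

#' Write / read tags as BED6
#'
#' Tags are exchanged as 6-column BED (chrom, pos, pos+1, sample_id, 0,
#' strand), 0-based half-open; the single-base interval marks the 5' end.
#'
#' @param tags Tag tibble as returned by [simulate_chip_tags()].
#' @param path File path.
#' @return `write_tags_bed()` returns `path` invisibly; `read_tags_bed()` a
#'   tag tibble with columns `sample_id`, `chrom`, `pos`, `strand`.
#' @export
write_tags_bed <- function(tags, path) {
  readr::write_tsv(
    tibble(chrom = tags$chrom, start = tags$pos, end = tags$pos + 1L,
           name = tags$sample_id, score = 0L, strand = tags$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_tags_bed
#' @export
read_tags_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  tibble(sample_id = bed$name, chrom = bed$chrom,
         pos = as.integer(bed$start), strand = bed$strand)
}

#' Library sizes of a tag table
#'
#' @param tags Tag tibble with a `sample_id` column.
#' @return Named integer vector of tag counts per sample.
#' @export
library_sizes <- function(tags) {
  tab <- table(tags$sample_id)
  setNames(as.integer(tab), names(tab))
}
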