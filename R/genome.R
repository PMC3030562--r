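#' Simulate a genome sequence
#'
#' Generates a synthetic genome of one or more chromosomes with i.i.d. bases
#' at a chosen GC content. The result stands in for a reference assembly: it
#' carries the chromosome lengths used by the Poisson peak null and the
#' nucleotide sequence scanned for consensus motifs.
#'
#' @param n_chroms Number of chromosomes.
#' @param length_per_chrom Length of each chromosome in bp (>= 10000).
#' @param gc_fraction Target GC content, strictly between 0 and 1.
#'   Per base, P(G) + P(C) = `gc_fraction`, split equally.
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#'
#' @return A tibble of class `genome_seq` with columns `chrom`, `length`,
#'   `sequence` (uppercase A/C/G/T).
#' @examples
#' g <- generate_genome(1, 10000, 0.42, seed = 1)
#' genome_lengths(g)
#' @export
generate_genome <- function(n_chroms, length_per_chrom, gc_fraction,
                            seed = NULL) {
  assert_count(n_chroms, "n_chroms", min = 1)
  if (!is.numeric(length_per_chrom) || length_per_chrom < 10000) {
    abort("`length_per_chrom` must be a positive length >= 10000 bp.")
  }
  assert_fraction(gc_fraction, "gc_fraction")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  len <- as.integer(length_per_chrom)
  g <- with_seed(seed, {
    tibble(
      chrom = sprintf("chr%d", seq_len(n_chroms)),
      length = len,
      sequence = vapply(seq_len(n_chroms), function(i) {
        paste(sample(names(probs), len, replace = TRUE, prob = probs),
              collapse = "")
      }, character(1))
    )
  })
  new_genome(g)
}

new_genome <- function(df) {
  stopifnot(all(c("chrom", "length", "sequence") %in% names(df)))
  if (!all(nchar(df$sequence) == df$length)) {
    abort("Genome invariant violated: `length` must equal nchar(sequence).")
  }
  structure(as_tibble(df), class = c("genome_seq", class(as_tibble(df))))
}

#' Chromosome lengths of a genome
#'
#' @param genome A `genome_seq` tibble.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  setNames(as.integer(genome$length), genome$chrom)
}

#' Extract region sequences from a genome
#'
#' Pulls the genomic sequence under each interval of a region table
#' (0-based half-open coordinates, BED convention).
#'
#' @param genome A `genome_seq` tibble.
#' @param regions Data frame with columns `chrom`, `start`, `end`.
#' @return A [Biostrings::DNAStringSet] named by `region_id` when present.
#' @export
region_sequences <- function(genome, regions) {
  seqs <- setNames(genome$sequence, genome$chrom)
  missing <- setdiff(unique(regions$chrom), names(seqs))
  if (length(missing)) {
    abort(paste0("Regions reference unknown chromosomes: ",
                 paste(missing, collapse = ", ")))
  }
  lens <- genome_lengths(genome)
  if (any(regions$start < 0 | regions$end > lens[regions$chrom])) {
    abort("Region outside genome bounds.")
  }
  out <- substring(seqs[regions$chrom], regions$start + 1L, regions$end)
  names(out) <- if ("region_id" %in% names(regions)) regions$region_id else
    sprintf("region_%d", seq_len(nrow(regions)))
  Biostrings::DNAStringSet(out)
}

#' Write / read a genome as FASTA
#'
#' @param genome A `genome_seq` tibble.
#' @param path Output FASTA path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a `genome_seq` tibble.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genome$sequence, genome$chrom)), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  new_genome(tibble(
    chrom = names(ss),
    length = Biostrings::width(ss),
    sequence = unname(as.character(ss))
  ))
}
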