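#' Tidy a differential-acetylation fit
#'
#' @param x A `diffac` object from [diff_acetylation()].
#' @param ... Unused.
#' @return The per-region result tibble (`region_id`, `mean_A`, `mean_B`,
#'   `t`, `p_raw`, `p`, `class`).
#' @method tidy diffac
#' @export
tidy.diffac <- function(x, ...) {
  x$table
}

#' One-row summary of a differential-acetylation fit
#'
#' @param x A `diffac` object.
#' @param ... Unused.
#' @return Tibble with region counts per class and the test settings.
#' @method glance diffac
#' @export
glance.diffac <- function(x, ...) {
  cnt <- table(factor(x$table$class,
                      levels = c("stable", "enriched", "deprived")))
  tibble(
    n_regions = nrow(x$table),
    n_stable = as.integer(cnt[["stable"]]),
    n_enriched = as.integer(cnt[["enriched"]]),
    n_deprived = as.integer(cnt[["deprived"]]),
    p_threshold = x$params$p_threshold,
    prior_df = x$params$prior_df,
    df = x$params$df,
    nA = x$params$nA,
    nB = x$params$nB
  )
}

#' Tidy a motif enrichment result
#'
#' @param x A `motif_enrichment_result` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-motif rows.
#' @method tidy motif_enrichment_result
#' @export
tidy.motif_enrichment_result <- function(x, ...) {
  structure(x, class = setdiff(class(x), "motif_enrichment_result"),
            z_threshold = NULL)
}

#' One-row summary of a motif enrichment result
#'
#' @param x A `motif_enrichment_result` tibble.
#' @param ... Unused.
#' @return Tibble with motif counts per call at the Z threshold used.
#' @method glance motif_enrichment_result
#' @export
glance.motif_enrichment_result <- function(x, ...) {
  tibble(
    n_motifs = nrow(x),
    n_over = sum(x$call == "over"),
    n_under = sum(x$call == "under"),
    n_ns = sum(x$call == "ns"),
    z_threshold = attr(x, "z_threshold") %||% 3
  )
}
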