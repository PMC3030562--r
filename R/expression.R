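#' Detection filter: probes expressed in at least one sample
#'
#' A probe is retained when it is detected in at least one sample. By the
#' platform's printed convention a cell counts as detected when its
#' detection score exceeds `threshold` (`direction = "greater"`, default);
#' chips whose detection p-values are small-when-detected are handled with
#' `direction = "less"`.
#'
#' @param detection Tibble with a `probe_id` column and one numeric column
#'   per sample (detection scores in `[0,1]`).
#' @param threshold Detection threshold (default 0.01).
#' @param direction `"greater"` (detected iff score > threshold, default)
#'   or `"less"` (detected iff score < threshold).
#' @return Tibble with columns `probe_id`, `n_detected`, `expressed`.
#' @export
detection_filter <- function(detection, threshold = 0.01,
                             direction = c("greater", "less")) {
  direction <- match.arg(direction)
  m <- as.matrix(detection[, setdiff(names(detection), "probe_id")])
  det <- if (direction == "greater") m > threshold else m < threshold
  tibble(
    probe_id = detection$probe_id,
    n_detected = as.integer(rowSums(det)),
    expressed = rowSums(det) >= 1
  )
}

#' Moderated differential expression for one transition
#'
#' Tests every (detection-filtered) probe for differential expression
#' between the two conditions of a transition with the shared
#' Bayesian-regularized t-statistic, applies Benjamini-Hochberg adjustment
#' across all tested probes, and calls probes at `adjusted p <= fdr_threshold`
#' (`up` when the log fold change `to - from` is positive).
#'
#' @param exprs Tibble with `probe_id` plus one column per sample
#'   (log-scale intensities).
#' @param samples Sample sheet tibble (`sample_id`, `condition`).
#' @param comparison One-row transition (list or tibble row with `name`,
#'   `from`, `to`).
#' @param fdr_threshold FDR threshold for calls (default 0.001).
#' @param probes Optional probe ids to test (e.g. the expressed set from
#'   [detection_filter()]); default all.
#' @param prior_df,w Regularized-t settings (defaults 10 and 101).
#' @return Tibble with columns `probe_id`, `transition`, `mean_from`,
#'   `mean_to`, `log_fc`, `t`, `p`, `adj_p`, `call`.
#' @export
moderated_de <- function(exprs, samples, comparison, fdr_threshold = 0.001,
                         probes = NULL, prior_df = 10, w = 101) {
  comparison <- as.list(comparison)
  for (side in c("from", "to")) {
    if (!comparison[[side]] %in% samples$condition) {
      abort(sprintf("Condition '%s' not present in `samples`.",
                    comparison[[side]]))
    }
  }
  if (!is.null(probes)) {
    exprs <- exprs[exprs$probe_id %in% probes, , drop = FALSE]
  }
  cols_from <- samples$sample_id[samples$condition == comparison$from]
  cols_to <- samples$sample_id[samples$condition == comparison$to]
  if (length(cols_from) < 2 || length(cols_to) < 2) {
    abort("insufficient-replicates: need >= 2 replicates per condition.")
  }
  A <- as.matrix(exprs[, cols_from])
  B <- as.matrix(exprs[, cols_to])
  res <- regularized_t(A, B, prior_df = prior_df, w = w)
  adj <- p.adjust(res$p, "BH")
  tibble(
    probe_id = exprs$probe_id,
    transition = comparison$name %||% paste0(comparison$from, "_",
                                             comparison$to),
    mean_from = res$mean_A,
    mean_to = res$mean_B,
    log_fc = res$mean_B - res$mean_A,
    t = res$t,
    p = res$p,
    adj_p = adj,
    call = dplyr::case_when(
      adj > fdr_threshold ~ "ns",
      res$mean_B - res$mean_A > 0 ~ "up",
      TRUE ~ "down")
  )
}

#' Run moderated DE for every transition of a table
#'
#' @inheritParams moderated_de
#' @param transitions Transition tibble (`name`, `from`, `to`).
#' @return One combined tibble of per-transition results.
#' @export
transitions_de <- function(exprs, samples, transitions = default_transitions(),
                           fdr_threshold = 0.001, probes = NULL,
                           prior_df = 10, w = 101) {
  dplyr::bind_rows(lapply(seq_len(nrow(transitions)), function(i) {
    moderated_de(exprs, samples, transitions[i, ], fdr_threshold,
                 probes, prior_df, w)
  }))
}

#' Non-redundant differentially expressed probes
#'
#' Union of the probes called in at least one of the supplied transitions
#' (e.g. both transitions of one oncogene model), each probe annotated
#' with its per-transition direction calls.
#'
#' @param de Combined DE tibble (from [transitions_de()] or
#'   `bind_rows()` of [moderated_de()] results).
#' @return Tibble with columns `probe_id`, `n_transitions`, `calls`
#'   (semicolon-joined `transition:direction` pairs).
#' @export
nonredundant_de <- function(de) {
  de %>%
    dplyr::filter(.data$call != "ns") %>%
    dplyr::group_by(.data$probe_id) %>%
    dplyr::summarise(
      n_transitions = dplyr::n(),
      calls = paste(sprintf("%s:%s", .data$transition, .data$call),
                    collapse = ";"),
      .groups = "drop") %>%
    dplyr::arrange(.data$probe_id)
}

#' Shared progression gene sets across two oncogene models
#'
#' Direction-matched intersection of two DE lists computed under the same
#' orientation convention: probes called `up` in both lists form the
#' shared-up set and probes called `down` in both form the shared-down
#' set; discordant probes are excluded. Used with the MLL-ENL
#' baseline-to-initiation arm and the MOZ-TIF2 initiation-to-progression
#' arm, this defines the convergent leukaemic program.
#'
#' @param de_a,de_b DE tibbles with `probe_id` and `call` columns.
#' @return Tibble with columns `probe_id`, `direction` ("up"/"down"),
#'   sorted by direction then probe.
#' @export
shared_progression_sets <- function(de_a, de_b) {
  up <- intersect(de_a$probe_id[de_a$call == "up"],
                  de_b$probe_id[de_b$call == "up"])
  down <- intersect(de_a$probe_id[de_a$call == "down"],
                    de_b$probe_id[de_b$call == "down"])
  tibble(
    probe_id = c(sort(up), sort(down)),
    direction = rep(c("up", "down"), c(length(up), length(down)))
  )
}

#' Collapse probe-level sets to genes
#'
#' Optional probe-to-gene collapsing for shared sets; with no mapping,
#' results stay at probe level.
#'
#' @param probe_set Tibble with `probe_id` (and optionally `direction`).
#' @param probe_to_gene Tibble with columns `probe_id`, `gene`.
#' @return Tibble with one row per (gene, direction).
#' @export
collapse_to_genes <- function(probe_set, probe_to_gene) {
  probe_set %>%
    dplyr::inner_join(probe_to_gene, by = "probe_id") %>%
    dplyr::distinct(dplyr::across(dplyr::any_of(c("gene", "direction")))) %>%
    dplyr::arrange(.data$gene)
}
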