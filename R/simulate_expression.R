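#' Default pairwise transitions of the progression time course
#'
#' Six representative pairwise comparisons across the two oncogene models:
#' the two baselines against each other, baseline-to-initiation and
#' initiation-to-progression for each model, and the two overt leukaemias
#' against each other. Log fold changes are oriented `to - from`.
#'
#' @return Tibble with columns `name`, `from`, `to`.
#' @export
default_transitions <- function() {
  tibble(
    name = c("WT_FDCP", "ME_init", "ME_prog", "MT_init", "MT_prog", "MEL_MTL"),
    from = c("WT", "FDCP", "ME-I", "FDCP", "MT-I", "ME-L"),
    to   = c("FDCP", "ME-I", "ME-L", "MT-I", "MT-L", "MT-L")
  )
}

#' Transitions belonging to one oncogene model
#'
#' @param model `"ME"` (MLL-ENL) or `"MT"` (MOZ-TIF2).
#' @return Tibble of transitions (baseline-to-initiation,
#'   initiation-to-progression) for that model.
#' @export
model_transitions <- function(model = c("ME", "MT")) {
  model <- match.arg(model)
  tr <- default_transitions()
  tr[tr$name %in% paste0(model, c("_init", "_prog")), ]
}

#' Simulate an expression matrix with planted differential expression
#'
#' Generates log-scale intensities for every condition/replicate of the
#' design: per-probe baseline ~ N(`baseline_mean`, `baseline_sd`), plus
#' planted condition shifts, plus replicate noise ~ N(0, `noise_sd`).
#' For each transition, `n_de_per_transition` probes get a +/-`log_fc` shift
#' of the transition's `to` condition (half up, half down). Optionally,
#' shared-progression probes are planted with the same-direction shift in
#' both the MLL-ENL baseline-to-initiation transition (`ME-I`) and the
#' MOZ-TIF2 initiation-to-progression transition (`MT-L`), modelling the
#' convergent leukaemic program the intersection analysis looks for.
#' A fraction `1 - detection_fraction` of probes is undetected in all
#' samples (low detection score everywhere).
#'
#' Ground-truth DE labels are derived from the planted condition-mean matrix
#' per transition (up / down / null), so they stay correct even where planted
#' shifts spill into overlapping comparisons.
#'
#' @param design A [sample_design()].
#' @param n_probes Number of probes.
#' @param n_de_per_transition DE probes planted per transition.
#' @param log_fc Planted log fold change for per-transition DE probes.
#' @param noise_sd Replicate noise SD on the log scale.
#' @param detection_fraction Fraction of probes detectable at all (default
#'   0.458, the proportion observed on the array platform being emulated).
#' @param transitions Transition table (default [default_transitions()]).
#' @param n_shared_up,n_shared_down Shared-progression probes planted up/down
#'   in both intersection arms.
#' @param shared_log_fc Planted log fold change for shared probes.
#' @param baseline_mean,baseline_sd Probe baseline intensity distribution.
#' @param seed Integer seed.
#'
#' @return List of class `expression_sim`: `exprs` (tibble, `probe_id` +
#'   one column per sample), `detection` (same shape, scores in `[0,1]`;
#'   detected cells score high), `samples` (sample sheet), and `truth`
#'   (list: `labels` — tibble `probe_id` x `transition` x `label`;
#'   `shared_up`, `shared_down` — planted probe ids; `delta` — condition
#'   shift matrix; `seed`).
#' @export
simulate_expression <- function(design, n_probes = 20000,
                                n_de_per_transition = 400,
                                log_fc = 2, noise_sd = 0.5,
                                detection_fraction = 0.458,
                                transitions = default_transitions(),
                                n_shared_up = 0, n_shared_down = 0,
                                shared_log_fc = 3,
                                baseline_mean = 8, baseline_sd = 1.5,
                                seed = NULL) {
  assert_count(n_probes, "n_probes", min = 1)
  assert_count(n_de_per_transition, "n_de_per_transition", min = 0)
  if (n_de_per_transition > n_probes) {
    abort("`n_de_per_transition` must be <= `n_probes`.")
  }
  assert_fraction(detection_fraction, "detection_fraction", open = FALSE)
  conds <- design$conditions
  stopifnot(all(transitions$from %in% conds), all(transitions$to %in% conds))
  samples <- expression_samples(design)
  probe_ids <- sprintf("P%06d", seq_len(n_probes))

  with_seed(seed, {
    delta <- matrix(0, n_probes, length(conds),
                    dimnames = list(probe_ids, conds))
    pool <- seq_len(n_probes)
    take <- function(n) {
      idx <- sort(sample(pool, n))
      pool <<- setdiff(pool, idx)
      idx
    }
    shared_up <- shared_down <- integer(0)
    if (n_shared_up > 0) {
      shared_up <- take(n_shared_up)
      delta[shared_up, "ME-I"] <- delta[shared_up, "ME-I"] + shared_log_fc
      delta[shared_up, "MT-L"] <- delta[shared_up, "MT-L"] + shared_log_fc
    }
    if (n_shared_down > 0) {
      shared_down <- take(n_shared_down)
      delta[shared_down, "ME-I"] <- delta[shared_down, "ME-I"] - shared_log_fc
      delta[shared_down, "MT-L"] <- delta[shared_down, "MT-L"] - shared_log_fc
    }
    if (n_de_per_transition > 0) {
      for (t in seq_len(nrow(transitions))) {
        idx <- take(min(n_de_per_transition, length(pool)))
        half <- length(idx) %/% 2
        sign_vec <- rep(c(1, -1), c(half, length(idx) - half))
        delta[idx, transitions$to[t]] <-
          delta[idx, transitions$to[t]] + sign_vec * log_fc
      }
    }

    mu <- rnorm(n_probes, baseline_mean, baseline_sd)
    expr_mat <- matrix(0, n_probes, nrow(samples),
                       dimnames = list(probe_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      expr_mat[, j] <- mu + delta[, samples$condition[j]] +
        rnorm(n_probes, 0, noise_sd)
    }

    # undetected probes carry no planted effect: a truly differential probe
    # is expressed, hence detected in at least one sample
    n_undet <- min(floor((1 - detection_fraction) * n_probes), length(pool))
    undetected <- sample(pool, n_undet)
    det_mat <- matrix(runif(n_probes * nrow(samples), 0.02, 1),
                      n_probes, nrow(samples),
                      dimnames = dimnames(expr_mat))
    det_mat[undetected, ] <- runif(n_undet * nrow(samples), 0, 0.005)

    labels <- dplyr::bind_rows(lapply(seq_len(nrow(transitions)), function(t) {
      d <- delta[, transitions$to[t]] - delta[, transitions$from[t]]
      tibble(probe_id = probe_ids, transition = transitions$name[t],
             label = dplyr::case_when(d > 0 ~ "up", d < 0 ~ "down",
                                      TRUE ~ "null"))
    }))

    structure(list(
      exprs = dplyr::bind_cols(tibble(probe_id = probe_ids),
                               as_tibble(expr_mat)),
      detection = dplyr::bind_cols(tibble(probe_id = probe_ids),
                                   as_tibble(det_mat)),
      samples = samples,
      truth = list(labels = labels,
                   shared_up = probe_ids[shared_up],
                   shared_down = probe_ids[shared_down],
                   undetected = probe_ids[undetected],
                   delta = delta,
                   seed = seed)
    ), class = "expression_sim")
  })
}
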