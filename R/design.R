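#' Describe the sample design of a progression experiment
#'
#' Encodes the six-condition leukaemia progression layout used throughout the
#' package: two baselines (primary lin-/kit+ marrow `WT`, the FDCP-mix line
#' `FDCP`), two initiation stages (`ME-I`, `MT-I` for the MLL-ENL and MOZ-TIF2
#' oncogene models) and two overt-leukaemia stages (`ME-L`, `MT-L`). For group
#' comparisons the conditions are partitioned into a non-leukaemic group A
#' (WT, FDCP, MT-I) and a leukaemic group B (ME-I, ME-L, MT-L), following the
#' clustering of the expression profiles.
#'
#' @param conditions Character vector of condition names.
#' @param chip_replicates Biological ChIP replicates per condition (default 2).
#' @param expr_replicates Expression replicates per condition (default 3).
#' @param group_b Conditions forming group B (the leukaemic side); all other
#'   conditions form group A. Must be a non-empty proper subset.
#'
#' @return A list of class `sample_design` with elements `conditions`,
#'   `chip_replicates`, `expr_replicates` and `groups` (named character
#'   vector, condition -> "A"/"B").
#' @examples
#' d <- sample_design()
#' chip_samples(d)
#' @export
sample_design <- function(conditions = c("WT", "FDCP", "MT-I", "ME-I", "ME-L", "MT-L"),
                          chip_replicates = 2,
                          expr_replicates = 3,
                          group_b = c("ME-I", "ME-L", "MT-L")) {
  if (anyDuplicated(conditions)) abort("`conditions` must be unique.")
  assert_count(chip_replicates, "chip_replicates", min = 1)
  assert_count(expr_replicates, "expr_replicates", min = 1)
  if (!all(group_b %in% conditions)) {
    abort("`group_b` must be a subset of `conditions`.")
  }
  if (length(group_b) == 0 || length(group_b) == length(conditions)) {
    abort("`group_b` must be a non-empty proper subset of `conditions`.")
  }
  groups <- setNames(ifelse(conditions %in% group_b, "B", "A"), conditions)
  structure(
    list(conditions = conditions,
         chip_replicates = as.integer(chip_replicates),
         expr_replicates = as.integer(expr_replicates),
         groups = groups),
    class = "sample_design"
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat("<sample_design> ", length(x$conditions), " conditions; ",
      x$chip_replicates, " ChIP / ", x$expr_replicates,
      " expression replicates\n", sep = "")
  cat("  group A:", paste(names(x$groups)[x$groups == "A"], collapse = ", "), "\n")
  cat("  group B:", paste(names(x$groups)[x$groups == "B"], collapse = ", "), "\n")
  invisible(x)
}

#' Sample sheets for a design
#'
#' `chip_samples()` enumerates the ChIP samples (condition x replicate) and
#' `expression_samples()` the expression samples, with their group labels.
#'
#' @param design A [sample_design()].
#' @return Tibble with columns `sample_id`, `condition`, `replicate`, `group`.
#' @export
chip_samples <- function(design) {
  sheet <- expand.grid(replicate = seq_len(design$chip_replicates),
                       condition = design$conditions,
                       stringsAsFactors = FALSE)
  tibble(
    sample_id = sprintf("%s_R%d", sheet$condition, sheet$replicate),
    condition = sheet$condition,
    replicate = as.integer(sheet$replicate),
    group = unname(design$groups[sheet$condition])
  )
}

#' @rdname chip_samples
#' @export
expression_samples <- function(design) {
  sheet <- expand.grid(replicate = seq_len(design$expr_replicates),
                       condition = design$conditions,
                       stringsAsFactors = FALSE)
  tibble(
    sample_id = sprintf("%s_E%d", sheet$condition, sheet$replicate),
    condition = sheet$condition,
    replicate = as.integer(sheet$replicate),
    group = unname(design$groups[sheet$condition])
  )
}

#' Group assignment of ChIP samples
#'
#' @param design A [sample_design()].
#' @return Named character vector sample_id -> "A"/"B".
#' @export
chip_groups <- function(design) {
  s <- chip_samples(design)
  setNames(s$group, s$sample_id)
}
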