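#' Windowed background variance for variance shrinkage
#'
#' Implements the local background-variance estimate used by the
#' Bayesian-regularized t-test: features (regions or probes) are ranked by
#' their within-group mean, and each feature's background variance is the
#' average of the ordinary sample variances of the `w` rank-nearest
#' features (window truncated at the rank edges). Pooling information from
#' features of similar intensity stabilizes variance estimates when only
#' two or three replicates are available.
#'
#' @param mat Numeric matrix, features x replicates (one group), >= 2
#'   replicates.
#' @param w Window size; odd and >= 3 (truncated at edges; values larger
#'   than the feature count fall back to the grand mean variance).
#' @return Numeric vector of background variances, one per feature, in the
#'   input row order.
#' @export
background_variance <- function(mat, w = 101) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) < 2) abort("insufficient-replicates: need >= 2 replicates.")
  if (w < 3 || w %% 2 == 0) abort("`w` must be odd and >= 3.")
  means <- rowMeans(mat)
  vars <- rowSums((mat - means)^2) / (ncol(mat) - 1)
  ord <- order(means)
  v_sorted <- vars[ord]
  k <- (w - 1) %/% 2
  cs <- cumsum(c(0, v_sorted))
  i <- seq_len(n)
  lo <- pmax(1L, i - k)
  hi <- pmin(n, i + k)
  bg_sorted <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  bg <- numeric(n)
  bg[ord] <- bg_sorted
  bg
}

#' Bayesian-regularized two-sample t-statistics
#'
#' For each feature, the per-group variance is shrunk toward a background
#' variance with `prior_df` pseudo-replicates of weight:
#' `s2_tilde = (prior_df * sigma0^2 + (n - 1) * s^2) / (prior_df + n - 1)`
#' (the `"n-2"` variant divides by `prior_df + n - 2`). The statistic is
#' `t = (mean_B - mean_A) / sqrt(s2_tilde_A / nA + s2_tilde_B / nB)` with
#' two-sided p-values from a Student t distribution on
#' `nA + nB - 2 + 2 * prior_df` degrees of freedom. With `prior_df = 0`
#' and equal group sizes this is exactly the classical pooled two-sample
#' t-test.
#'
#' @param A,B Numeric matrices, features x replicates, >= 2 replicates each.
#' @param sigma0_A,sigma0_B Background variances per feature; computed via
#'   [background_variance()] with window `w` when `NULL`.
#' @param prior_df Prior pseudo-replicate count `nu0 >= 0` (default 10).
#' @param w Background-variance window (default 101).
#' @param var_mode Shrinkage denominator: `"n-1"` (`prior_df + n - 1`,
#'   default; makes `prior_df = 0` the exact classical test) or `"n-2"`
#'   (`prior_df + n - 2`).
#' @return Tibble with columns `mean_A`, `mean_B`, `t`, `p`, `df`.
#' @export
regularized_t <- function(A, B, sigma0_A = NULL, sigma0_B = NULL,
                          prior_df = 10, w = 101,
                          var_mode = c("n-1", "n-2")) {
  var_mode <- match.arg(var_mode)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) abort("`A` and `B` must have the same features.")
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2 || nB < 2) abort("insufficient-replicates: need >= 2 per group.")
  if (prior_df < 0) abort("`prior_df` must be >= 0.")
  if (prior_df > 0) {
    if (is.null(sigma0_A)) sigma0_A <- background_variance(A, min_odd(w, nrow(A)))
    if (is.null(sigma0_B)) sigma0_B <- background_variance(B, min_odd(w, nrow(B)))
  } else {
    sigma0_A <- sigma0_B <- 0
  }
  mA <- rowMeans(A); mB <- rowMeans(B)
  sA2 <- rowSums((A - mA)^2) / (nA - 1)
  sB2 <- rowSums((B - mB)^2) / (nB - 1)
  denA <- prior_df + nA - ifelse(var_mode == "n-1", 1, 2)
  denB <- prior_df + nB - ifelse(var_mode == "n-1", 1, 2)
  if (denA <= 0 || denB <= 0) abort("Shrinkage denominator must be positive.")
  vA <- (prior_df * sigma0_A + (nA - 1) * sA2) / denA
  vB <- (prior_df * sigma0_B + (nB - 1) * sB2) / denB
  se <- sqrt(vA / nA + vB / nB)
  diff <- mB - mA
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- nA + nB - 2 + 2 * prior_df
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  p[se == 0 & diff == 0] <- 1
  tibble(mean_A = mA, mean_B = mB, t = t, p = p, df = df)
}

# Largest odd window not exceeding the feature count (>= 3).
min_odd <- function(w, n) {
  w <- min(w, n)
  if (w %% 2 == 0) w <- w - 1
  max(w, 3)
}

#' Classify regions into stable / enriched / deprived
#'
#' A region is non-stable iff its p-value is at or below `p_threshold`;
#' non-stable regions are `enriched` when the group-B mean exceeds the
#' group-A mean and `deprived` when it is lower (group B is the leukaemic
#' side of the comparison).
#'
#' @param results Tibble with columns `mean_A`, `mean_B`, `p` (e.g. from
#'   [regularized_t()]).
#' @param p_threshold Significance threshold on raw p (default 0.05).
#' @return The input with a `class` column added.
#' @export
classify_regions <- function(results, p_threshold = 0.05) {
  results %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$p > p_threshold ~ "stable",
      .data$mean_B > .data$mean_A ~ "enriched",
      .data$mean_B < .data$mean_A ~ "deprived",
      TRUE ~ "stable"
    ))
}

#' Differential acetylation between two condition groups
#'
#' Tests every atlas region for a change of normalized acetylation score
#' between groups A and B with the Bayesian-regularized t-test and
#' partitions the significant ("variable") regions into enriched and
#' deprived sets. P-values are thresholded raw by default; Benjamini-
#' Hochberg adjustment is available via `adjust = "BH"`.
#'
#' @param scores A `region_scores` tibble from [score_regions()].
#' @param groups Named character vector sample_id -> "A"/"B" (see
#'   [chip_groups()]).
#' @param p_threshold Significance threshold (default 0.05).
#' @param prior_df,w,var_mode Passed to [regularized_t()].
#' @param value Score column to test (default `"rpm"`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `diffac`: list with `table` (tibble `region_id`,
#'   `mean_A`, `mean_B`, `t`, `p`, `class`) and `params`. Use [tidy()] /
#'   [glance()] / [autoplot()].
#' @export
diff_acetylation <- function(scores, groups, p_threshold = 0.05,
                             prior_df = 10, w = 101,
                             var_mode = c("n-1", "n-2"),
                             value = c("rpm", "raw"),
                             adjust = c("none", "BH")) {
  value <- match.arg(value)
  adjust <- match.arg(adjust)
  var_mode <- match.arg(var_mode)
  assert_fraction(p_threshold, "p_threshold")
  m <- scores_matrix(scores, value)
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing)) {
    abort(paste0("No group assignment for samples: ",
                 paste(missing, collapse = ", ")))
  }
  g <- groups[colnames(m)]
  if (!all(g %in% c("A", "B"))) abort("`groups` must map to 'A' or 'B'.")
  A <- m[, g == "A", drop = FALSE]
  B <- m[, g == "B", drop = FALSE]
  res <- regularized_t(A, B, prior_df = prior_df, w = w, var_mode = var_mode)
  tab <- tibble(
    region_id = rownames(m),
    mean_A = res$mean_A, mean_B = res$mean_B, t = res$t,
    p_raw = res$p,
    p = if (adjust == "BH") p.adjust(res$p, "BH") else res$p)
  tab <- classify_regions(tab, p_threshold)
  structure(
    list(table = tab,
         params = list(p_threshold = p_threshold, prior_df = prior_df,
                       w = w, var_mode = var_mode, value = value,
                       adjust = adjust,
                       nA = sum(g == "A"), nB = sum(g == "B"),
                       df = res$df[1])),
    class = "diffac")
}

#' @export
print.diffac <- function(x, ...) {
  cnt <- table(factor(x$table$class,
                      levels = c("stable", "enriched", "deprived")))
  cat("<diffac> ", nrow(x$table), " regions (",
      x$params$nA, " vs ", x$params$nB, " samples): ",
      cnt[["enriched"]], " enriched, ", cnt[["deprived"]], " deprived, ",
      cnt[["stable"]], " stable at p <= ", x$params$p_threshold, "\n",
      sep = "")
  invisible(x)
}

#' Replicate-concordance kernel density grid
#'
#' 2-D Gaussian kernel density of paired log scores from two samples
#' (typically biological replicates), the display used to judge
#' reproducibility of region scores. Cell masses are normalized so that
#' `sum(z) * dx * dy = 1`.
#'
#' @param scores_x,scores_y Equal-length nonnegative score vectors.
#' @param grid_size Grid points per axis (default 64).
#' @param bandwidth Kernel bandwidth (scalar or length-2); a normal
#'   reference bandwidth is used when `NULL`, with a floor for degenerate
#'   inputs.
#' @param pseudocount Added before the log10 transform (default 0.5).
#' @return List of class `density_grid` with `x`, `y` (grid coordinates,
#'   log10 scale) and `z` (density matrix).
#' @export
replicate_density_grid <- function(scores_x, scores_y, grid_size = 64,
                                   bandwidth = NULL, pseudocount = 0.5) {
  if (length(scores_x) == 0 || length(scores_x) != length(scores_y)) {
    abort("`scores_x` and `scores_y` must be non-empty and equal length.")
  }
  lx <- log10(scores_x + pseudocount)
  ly <- log10(scores_y + pseudocount)
  if (is.null(bandwidth)) {
    bw <- c(bandwidth.nrd(lx), bandwidth.nrd(ly))
    bw[!is.finite(bw) | bw <= 0] <- 0.1
  } else {
    bw <- rep(bandwidth, length.out = 2)
  }
  pad <- 4 * max(bw)
  d <- kde2d(lx, ly, h = bw, n = grid_size,
             lims = c(range(lx) + c(-pad, pad), range(ly) + c(-pad, pad)))
  dx <- diff(d$x[1:2]); dy <- diff(d$y[1:2])
  d$z <- d$z / (sum(d$z) * dx * dy)
  structure(list(x = d$x, y = d$y, z = d$z), class = "density_grid")
}
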