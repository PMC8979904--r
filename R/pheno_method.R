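# Phenotypic estimation of the total additive x additive x additive (aaa)
# interaction effect from groups of extreme lines, plus an effective-factor
# count.

#' Select groups of extreme lines
#'
#' Identifies the lines with minimal and maximal expression of a trait:
#' the `ceiling(fraction * n)` smallest and largest values of the
#' empirical distribution.  Ties at a group boundary are broken by line-id
#' lexicographic order so the selection is deterministic.
#'
#' @param y named numeric trait vector (names are line ids); `n >= 4`.
#' @param fraction fraction of lines per extreme group, in `(0, 0.5]`.
#'   The default 0.05 keeps the groups small, approximating lines that
#'   carry only trait-decreasing (resp. -increasing) alleles.
#' @return Object of class `extreme_groups`: list with `min_ids`,
#'   `max_ids`, `mean_min`, `mean_max`, `size`.
#' @examples
#' y <- c(a = 1, b = 2, c = 3, d = 4, e = 10)
#' select_extreme_groups(y, fraction = 0.2)
#' @export
select_extreme_groups <- function(y, fraction = 0.05) {
  n <- length(y)
  if (n < 4L) te_stop("te_domain_error", "need n >= 4 lines, got ", n)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    te_stop("te_config_error", "extreme fraction must be in (0, 0.5]")
  }
  if (anyNA(y)) te_stop("te_domain_error", "trait vector contains NA")
  if (is.null(names(y))) names(y) <- sprintf("L%03d", seq_len(n))
  if (max(y) == min(y)) {
    te_stop("te_degenerate_error", "constant trait vector: extreme groups",
            " are undefined")
  }
  size <- ceiling(fraction * n)
  if (2L * size > n) {
    te_stop("te_config_error", "extreme groups of ", size,
            " lines each overlap for n = ", n,
            "; reduce the extreme fraction")
  }
  ord <- order(y, names(y))
  min_ids <- names(y)[ord[seq_len(size)]]
  max_ids <- names(y)[ord[seq.int(n - size + 1L, n)]]
  structure(
    list(min_ids = min_ids, max_ids = max_ids,
         mean_min = mean(y[min_ids]), mean_max = mean(y[max_ids]),
         size = size),
    class = "extreme_groups"
  )
}

#' Phenotypic estimate of the total aaa interaction effect
#'
#' Estimates the total three-way epistatic effect from phenotypes alone as
#' `aaa_p = (L_max + L_min) / 2 - L`, where `L_min` and `L_max` are the
#' means of the minimal and maximal extreme-line groups and `L` is the
#' mean over all lines.  The estimator is location-invariant and
#' scale-equivariant.  Note that this symmetric form, applied to -1/+1
#' product-coded loci fixed at opposite extremes, cancels odd-order
#' (additive and triple) contributions on a perfectly balanced design; it
#' is nevertheless the classical phenotypic surrogate and is implemented
#' exactly in this form.
#'
#' @param y named numeric trait vector.
#' @param groups an [select_extreme_groups()] result drawn from `y`.
#' @return Object of class `phenotypic_estimate`: list with `aaa_p`,
#'   `mean_min`, `mean_max`, `mean_all`, `groups`.
#' @examples
#' y <- c(a = 1, b = 2, c = 3, d = 4, e = 10)
#' g <- select_extreme_groups(y, fraction = 0.2)
#' estimate_aaa_phenotypic(y, g)$aaa_p  # 0.5 * (1 + 10) - 4 = 1.5
#' @export
estimate_aaa_phenotypic <- function(y, groups) {
  stopifnot(inherits(groups, "extreme_groups"))
  ids <- c(groups$min_ids, groups$max_ids)
  if (!all(ids %in% names(y))) {
    te_stop("te_alignment_error", "extreme-group line ids not found in y")
  }
  mean_min <- mean(y[groups$min_ids])
  mean_max <- mean(y[groups$max_ids])
  mean_all <- mean(y)
  structure(
    list(aaa_p = 0.5 * (mean_max + mean_min) - mean_all,
         mean_min = mean_min, mean_max = mean_max, mean_all = mean_all,
         groups = groups),
    class = "phenotypic_estimate"
  )
}

#' Wright-type effective-factor count
#'
#' Estimates the number of segregating genes (effective factors)
#' controlling a trait as `round((L_max - L_min)^2 / (8 * s2))`, where
#' `L_min`/`L_max` are the extreme-group means and `s2` is the sample
#' variance of the trait.  This is a classical Wright-style range-based
#' stand-in; the estimator is pluggable so an alternative formula can be
#' substituted via `estimator`.
#'
#' @param y named numeric trait vector with positive sample variance.
#' @param groups an [select_extreme_groups()] result.
#' @param estimator optional replacement function taking
#'   `(mean_min, mean_max, y)` and returning a non-negative integer.
#' @return Non-negative integer count of effective factors.
#' @export
count_effective_factors <- function(y, groups, estimator = NULL) {
  stopifnot(inherits(groups, "extreme_groups"))
  s2 <- stats::var(y)
  if (!is.finite(s2) || s2 <= 0) {
    te_stop("te_degenerate_error",
            "zero trait variance: effective factors undefined")
  }
  mean_min <- mean(y[groups$min_ids])
  mean_max <- mean(y[groups$max_ids])
  if (!is.null(estimator)) {
    k <- estimator(mean_min, mean_max, y)
  } else {
    k <- round((mean_max - mean_min)^2 / (8 * s2))
  }
  max(0L, as.integer(k))
}
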