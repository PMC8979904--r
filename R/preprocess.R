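# Preprocessing: trait transformation, normality screening, flanking-marker
# imputation under the Haldane map function, and the 1:1 segregation
# chi-square pre-test.

#' Arcsine square-root transformation of percentage traits
#'
#' Computes `asin(sqrt(x / 100))` elementwise, mapping percentages in
#' `[0, 100]` to radians in `[0, pi/2]`.  Standard variance-stabilizing
#' transformation for percentage-scale traits (lodging, malt extract,
#' grain protein).
#'
#' @param x numeric vector of percentages in `[0, 100]`.
#' @return Transformed values in radians, names preserved.
#' @examples
#' arcsin_sqrt_transform(c(0, 50, 100))
#' @export
arcsin_sqrt_transform <- function(x) {
  bad <- which(!is.finite(x) | x < 0 | x > 100)
  if (length(bad) > 0L) {
    who <- if (!is.null(names(x))) names(x)[bad[1L]] else bad[1L]
    te_stop("te_domain_error", "value ", x[bad[1L]], " outside [0, 100] (",
            who, "); arcsin sqrt transform needs percentages")
  }
  asin(sqrt(x / 100))
}

#' Shapiro-Wilk normality screen for a trait vector
#'
#' Advisory check that a (possibly transformed) trait is compatible with a
#' normal distribution; it never blocks the analysis pipeline.
#'
#' @param y numeric trait vector, `n >= 8`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
check_normality <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 8L) {
    te_stop("te_domain_error", "normality check needs n >= 8, got ",
            length(y))
  }
  if (stats::sd(y) == 0) {
    te_stop("te_degenerate_error", "constant trait vector")
  }
  sw <- stats::shapiro.test(y)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Haldane map function: distance to recombination fraction
#'
#' Computes the recombination fraction `(1 - exp(-2 d / 100)) / 2` of a
#' map distance `d` in centiMorgans,
#' assuming no crossover interference.
#'
#' @param d numeric vector of map distances in cM (>= 0).
#' @return Recombination fractions in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 10, 50))
#' @export
haldane_r <- function(d) {
  if (any(!is.finite(d) | d < 0)) {
    te_stop("te_domain_error", "map distance must be finite and >= 0 cM")
  }
  0.5 * (1 - exp(-2 * d / 100))
}

# Conditional expectation of a DH +/-1 genotype given flanking observations,
# Markov (no-interference) model with Haldane recombination fractions.
# s_left / s_right are +/-1 or NA when the flank is absent.
.flank_expectation <- function(s_left, r_left, s_right, r_right) {
  has_l <- !is.na(s_left)
  has_r <- !is.na(s_right)
  if (!has_l && !has_r) return(0)
  if (has_l && !has_r) return(s_left * (1 - 2 * r_left))
  if (!has_l && has_r) return(s_right * (1 - 2 * r_right))
  p_l <- if (s_left > 0) 1 - r_left else r_left    # P(x = +1 | left)
  p_r <- if (s_right > 0) 1 - r_right else r_right # P(right | x = +1)
  num_plus <- p_l * p_r
  num_minus <- (1 - p_l) * (1 - p_r)
  (num_plus - num_minus) / (num_plus + num_minus)
}

#' Impute missing genotypes from flanking markers
#'
#' Each missing entry is replaced by the conditional expectation of the
#' -1/+1 genotype given the nearest non-missing markers to its left and
#' right on the same chromosome, under a Markov (no-interference) model
#' with Haldane recombination fractions.  With a single informative flank
#' at recombination fraction `r` the expectation is `s * (1 - 2 r)`; with
#' no informative marker on the chromosome it is 0 (1:1 segregation
#' prior).  Observed entries are unchanged, so the operation is
#' idempotent.
#'
#' @param geno genotype matrix (lines x markers, -1/+1 with `NA` missing)
#'   or a [dh_population()].
#' @param map a [linkage_map()]; required when `geno` is a matrix.
#' @param round_to_allele logical; if `TRUE`, imputed expectations are
#'   rounded to the nearer of -1/+1 (an expectation of exactly 0 maps to
#'   +1) for strict allele coding.  Default keeps continuous expectations.
#' @return Object of the same kind as `geno` with no missing entries.
#' @export
impute_flanking <- function(geno, map = NULL, round_to_allele = FALSE) {
  pop <- NULL
  if (inherits(geno, "dh_population")) {
    pop <- geno
    map <- pop$map
    geno <- pop$geno
  }
  stopifnot(is.matrix(geno), !is.null(map))
  if (!identical(colnames(geno), map$marker)) {
    te_stop("te_alignment_error",
            "genotype columns must match map marker order")
  }
  out <- geno
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$position_cM[idx]
    sub <- geno[, idx, drop = FALSE]
    if (!anyNA(sub)) next
    for (i in seq_len(nrow(sub))) {
      v <- sub[i, ]
      mis <- which(is.na(v))
      if (length(mis) == 0L) next
      obs <- which(!is.na(v))
      for (j in mis) {
        k <- findInterval(j, obs)
        left <- if (k >= 1L) obs[k] else NA_integer_
        right <- if (k < length(obs)) obs[k + 1L] else NA_integer_
        e <- .flank_expectation(
          if (is.na(left)) NA_real_ else v[left],
          if (is.na(left)) NA_real_ else haldane_r(pos[j] - pos[left]),
          if (is.na(right)) NA_real_ else v[right],
          if (is.na(right)) NA_real_ else haldane_r(pos[right] - pos[j])
        )
        out[i, idx[j]] <- e
      }
    }
  }
  if (round_to_allele) {
    imputed <- is.na(geno)
    out[imputed] <- ifelse(out[imputed] >= 0, 1, -1)
  }
  if (!is.null(pop)) {
    pop$geno <- out
    return(pop)
  }
  out
}

#' Chi-square test of 1:1 marker segregation
#'
#' Per-marker goodness-of-fit of the observed +1/-1 counts against the 1:1
#' ratio expected in a DH population: `chi2 = (n_plus - n_minus)^2 /
#' (n_plus + n_minus)` on 1 degree of freedom.  Used as a pre-test of the
#' equal-segregation assumption before estimation; distorted markers are
#' flagged, not removed, unless the caller excludes them.
#'
#' @param geno genotype matrix or [dh_population()].
#' @param map optional [linkage_map()] used to annotate chromosomes.
#' @param alpha flagging level for distortion (default 0.05).
#' @return Data frame with columns `marker`, `chromosome`, `n_plus`,
#'   `n_minus`, `chi2`, `p_value`, `distorted`.
#' @export
segregation_chi2 <- function(geno, map = NULL, alpha = 0.05) {
  if (inherits(geno, "dh_population")) {
    map <- geno$map
    geno <- geno$geno
  }
  stopifnot(is.matrix(geno))
  n_plus <- colSums(geno > 0, na.rm = TRUE)
  n_minus <- colSums(geno < 0, na.rm = TRUE)
  tot <- n_plus + n_minus
  if (any(tot == 0L)) {
    te_stop("te_degenerate_error", "marker(s) with no informative entries: ",
            paste(colnames(geno)[tot == 0L], collapse = ", "))
  }
  chi2 <- (n_plus - n_minus)^2 / tot
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(
    marker = colnames(geno),
    chromosome = if (!is.null(map))
      map$chromosome[match(colnames(geno), map$marker)]
    else NA_character_,
    n_plus = unname(n_plus),
    n_minus = unname(n_minus),
    chi2 = unname(chi2),
    p_value = unname(p),
    distorted = unname(p < alpha),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a segregation report to TSV
#'
#' @param report output of [segregation_chi2()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segregation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
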