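# Batch orchestration: run both estimators over every trait-by-environment
# set of a population, pair them, and summarize the (aaa_g / aaa_p) * 100
# ratio distribution.

#' Default comparison configuration
#'
#' @param extreme_fraction fraction of lines per extreme group for the
#'   phenotypic estimator (default 0.05 of n, minimum one line).
#' @param alpha family-wise significance level for triple terms
#'   (default 0.05, Bonferroni-corrected per test).
#' @param transform character vector of trait ids to transform by
#'   arcsin(sqrt(x/100)) before analysis (percentage-scale traits).
#' @param segregation_alpha flagging level of the 1:1 segregation pre-test.
#' @param exclude_distorted drop markers failing the segregation test
#'   before estimation (default `FALSE`: report only).
#' @param round_imputed round imputed genotypes to -1/+1 (default keeps
#'   conditional expectations).
#' @param max_params stage-3 cap on fitted parameters (default `n - 10`).
#' @param m_rule Bonferroni denominator rule, see [total_aaa_genotypic()].
#' @param verbose print per-trait progress and stepwise moves.
#' @return Named list of settings for [run_comparison()].
#' @export
comparison_config <- function(extreme_fraction = 0.05, alpha = 0.05,
                              transform = character(),
                              segregation_alpha = 0.05,
                              exclude_distorted = FALSE,
                              round_imputed = FALSE, max_params = NULL,
                              m_rule = "candidates", verbose = FALSE) {
  list(extreme_fraction = extreme_fraction, alpha = alpha,
       transform = transform, segregation_alpha = segregation_alpha,
       exclude_distorted = exclude_distorted,
       round_imputed = round_imputed, max_params = max_params,
       m_rule = m_rule, verbose = verbose)
}

#' Run the phenotypic / genotypic comparison over all traits
#'
#' For each trait-by-environment column of the population's phenotype
#' table, independently: optional arcsin square-root transformation,
#' flanking-marker imputation, segregation report (with optional exclusion
#' of distorted markers), the phenotypic extreme-group estimate with
#' effective-factor count, the three-stage genotypic estimate, and the
#' paired ratio `(aaa_g / aaa_p) * 100`.  A failure in one trait is
#' captured in that trait's record and does not abort the batch.
#'
#' @param pop a [dh_population()] with at least one trait.
#' @param config a [comparison_config()].
#' @return Data frame of class `comparison_records`, one row per trait
#'   set, with columns `trait_id`, `environment_id`, `aaa_p`,
#'   `n_effective_factors`, `mean_min`, `mean_max`, `mean_all`,
#'   `group_size`, `aaa_g`, `ns_flag`, `n_markers_included`,
#'   `n_significant_aaa`, `ratio_percent`, `error`.  `ratio_percent` is
#'   `NA` (undefined) when `aaa_p == 0` or the genotypic estimate is NS.
#'   Attributes `details` (per-trait fits and triple tables) and
#'   `segregation` (the marker report) carry the full results.
#' @export
run_comparison <- function(pop, config = comparison_config()) {
  stopifnot(inherits(pop, "dh_population"))
  if (ncol(pop$pheno) == 0L) {
    te_stop("te_config_error", "population has no traits to analyze")
  }
  seg <- segregation_chi2(pop, alpha = config$segregation_alpha)
  work <- impute_flanking(pop, round_to_allele = config$round_imputed)
  if (config$exclude_distorted && any(seg$distorted)) {
    keep <- seg$marker[!seg$distorted]
    work$geno <- work$geno[, keep, drop = FALSE]
    work$map <- work$map[work$map$marker %in% keep, , drop = FALSE]
  }
  n <- nrow(work$geno)
  details <- list()
  rows <- lapply(names(pop$pheno), function(nm) {
    ids <- .split_trait_id(nm)
    rec <- data.frame(
      trait_id = ids[["trait"]], environment_id = ids[["environment"]],
      aaa_p = NA_real_, n_effective_factors = NA_integer_,
      mean_min = NA_real_, mean_max = NA_real_, mean_all = NA_real_,
      group_size = NA_integer_, aaa_g = NA_real_, ns_flag = NA,
      n_markers_included = NA_integer_, n_significant_aaa = NA_integer_,
      ratio_percent = NA_real_, error = NA_character_,
      stringsAsFactors = FALSE
    )
    tryCatch({
      y <- pop$pheno[[nm]]
      names(y) <- rownames(pop$pheno)
      if (ids[["trait"]] %in% config$transform) {
        y <- arcsin_sqrt_transform(y)
      }
      if (config$verbose) message("trait ", nm, ": phenotypic estimate")
      groups <- select_extreme_groups(y, config$extreme_fraction)
      ph <- estimate_aaa_phenotypic(y, groups)
      rec$aaa_p <- ph$aaa_p
      rec$mean_min <- ph$mean_min
      rec$mean_max <- ph$mean_max
      rec$mean_all <- ph$mean_all
      rec$group_size <- groups$size
      rec$n_effective_factors <- count_effective_factors(y, groups)
      if (config$verbose) message("trait ", nm, ": genotypic estimate")
      gn <- estimate_aaa_genotypic(work, y, alpha = config$alpha,
                                   max_params = config$max_params,
                                   m_rule = config$m_rule,
                                   verbose = config$verbose)
      est <- gn$estimate
      rec$aaa_g <- est$aaa_g
      rec$ns_flag <- est$ns_flag
      rec$n_markers_included <- est$n_markers_included
      rec$n_significant_aaa <- est$n_significant_aaa
      if (!est$ns_flag && rec$aaa_p != 0) {
        rec$ratio_percent <- rec$aaa_g / rec$aaa_p * 100
      }
      details[[nm]] <<- list(phenotypic = ph, genotypic = gn)
      rec
    }, te_error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_records", "data.frame")
  attr(out, "details") <- details
  attr(out, "segregation") <- seg
  attr(out, "config") <- config
  out
}

#' Summarize paired phenotypic / genotypic estimates
#'
#' Reports, over the records with a defined pair (phenotypic estimate
#' nonzero, genotypic estimate not NS): the count and fraction of cases
#' where the genotypic estimate is smaller than the phenotypic one both in
#' magnitude and in signed value, the count of records with at least one
#' significant aaa interaction, the quartile box-plot statistics of
#' `ratio_percent` per trait, and the ratio extremes.
#'
#' @param records output of [run_comparison()].
#' @return List with `n_records`, `n_failed`, `n_defined_pairs`,
#'   `n_smaller_magnitude`, `frac_smaller_magnitude`, `n_smaller_signed`,
#'   `frac_smaller_signed`, `n_with_significant_aaa`, `ratio_quartiles`
#'   (data frame per trait: min, q1, median, q3, max, n) and
#'   `ratio_range`.
#' @export
summarize_comparison <- function(records) {
  if (nrow(records) < 1L) te_stop("te_config_error", "no records")
  ok <- is.na(records$error)
  defined <- ok & !is.na(records$ratio_percent)
  d <- records[defined, , drop = FALSE]
  n_def <- nrow(d)
  smaller_mag <- sum(abs(d$aaa_g) < abs(d$aaa_p))
  smaller_sgn <- sum(d$aaa_g < d$aaa_p)
  quart <- if (n_def > 0L) {
    do.call(rbind, lapply(split(d$ratio_percent, d$trait_id), function(r) {
      q <- stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 max = q[5], n = length(r))
    }))
  } else {
    data.frame(min = numeric(), q1 = numeric(), median = numeric(),
               q3 = numeric(), max = numeric(), n = integer())
  }
  quart <- cbind(trait_id = rownames(quart), quart)
  rownames(quart) <- NULL
  list(
    n_records = nrow(records),
    n_failed = sum(!ok),
    n_defined_pairs = n_def,
    n_smaller_magnitude = smaller_mag,
    frac_smaller_magnitude = if (n_def > 0L) smaller_mag / n_def else
      NA_real_,
    n_smaller_signed = smaller_sgn,
    frac_smaller_signed = if (n_def > 0L) smaller_sgn / n_def else NA_real_,
    n_with_significant_aaa = sum(records$n_significant_aaa > 0, na.rm = TRUE),
    ratio_quartiles = quart,
    ratio_range = if (n_def > 0L) range(d$ratio_percent) else
      c(NA_real_, NA_real_)
  )
}

.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Export comparison tables
#'
#' Writes four files to `out_dir`: `phenotypic_estimates.tsv` (per-trait
#' aaa_p with extreme-group means and effective-factor count),
#' `genotypic_estimates.tsv` (per-trait aaa_g -- literally `NS` when no
#' triple is significant -- with the `(markers | significant)`
#' annotation), `ratio_percent.tsv` (the per-trait ratio data underlying a
#' box-plot summary), and `run_metadata.json` (configuration, package
#' version).  Re-running with an identical population and configuration
#' reproduces the tables byte-identically.
#'
#' @param records output of [run_comparison()].
#' @param summary output of [summarize_comparison()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
export_tables <- function(records, summary, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    te_stop("te_io_error", "cannot create directory ", out_dir)
  }
  ppath <- file.path(out_dir, "phenotypic_estimates.tsv")
  gpath <- file.path(out_dir, "genotypic_estimates.tsv")
  rpath <- file.path(out_dir, "ratio_percent.tsv")
  mpath <- file.path(out_dir, "run_metadata.json")

  ptab <- data.frame(
    trait = records$trait_id, environment = records$environment_id,
    aaa_p = .fmt_num(records$aaa_p),
    mean_min = .fmt_num(records$mean_min),
    mean_max = .fmt_num(records$mean_max),
    mean_all = .fmt_num(records$mean_all),
    group_size = records$group_size,
    n_effective_factors = records$n_effective_factors,
    stringsAsFactors = FALSE
  )
  utils::write.table(ptab, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gtab <- data.frame(
    trait = records$trait_id, environment = records$environment_id,
    aaa_g = ifelse(!is.na(records$ns_flag) & records$ns_flag, "NS",
                   .fmt_num(records$aaa_g)),
    annotation = ifelse(
      is.na(records$n_markers_included), "NA",
      sprintf("(%d | %d)", records$n_markers_included,
              records$n_significant_aaa)),
    stringsAsFactors = FALSE
  )
  utils::write.table(gtab, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  rtab <- data.frame(
    trait = records$trait_id, environment = records$environment_id,
    ratio_percent = .fmt_num(records$ratio_percent),
    stringsAsFactors = FALSE
  )
  utils::write.table(rtab, rpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cfg <- attr(records, "config")
  cfg$verbose <- NULL
  meta <- list(
    package = "triepistasis",
    version = as.character(utils::packageVersion("triepistasis")),
    config = cfg,
    summary = summary[c("n_records", "n_failed", "n_defined_pairs",
                        "n_smaller_magnitude", "n_with_significant_aaa")]
  )
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")

  invisible(c(phenotypic = ppath, genotypic = gpath, ratio = rpath,
              metadata = mpath))
}
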