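multi_trait_pop <- function(seed = 801) {
  sim_config(
    n_lines = 100,
    chromosomes = lapply(1:3, function(i) {
      list(name = paste0("C", i), n_markers = 6, spacing_cM = 15)
    }),
    mu = 0, sigma_e = 1, missing_rate = 0.02, seed = seed,
    traits = list(
      T1.E1 = list(mu = 5, sigma_e = 1, effects = list(
        list(markers = "C1_M03", value = 1.2),
        list(markers = "C2_M03", value = 1.0),
        list(markers = "C3_M03", value = 0.9),
        list(markers = c("C1_M03", "C2_M03", "C3_M03"), value = 1.0))),
      T2.E1 = list(mu = 2, sigma_e = 1, effects = list(
        list(markers = "C2_M02", value = 1.5))),
      T3.E1 = list(mu = 0, sigma_e = 1, effects = list())
    )
  ) |> simulate_population()
}

test_that("a multi-trait batch yields one record per trait set", {
  pop <- multi_trait_pop()
  rec <- run_comparison(pop)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$trait_id, c("T1", "T2", "T3"))
  expect_identical(rec$environment_id, rep("E1", 3))
  expect_true(all(is.na(rec$error)))
  # ratio invariant wherever defined
  def <- !is.na(rec$ratio_percent)
  expect_lt(max(abs(rec$ratio_percent[def] * rec$aaa_p[def] / 100 -
                      rec$aaa_g[def]), 0), 1e-10)
})

test_that("traits whose model retains no triples are reported NS", {
  # a single 2-marker chromosome can never form a triple
  cfg <- sim_config(
    n_lines = 60,
    chromosomes = list(list(name = "1H", n_markers = 2, spacing_cM = 30)),
    effects = list(list(markers = "1H_M01", value = 1)),
    mu = 0, sigma_e = 1, seed = 802
  )
  pop <- simulate_population(cfg)
  rec <- run_comparison(pop)
  expect_true(rec$ns_flag)
  expect_identical(rec$n_significant_aaa, 0L)
  expect_true(is.na(rec$ratio_percent))
})

test_that("noise-free architectures give records with aaa_g equal to the injected total", {
  cfg <- sim_config(
    n_lines = 120,
    chromosomes = lapply(1:3, function(i) {
      list(name = paste0("C", i), n_markers = 4, spacing_cM = 25)
    }),
    effects = list(
      list(markers = "C1_M02", value = 1.0),
      list(markers = "C2_M02", value = 0.9),
      list(markers = "C3_M02", value = -0.8),
      list(markers = c("C1_M02", "C2_M02", "C3_M02"), value = 0.7)
    ),
    mu = 1, sigma_e = 0, missing_rate = 0, seed = 803
  )
  pop <- simulate_population(cfg)
  rec <- run_comparison(pop)
  expect_true(is.na(rec$error))
  expect_equal(rec$aaa_g, 0.7, tolerance = 1e-8)
})

test_that("one failing trait does not abort the batch", {
  pop <- multi_trait_pop()
  pop$pheno$T4.E1 <- rep(3, nrow(pop$pheno))  # constant: degenerate
  rec <- run_comparison(pop)
  expect_identical(nrow(rec), 4L)
  expect_match(rec$error[rec$trait_id == "T4"], "constant")
  expect_true(all(is.na(rec$error[rec$trait_id != "T4"])))
})

test_that("percentage traits can be transformed in the pipeline", {
  pop <- multi_trait_pop()
  # rescale one trait into percentages
  y <- pop$pheno$T2.E1
  pop$pheno$L.E1 <- 100 * (y - min(y)) / (max(y) - min(y))
  cfg <- comparison_config(transform = "L")
  rec <- run_comparison(pop, cfg)
  row <- rec[rec$trait_id == "L", ]
  expect_true(is.na(row$error))
  # means are on the transformed (radian) scale
  expect_lte(row$mean_max, pi / 2)
  expect_gte(row$mean_min, 0)
})

test_that("summaries count magnitude ordering and are permutation-invariant", {
  rec <- data.frame(
    trait_id = c("A", "A", "B"), environment_id = "E",
    aaa_p = c(1, 1, 1), n_effective_factors = 1L,
    mean_min = 0, mean_max = 2, mean_all = 1, group_size = 1L,
    aaa_g = c(0.5, 0.8, 1.2), ns_flag = FALSE,
    n_markers_included = 3L, n_significant_aaa = 1L,
    ratio_percent = c(50, 80, 120), error = NA_character_,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("comparison_records", "data.frame")
  s <- summarize_comparison(rec)
  expect_identical(s$n_defined_pairs, 3L)
  expect_equal(s$frac_smaller_magnitude, 2 / 3)
  expect_identical(s$ratio_range, c(50, 120))
  # single-record trait: all quartiles collapse to its ratio
  bq <- s$ratio_quartiles[s$ratio_quartiles$trait_id == "B", ]
  expect_true(all(bq[, c("min", "q1", "median", "q3", "max")] == 120))

  s2 <- summarize_comparison(rec[c(3, 1, 2), ])
  expect_identical(s2[c("n_smaller_magnitude", "n_defined_pairs")],
                   s[c("n_smaller_magnitude", "n_defined_pairs")])

  # all-NS batch: counts zero, fractions undefined
  rec_ns <- rec
  rec_ns$ns_flag <- TRUE
  rec_ns$ratio_percent <- NA_real_
  s3 <- summarize_comparison(rec_ns)
  expect_identical(s3$n_defined_pairs, 0L)
  expect_true(is.na(s3$frac_smaller_magnitude))
  expect_identical(s3$n_smaller_magnitude, 0L)
})

test_that("exported tables are re-readable, literal about NS, and deterministic", {
  pop <- multi_trait_pop()
  rec <- run_comparison(pop)
  s <- summarize_comparison(rec)
  d1 <- withr::local_tempdir()
  paths <- export_tables(rec, s, d1)
  expect_true(all(file.exists(paths)))
  gtab <- utils::read.delim(paths[["genotypic"]])
  expect_identical(nrow(gtab), nrow(rec))
  if (any(rec$ns_flag)) {
    expect_true(all(gtab$aaa_g[rec$ns_flag] == "NS"))
  }
  expect_match(gtab$annotation[1], "^\\([0-9]+ \\| [0-9]+\\)$")
  ptab <- utils::read.delim(paths[["phenotypic"]])
  expect_equal(as.numeric(ptab$aaa_p), rec$aaa_p, tolerance = 1e-5)

  d2 <- withr::local_tempdir()
  export_tables(run_comparison(multi_trait_pop()), s, d2)
  for (f in setdiff(basename(paths), "run_metadata.json")) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)))
  }
})

test_that("populations without traits are refused", {
  ff <- make_full_factorial(3)
  expect_error(run_comparison(ff), class = "te_config_error")
})
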