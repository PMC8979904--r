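test_that("design construction enumerates all pairwise and triple products", {
  ff <- make_full_factorial(3)
  d3 <- build_design(ff, c("F1", "F2", "F3"))
  expect_identical(ncol(d3$G), 1L + 3L + 3L + 1L)
  expect_identical(sum(d3$terms$order == 2L), 3L)
  expect_identical(sum(d3$terms$order == 3L), 1L)
  expect_true(all(d3$G[, d3$terms$order == 3L] %in% c(-1, 1)))
  # triple column is the elementwise product of the three main columns
  expect_identical(unname(d3$G[, "F1:F2:F3"]),
                   unname(d3$G[, "F1"] * d3$G[, "F2"] * d3$G[, "F3"]))

  d2 <- build_design(ff, c("F1", "F3"))
  expect_identical(sum(d2$terms$order == 3L), 0L)
  expect_identical(ncol(d2$G), 4L)

  # canonical ordering: selection order does not matter
  d3b <- build_design(ff, c("F3", "F1", "F2"))
  expect_identical(d3b$terms$term, d3$terms$term)
})

test_that("OLS recovers exact coefficients on the orthogonal full factorial", {
  ff <- make_full_factorial(3)
  x <- ff$geno
  y <- x[, 1] * x[, 2] * x[, 3]
  names(y) <- rownames(x)
  d <- build_design(ff, colnames(x))
  f <- fit_ols(d, y)
  est <- f$coefficients$estimate
  names(est) <- f$coefficients$term
  expect_equal(unname(est["F1:F2:F3"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(est[names(est) != "F1:F2:F3"])), 1e-12)
  expect_lt(f$rss, 1e-20)

  # orthogonality: dropping a term leaves the others unchanged
  y2 <- 2 + 1.5 * x[, 1] + 0.25 * x[, 2] * x[, 3]
  names(y2) <- rownames(x)
  full <- fit_ols(d, y2)$coefficients
  sub <- fit_ols(build_design(ff, c("F1", "F2")), y2)$coefficients
  expect_equal(sub$estimate[sub$term == "F1"],
               full$estimate[full$term == "F1"], tolerance = 1e-10)
  expect_equal(full$estimate[full$term == "(Intercept)"], 2,
               tolerance = 1e-12)
  expect_equal(full$estimate[full$term == "F1"], 1.5, tolerance = 1e-12)
})

test_that("OLS matches the brute-force normal-equation oracle on random designs", {
  set.seed(601)
  for (i in 1:25) {
    G <- cbind(1, matrix(sample(c(-1, 1), 150 * 9, replace = TRUE), 150))
    colnames(G) <- c("(Intercept)", sprintf("V%d", 1:9))
    y <- rnorm(150)
    f <- fit_ols(raw_design(G), y)
    oracle <- normal_equation_solve(G, y)
    rel <- max(abs(f$coefficients$estimate - oracle)) /
      max(abs(oracle))
    expect_lt(rel, 1e-8)
  }
})

test_that("aliased columns are dropped deterministically, first kept wins", {
  set.seed(602)
  x1 <- sample(c(-1, 1), 30, replace = TRUE)
  x2 <- sample(c(-1, 1), 30, replace = TRUE)
  G <- cbind("(Intercept)" = 1, A = x1, B = x2, Adup = x1)
  f <- fit_ols(raw_design(G), rnorm(30))
  expect_false(f$rank_ok)
  expect_identical(f$dropped_terms, "Adup")
  expect_true(is.na(
    f$coefficients$estimate[f$coefficients$term == "Adup"]))
})

test_that("fit AIC equals the Gaussian stats::AIC of the same model", {
  set.seed(603)
  G <- cbind("(Intercept)" = 1,
             A = sample(c(-1, 1), 50, TRUE), B = sample(c(-1, 1), 50, TRUE))
  y <- rnorm(50, 1 + 0.5 * G[, "A"])
  f <- fit_ols(raw_design(G), y)
  lmfit <- stats::lm(y ~ A + B, data = as.data.frame(G[, -1]))
  expect_equal(f$aic, stats::AIC(lmfit), tolerance = 1e-8)
  expect_equal(unname(f$coefficients$estimate),
               unname(coef(lmfit)), tolerance = 1e-10)
  sm <- summary(lmfit)$coefficients
  expect_equal(f$coefficients$se, unname(sm[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(f$coefficients$p_value, unname(sm[, "Pr(>|t|)"]),
               tolerance = 1e-10)
})

test_that("stage-1/2 selection matches stats::step on an unconstrained case", {
  set.seed(604)
  n <- 100
  geno <- matrix(sample(c(-1, 1), n * 8, replace = TRUE), n,
                 dimnames = list(sprintf("L%03d", 1:n),
                                 sprintf("1H_M%02d", 1:8)))
  map <- linkage_map(colnames(geno), rep("1H", 8), seq(0, 70, by = 10))
  pop <- dh_population(geno, map)
  y <- 1 + 1.2 * geno[, 3] - 0.9 * geno[, 6] + rnorm(n)
  names(y) <- rownames(geno)

  mine <- stage1_chromosome_select(pop, y)[["1H"]]

  df <- data.frame(y = y, geno, check.names = TRUE)
  null_fit <- stats::lm(y ~ 1, data = df)
  scope <- stats::as.formula(
    paste("~", paste(make.names(colnames(geno)), collapse = "+")))
  ref <- stats::step(null_fit, scope = scope, direction = "both", trace = 0)
  ref_sel <- sub("^X", "", names(coef(ref))[-1])
  expect_setequal(make.names(mine), make.names(ref_sel))
})

test_that("stage 1 keeps strong signals and stays sparse under the null", {
  # a lone marker with overwhelming effect always survives
  set.seed(605)
  n <- 150
  geno <- matrix(sample(c(-1, 1), n, replace = TRUE), n,
                 dimnames = list(sprintf("L%03d", 1:n), "1H_M01"))
  map <- linkage_map("1H_M01", "1H", 0)
  pop <- dh_population(geno, map)
  y <- 2 * geno[, 1] + rnorm(n, sd = 0.5)
  names(y) <- rownames(geno)
  expect_identical(stage1_chromosome_select(pop, y)[["1H"]], "1H_M01")

  # pure-noise chromosome of 10 unlinked markers: mean survivors < 2
  set.seed(606)
  survivors <- replicate(100, {
    g <- matrix(sample(c(-1, 1), 150 * 10, replace = TRUE), 150,
                dimnames = list(NULL, sprintf("1H_M%02d", 1:10)))
    rownames(g) <- sprintf("L%03d", 1:150)
    m <- linkage_map(colnames(g), rep("1H", 10), seq(0, 900, by = 100))
    p <- dh_population(g, m)
    yy <- rnorm(150); names(yy) <- rownames(g)
    length(stage1_chromosome_select(p, yy)[["1H"]])
  })
  expect_lt(mean(survivors), 2)
})

test_that("stage 2 pools chromosomes and collapses aliased markers", {
  set.seed(607)
  n <- 150
  g1 <- sample(c(-1, 1), n, replace = TRUE)
  g2 <- sample(c(-1, 1), n, replace = TRUE)
  geno <- cbind("1H_M01" = g1, "2H_M01" = g2, "2H_M02" = g1)  # alias of 1H_M01
  rownames(geno) <- sprintf("L%03d", 1:n)
  map <- linkage_map(colnames(geno), c("1H", "2H", "2H"), c(0, 0, 50))
  pop <- dh_population(geno, map)
  y <- 1.5 * g1 - 1.2 * g2 + rnorm(n, sd = 0.5)
  names(y) <- rownames(geno)
  sel <- stage2_combined_select(pop, y, list(colnames(geno)))
  expect_true("2H_M01" %in% sel)
  # only one of the aliased pair is retained
  expect_identical(sum(c("1H_M01", "2H_M02") %in% sel), 1L)
  expect_identical(stage2_combined_select(pop, y, list()), character())
})

test_that("stage 3 finds an exact triple signal and respects its guards", {
  ff <- make_full_factorial(3)
  x <- ff$geno
  y <- 0.5 * x[, 1] + x[, 1] * x[, 2] * x[, 3]
  names(y) <- rownames(x)
  d <- build_design(ff, colnames(x))
  pruned <- stage3_interaction_select(d, y, max_params = 8)
  expect_true("F1:F2:F3" %in% pruned$terms$term)
  tr <- attr(pruned, "stepwise_trace")
  expect_true(all(tr$aic_after < tr$aic_before))  # strict AIC descent

  # additive terms are always retained
  expect_true(all(c("F1", "F2", "F3") %in% pruned$terms$term))

  # candidate pool empty (p < 2): design returned unchanged
  d1 <- build_design(ff, "F1")
  same <- stage3_interaction_select(d1, y)
  expect_identical(same$terms$term, d1$terms$term)

  expect_error(stage3_interaction_select(d, y, max_params = 3),
               class = "te_config_error")
})

test_that("total aaa sums retained triples with Bonferroni thresholds", {
  fake_fit <- function(p_triples, est_triples, n_pairs = 3L,
                       n_cand = NULL) {
    k <- length(p_triples)
    co <- data.frame(
      term = c("(Intercept)", "A", "B", "C",
               paste0("Z", seq_len(n_pairs)),
               paste0("W", seq_len(k))),
      order = c(0L, 1L, 1L, 1L, rep(2L, n_pairs), rep(3L, k)),
      markers = "", estimate = c(rep(0, 4 + n_pairs), est_triples),
      se = 1, t = 0,
      p_value = c(rep(0.5, 4 + n_pairs), p_triples),
      dropped = FALSE, stringsAsFactors = FALSE
    )
    structure(list(coefficients = co, residual_variance = 1,
                   df_residual = 10, rss = 10, aic = 0, rank_ok = TRUE,
                   dropped_terms = character(), n = 20,
                   n_interaction_candidates = n_cand),
              class = "fit_result")
  }
  # one triple, p = 1e-9, m = 4 interaction terms, alpha 0.05: significant
  est <- total_aaa_genotypic(fake_fit(1e-9, 0.8), alpha = 0.05,
                             m_rule = "model")
  expect_identical(est$m_tests, 4L)
  expect_true(est$per_triple$significant)
  expect_identical(est$aaa_g, 0.8)
  expect_false(est$ns_flag)

  # same p-value fails a stricter candidates denominator
  est2 <- total_aaa_genotypic(fake_fit(0.02, 0.8, n_cand = 10L),
                              m_rule = "candidates")
  expect_identical(est2$m_tests, 10L)
  expect_false(est2$per_triple$significant)
  expect_true(est2$ns_flag)
  expect_identical(est2$aaa_g, 0.8)  # the sum is reported regardless

  # cancellation: +0.5 and -0.5 triples sum to zero
  est3 <- total_aaa_genotypic(fake_fit(c(1e-9, 1e-9), c(0.5, -0.5)))
  expect_identical(est3$aaa_g, 0)
  expect_identical(est3$n_significant_aaa, 2L)

  # sum is invariant under term reordering
  est4 <- total_aaa_genotypic(fake_fit(c(1e-9, 1e-9), c(-0.5, 0.5)))
  expect_identical(est4$aaa_g, est3$aaa_g)
})

test_that("the symmetric contrast vanishes for a pure triple on the factorial", {
  ff <- make_full_factorial(3)
  x <- ff$geno
  y <- x[, 1] * x[, 2] * x[, 3]
  names(y) <- rownames(x)
  cc <- contrast_aaa(ff, y, list(c("F1", "F2", "F3")))
  expect_identical(cc$total, 0)
  expect_identical(cc$total_difference, 1)

  # constant trait: zero under both forms
  y0 <- rep(5, 8); names(y0) <- rownames(x)
  cc0 <- contrast_aaa(ff, y0, list(c("F1", "F2", "F3")))
  expect_identical(cc0$total, 0)
  expect_identical(cc0$total_difference, 0)

  # pairwise-only signal leaks into the symmetric triple contrast
  y12 <- x[, 1] * x[, 2]; names(y12) <- rownames(x)
  cc12 <- contrast_aaa(ff, y12, list(c("F1", "F2", "F3")))
  expect_identical(cc12$total, 1)

  err <- expect_error(
    contrast_aaa(ff, y, list(c("F1", "F2", "F2"))),
    class = "te_config_error")
})

test_that("noise-free architectures are recovered exactly end to end", {
  cfg <- sim_config(
    n_lines = 120,
    chromosomes = lapply(1:3, function(i) {
      list(name = paste0("C", i), n_markers = 5, spacing_cM = 20)
    }),
    effects = list(
      list(markers = "C1_M03", value = 1.0),
      list(markers = "C2_M03", value = -0.8),
      list(markers = "C3_M03", value = 0.9),
      list(markers = c("C1_M03", "C2_M03", "C3_M03"), value = 0.6)
    ),
    mu = 2, sigma_e = 0, missing_rate = 0, seed = 608
  )
  pop <- simulate_population(cfg)
  y <- pop$pheno$T1
  names(y) <- rownames(pop$pheno)
  res <- estimate_aaa_genotypic(pop, y)
  expect_equal(res$estimate$aaa_g, 0.6, tolerance = 1e-8)
  expect_identical(res$estimate$n_significant_aaa, 1L)
})
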