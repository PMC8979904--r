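# Shared fixtures: small hand-written populations and the standard
# simulation configuration used by the recovery / null studies
# (150 lines, 3 chromosomes x 20 markers at 10 cM, three additive
# anchors of 1.0 on the middle markers, optional triple effect on them).

tiny_population <- function() {
  map <- linkage_map(c("M1", "M2"), c("1H", "1H"), c(0, 10))
  geno <- matrix(c(1, -1, 1, -1, 1, 1), nrow = 3,
                 dimnames = list(c("La", "Lb", "Lc"), c("M1", "M2")))
  pheno <- data.frame(GY.E1 = c(10, 12, 14), row.names = c("La", "Lb", "Lc"))
  dh_population(geno, map, pheno)
}

anchor_triple_config <- function(seed, delta = 0.8) {
  true_mk <- c("C1_M10", "C2_M10", "C3_M10")
  effects <- list(
    list(markers = "C1_M10", value = 1.0),
    list(markers = "C2_M10", value = 1.0),
    list(markers = "C3_M10", value = 1.0)
  )
  if (delta != 0) {
    effects <- c(effects, list(list(markers = true_mk, value = delta)))
  }
  sim_config(
    n_lines = 150,
    chromosomes = lapply(1:3, function(i) {
      list(name = paste0("C", i), n_markers = 20, spacing_cM = 10)
    }),
    effects = effects, mu = 0, sigma_e = 1, missing_rate = 0, seed = seed
  )
}

true_triple_id <- "C1_M10:C2_M10:C3_M10"

# model_design wrapper around an arbitrary numeric matrix (intercept plus
# main-effect-like columns), for fitting tests that do not need genotypes
raw_design <- function(G) {
  terms <- data.frame(
    term = colnames(G),
    order = c(0L, rep(1L, ncol(G) - 1L)),
    markers = c("", colnames(G)[-1L]),
    stringsAsFactors = FALSE
  )
  structure(list(G = G, terms = terms,
                 selected_markers = colnames(G)[-1L], n = nrow(G)),
            class = "model_design")
}

# independent OLS oracle: brute-force normal equations
normal_equation_solve <- function(G, y) {
  solve(crossprod(G), crossprod(G, y))[, 1L]
}
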