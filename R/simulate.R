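# Synthetic DH population generator: Markov-chain gametes along each
# chromosome under the Haldane map function, additive / pairwise / triple
# genetic effects, Gaussian residual noise, and sporadic missing genotypes.

#' Build a simulation configuration
#'
#' @param n_lines number of DH lines (>= 2).
#' @param chromosomes list describing the map; each element is a list with
#'   `name`, and either `n_markers` + `spacing_cM` (evenly spaced markers
#'   starting at 0 cM) or explicit `positions` (cM).
#' @param effects list of genetic effects; each element is a list with
#'   `markers` (1-3 marker ids) and `value` (trait units).  One marker id
#'   gives an additive effect, two a pairwise (aa) interaction, three a
#'   triple (aaa) interaction.
#' @param mu general mean (trait units).
#' @param sigma_e residual standard deviation (>= 0).
#' @param missing_rate fraction of genotype entries masked as missing, in
#'   `[0, 1)`.
#' @param seed integer RNG seed; every downstream draw is reproducible
#'   from it.
#' @param traits optional named list for multi-trait simulation; each
#'   element is a list with `mu`, `sigma_e` and `effects` overriding the
#'   top-level values.  Element names become trait ids.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_lines, chromosomes, effects = list(), mu = 0,
                       sigma_e = 1, missing_rate = 0, seed = 1,
                       traits = NULL) {
  if (n_lines < 2L) te_stop("te_config_error", "n_lines must be >= 2")
  if (sigma_e < 0) te_stop("te_config_error", "sigma_e must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    te_stop("te_config_error", "missing_rate must be in [0, 1)")
  }
  cfg <- structure(
    list(n_lines = as.integer(n_lines), chromosomes = chromosomes,
         effects = effects, mu = mu, sigma_e = sigma_e,
         missing_rate = missing_rate, seed = as.integer(seed),
         traits = traits),
    class = "sim_config"
  )
  map <- .map_from_config(cfg)
  for (eff in .all_effects(cfg)) {
    unknown <- setdiff(eff$markers, map$marker)
    if (length(unknown) > 0L) {
      te_stop("te_config_error", "effect references unknown marker(s): ",
              paste(unknown, collapse = ", "))
    }
  }
  cfg
}

.all_effects <- function(cfg) {
  effs <- cfg$effects
  for (tr in cfg$traits) effs <- c(effs, tr$effects)
  effs
}

.map_from_config <- function(cfg) {
  rows <- lapply(cfg$chromosomes, function(ch) {
    pos <- if (!is.null(ch$positions)) as.numeric(ch$positions)
    else seq(0, by = ch$spacing_cM, length.out = ch$n_markers)
    data.frame(
      marker = sprintf("%s_M%02d", ch$name, seq_along(pos)),
      chromosome = ch$name, position_cM = pos,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  linkage_map(df$marker, df$chromosome, df$position_cM)
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the arguments of [sim_config()]: scalar keys
#' `n_lines`, `mu`, `sigma_e`, `missing_rate`, `seed`, plus nested lists
#' `chromosomes`, `effects` and optionally `traits`.
#'
#' @param path path to a YAML configuration file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) te_stop("te_io_error", "config not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}

# One chromosome of DH gametes: first marker +/-1 with probability 1/2,
# each subsequent marker flips with the Haldane recombination fraction of
# the inter-marker gap (Markov chain, no interference).
.sim_chromosome <- function(n, positions) {
  m <- length(positions)
  x <- matrix(0, n, m)
  x[, 1L] <- sample(c(-1, 1), n, replace = TRUE)
  if (m > 1L) {
    r <- haldane_r(diff(positions))
    for (j in 2:m) {
      flip <- stats::runif(n) < r[j - 1L]
      x[, j] <- ifelse(flip, -x[, j - 1L], x[, j - 1L])
    }
  }
  x
}

.sim_geno_matrix <- function(cfg, map) {
  n <- cfg$n_lines
  blocks <- lapply(unique(map$chromosome), function(chr) {
    .sim_chromosome(n, map$position_cM[map$chromosome == chr])
  })
  geno <- do.call(cbind, blocks)
  dimnames(geno) <- list(sprintf("L%04d", seq_len(n)), map$marker)
  geno
}

#' Simulate DH genotypes on a linkage map
#'
#' Draws each line's genotype as independent Markov chains over
#' `{-1, +1}` along each chromosome (equal 1:1 segregation at every
#' marker, Haldane recombination between adjacent markers, independent
#' chromosomes), then masks entries as missing at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param mask mask missing entries (default `TRUE`); set `FALSE` to get
#'   the complete matrix, e.g. before trait generation.
#' @return A [dh_population()] with genotypes and map, no traits.
#' @export
simulate_genotypes <- function(cfg, mask = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- .map_from_config(cfg)
  geno <- .sim_geno_matrix(cfg, map)
  if (mask && cfg$missing_rate > 0) {
    hide <- stats::runif(length(geno)) < cfg$missing_rate
    geno[hide] <- NA_real_
  }
  dh_population(geno, map)
}

.trait_values <- function(geno, mu, sigma_e, effects) {
  n <- nrow(geno)
  y <- rep(mu, n)
  for (eff in effects) {
    unknown <- setdiff(eff$markers, colnames(geno))
    if (length(unknown) > 0L) {
      te_stop("te_config_error", "effect references unknown marker(s): ",
              paste(unknown, collapse = ", "))
    }
    prod_col <- apply(geno[, eff$markers, drop = FALSE], 1L, prod)
    y <- y + eff$value * prod_col
  }
  y <- y + stats::rnorm(n, 0, sigma_e)
  names(y) <- rownames(geno)
  y
}

#' Simulate a trait from complete genotypes
#'
#' Generates `y = mu + sum(beta * x) + sum(gamma * x x') +
#' sum(delta * x x' x'') + e` with `e ~ N(0, sigma_e^2)` i.i.d., using the
#' effects in `cfg`.  Genotypes must be complete (simulate unmasked, or
#' impute first), so the true genetic effects are well defined.
#'
#' @param pop a [dh_population()] with complete genotypes.
#' @param cfg a [sim_config()] carrying `mu`, `sigma_e` and `effects`.
#' @return Named numeric trait vector.
#' @export
simulate_trait <- function(pop, cfg) {
  stopifnot(inherits(pop, "dh_population"), inherits(cfg, "sim_config"))
  .require_complete(pop$geno)
  .trait_values(pop$geno, cfg$mu, cfg$sigma_e, cfg$effects)
}

#' Simulate a complete DH population with traits
#'
#' Runs the full generative model in one reproducible stream: complete
#' genotypes, then one trait per configuration entry, then missing-value
#' masking of the genotypes (masking last, so the true genetic
#' architecture underlying each trait is well defined).
#'
#' @param cfg a [sim_config()].  If `cfg$traits` is `NULL` a single trait
#'   named `"T1"` is generated from the top-level `mu`/`sigma_e`/`effects`.
#' @return A [dh_population()] with phenotypes attached.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- .map_from_config(cfg)
  geno <- .sim_geno_matrix(cfg, map)
  traits <- cfg$traits
  if (is.null(traits)) {
    traits <- list(T1 = list(mu = cfg$mu, sigma_e = cfg$sigma_e,
                             effects = cfg$effects))
  }
  pheno <- data.frame(row.names = rownames(geno))
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    pheno[[nm]] <- .trait_values(
      geno,
      if (is.null(tr$mu)) cfg$mu else tr$mu,
      if (is.null(tr$sigma_e)) cfg$sigma_e else tr$sigma_e,
      if (is.null(tr$effects)) cfg$effects else tr$effects
    )
  }
  if (cfg$missing_rate > 0) {
    hide <- stats::runif(length(geno)) < cfg$missing_rate
    geno[hide] <- NA_real_
  }
  dh_population(geno, map, pheno)
}

#' Full-factorial population of unlinked markers
#'
#' Enumerates all `2^k` combinations of `k` markers coded -1/+1, one
#' marker per pseudo-chromosome (unlinked).  All main-effect, pairwise and
#' triple product columns are mutually orthogonal with zero column sums --
#' the exact-fit oracle fixture for the regression model.
#'
#' @param k number of markers, 2 to 4.
#' @return A [dh_population()] with `2^k` lines and no traits.
#' @examples
#' make_full_factorial(3)
#' @export
make_full_factorial <- function(k) {
  if (!is.numeric(k) || k < 2 || k > 4) {
    te_stop("te_config_error", "k must be in 2..4")
  }
  k <- as.integer(k)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  dimnames(grid) <- list(sprintf("L%02d", seq_len(2^k)),
                         sprintf("F%d", seq_len(k)))
  map <- linkage_map(colnames(grid), paste0("C", seq_len(k)),
                     rep(0, k))
  dh_population(grid, map)
}

#' Preset simulation configurations emulating the barley DH populations
#'
#' `"SxM"` emulates a Steptoe x Morex-like population: 150 lines, 223
#' markers on 7 chromosomes at 5.66 cM mean spacing.  `"HxT"` emulates a
#' Harrington x TR306-like population: 145 lines, 127 markers on 7
#' chromosomes at 10.62 cM mean spacing.  Both carry a handful of additive
#' QTL plus one pairwise and one triple interaction, unit residual SD and
#' 2% sporadic missing genotypes; pass `effects`/`traits` to override.
#'
#' @param name `"SxM"` or `"HxT"`.
#' @param seed RNG seed.
#' @param ... overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("SxM", "HxT"), seed = 1, ...) {
  name <- match.arg(name)
  shape <- switch(name,
    SxM = list(n_lines = 150L, sizes = c(32L, 32L, 32L, 32L, 32L, 32L, 31L),
               spacing = 5.66),
    HxT = list(n_lines = 145L, sizes = c(19L, rep(18L, 6L)),
               spacing = 10.62)
  )
  chroms <- lapply(seq_along(shape$sizes), function(i) {
    list(name = paste0(i, "H"), n_markers = shape$sizes[i],
         spacing_cM = shape$spacing)
  })
  mid <- function(chr) {
    sprintf("%dH_M%02d", chr, ceiling(shape$sizes[chr] / 2))
  }
  defaults <- list(
    n_lines = shape$n_lines, chromosomes = chroms,
    effects = list(
      list(markers = mid(1), value = 1.0),
      list(markers = mid(2), value = 0.8),
      list(markers = mid(3), value = -0.7),
      list(markers = mid(4), value = 0.6),
      list(markers = mid(5), value = 0.5),
      list(markers = c(mid(1), mid(2)), value = 0.4),
      list(markers = c(mid(1), mid(2), mid(3)), value = 0.5)
    ),
    mu = 10, sigma_e = 1, missing_rate = 0.02, seed = seed
  )
  override <- list(...)
  defaults[names(override)] <- override
  do.call(sim_config, defaults)
}
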