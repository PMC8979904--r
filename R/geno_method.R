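# Genotypic estimation of the total aaa interaction effect: marker-regression
# model y = 1*mu + X*beta + Z*gamma + W*delta + e, with X the selected marker
# columns, Z all pairwise products and W all triple products of those columns;
# three-stage stepwise-AIC selection; OLS fit; Bonferroni-corrected
# significance of triple terms; and the balanced-design contrast form.

# Gaussian AIC, identical to stats::AIC on an lm fit: the (k+1)-th parameter
# is the residual variance.  Only differences matter in the stepwise search,
# but matching the stats convention keeps fits comparable across tools.
.gauss_aic <- function(rss, n, k) {
  if (rss <= 0) return(-Inf)
  n * log(2 * pi) + n * log(rss / n) + n + 2 * (k + 1)
}

.rss_rank <- function(X, y) {
  f <- .lm.fit(X, y)
  list(rss = sum(f$residuals^2), rank = f$rank)
}

# Bidirectional stepwise search by AIC.  `base` columns (intercept and any
# forced terms) are always retained; `candidates` may be added or dropped one
# at a time; each accepted move must strictly decrease AIC.  Additions are
# refused when they would push the fitted-parameter count past `max_params`.
.step_aic <- function(y, base, candidates, start = character(),
                      max_params = Inf, verbose = FALSE) {
  n <- length(y)
  incl <- intersect(colnames(candidates), start)
  cur <- .rss_rank(cbind(base, candidates[, incl, drop = FALSE]), y)
  cur_aic <- .gauss_aic(cur$rss, n, cur$rank)
  steps <- list()
  tol <- 1e-8
  repeat {
    pool <- setdiff(colnames(candidates), incl)
    best_aic <- Inf
    best_move <- NULL
    if (cur$rank + 1 <= max_params) {
      for (j in pool) {
        f <- .rss_rank(cbind(base, candidates[, c(incl, j), drop = FALSE]), y)
        a <- .gauss_aic(f$rss, n, f$rank)
        if (a < best_aic) {
          best_aic <- a
          best_move <- c("add", j)
        }
      }
    }
    for (j in incl) {
      keep <- setdiff(incl, j)
      f <- .rss_rank(cbind(base, candidates[, keep, drop = FALSE]), y)
      a <- .gauss_aic(f$rss, n, f$rank)
      if (a < best_aic) {
        best_aic <- a
        best_move <- c("drop", j)
      }
    }
    if (is.null(best_move) || best_aic >= cur_aic - tol) break
    if (best_move[1L] == "add") {
      incl <- c(incl, best_move[2L])
    } else {
      incl <- setdiff(incl, best_move[2L])
    }
    steps[[length(steps) + 1L]] <- data.frame(
      action = best_move[1L], term = best_move[2L],
      aic_before = cur_aic, aic_after = best_aic,
      stringsAsFactors = FALSE
    )
    if (verbose) {
      message(sprintf("  step %s %s: AIC %.3f -> %.3f", best_move[1L],
                      best_move[2L], cur_aic, best_aic))
    }
    cur <- .rss_rank(cbind(base, candidates[, incl, drop = FALSE]), y)
    cur_aic <- best_aic
  }
  trace <- if (length(steps) > 0L) do.call(rbind, steps) else
    data.frame(action = character(), term = character(),
               aic_before = numeric(), aic_after = numeric())
  list(selected = intersect(colnames(candidates), incl), aic = cur_aic,
       trace = trace)
}

.require_complete <- function(geno) {
  if (anyNA(geno)) {
    te_stop("te_domain_error",
            "genotypes contain missing values; run impute_flanking() first")
  }
}

#' Stage 1: per-chromosome stepwise-AIC marker screening
#'
#' For each chromosome separately, runs bidirectional stepwise selection by
#' AIC over additive (main-effect) terms of that chromosome's markers,
#' starting from the intercept-only model.  The survivors from all
#' chromosomes form the candidate pool for [stage2_combined_select()].
#'
#' @param pop a [dh_population()] with imputed (complete) genotypes.
#' @param y named numeric trait vector aligned to the population's lines.
#' @param verbose print each stepwise move.
#' @return Named list (one element per chromosome) of surviving marker ids.
#' @export
stage1_chromosome_select <- function(pop, y, verbose = FALSE) {
  stopifnot(inherits(pop, "dh_population"))
  .require_complete(pop$geno)
  n <- nrow(pop$geno)
  base <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  out <- list()
  for (chr in unique(pop$map$chromosome)) {
    mk <- pop$map$marker[pop$map$chromosome == chr]
    cand <- pop$geno[, mk, drop = FALSE]
    sds <- apply(cand, 2L, stats::sd)
    if (all(sds == 0)) {
      warning("chromosome ", chr, ": all markers have zero variance")
      out[[chr]] <- character()
      next
    }
    out[[chr]] <- .step_aic(y, base, cand, verbose = verbose)$selected
  }
  out
}

#' Stage 2: pooled stepwise-AIC marker selection
#'
#' Pools the per-chromosome survivors of [stage1_chromosome_select()] into
#' one candidate group and repeats bidirectional stepwise AIC selection over
#' additive terms, again from the intercept-only model.  The result is the
#' marker set that defines the regression model's main-effect block.
#'
#' @inheritParams stage1_chromosome_select
#' @param stage1_survivors output of [stage1_chromosome_select()] (or any
#'   character vector / list of marker ids).
#' @return Character vector of selected marker ids, in map order.
#' @export
stage2_combined_select <- function(pop, y, stage1_survivors,
                                   verbose = FALSE) {
  stopifnot(inherits(pop, "dh_population"))
  .require_complete(pop$geno)
  pool <- unique(unlist(stage1_survivors, use.names = FALSE))
  pool <- pop$map$marker[pop$map$marker %in% pool]
  if (length(pool) == 0L) return(character())
  n <- nrow(pop$geno)
  base <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  sel <- .step_aic(y, base, pop$geno[, pool, drop = FALSE],
                   verbose = verbose)$selected
  pop$map$marker[pop$map$marker %in% sel]
}

#' Build the full interaction design for selected markers
#'
#' Constructs the model matrix of the marker-regression model: an intercept
#' column, the selected marker columns (X block, additive effects), all
#' pairwise products of distinct selected markers (Z block, additive x
#' additive effects), and all triple products (W block, additive x additive
#' x additive effects).  Products are formed only among the selected
#' markers, reflecting the assumption that epistatic effects involve only
#' loci with significant additive effects.  Terms are ordered canonically
#' by map position, so `(A,B,C)` and `(C,A,B)` denote the same term.
#'
#' @param pop a [dh_population()] with complete genotypes.
#' @param selected_markers character vector of marker ids (typically from
#'   [stage2_combined_select()]).
#' @return Object of class `model_design`: list with the model matrix `G`,
#'   a `terms` data frame (`term`, `order`, `markers`), and
#'   `selected_markers`.
#' @export
build_design <- function(pop, selected_markers) {
  stopifnot(inherits(pop, "dh_population"))
  .require_complete(pop$geno)
  unknown <- setdiff(selected_markers, pop$map$marker)
  if (length(unknown) > 0L) {
    te_stop("te_alignment_error", "unknown marker(s): ",
            paste(unknown, collapse = ", "))
  }
  sel <- pop$map$marker[pop$map$marker %in% selected_markers]
  n <- nrow(pop$geno)
  p <- length(sel)
  cols <- list(`(Intercept)` = rep(1, n))
  terms <- data.frame(term = "(Intercept)", order = 0L,
                      markers = "", stringsAsFactors = FALSE)
  for (m in sel) {
    cols[[m]] <- pop$geno[, m]
    terms <- rbind(terms, data.frame(term = m, order = 1L, markers = m))
  }
  add_products <- function(k) {
    for (idx in seq_len(ncol(combos <- utils::combn(p, k)))) {
      mk <- sel[combos[, idx]]
      nm <- paste(mk, collapse = ":")
      cols[[nm]] <<- apply(pop$geno[, mk, drop = FALSE], 1L, prod)
      terms <<- rbind(terms, data.frame(term = nm, order = k,
                                        markers = nm))
    }
  }
  if (p >= 2L) add_products(2L)
  if (p >= 3L) add_products(3L)
  G <- do.call(cbind, cols)
  colnames(G) <- names(cols)
  rownames(G) <- rownames(pop$geno)
  structure(list(G = G, terms = terms, selected_markers = sel, n = n),
            class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  tab <- table(factor(x$terms$order, levels = 0:3))
  cat("Model design: ", x$n, " lines; terms: intercept + ", tab[["1"]],
      " additive + ", tab[["2"]], " pairwise + ", tab[["3"]],
      " triple\n", sep = "")
  invisible(x)
}

#' Stage 3: stepwise-AIC selection of interaction terms
#'
#' Starting from the full additive model (intercept plus all selected
#' markers, which are always retained), runs bidirectional stepwise AIC
#' with the pairwise (Z) and triple (W) product terms as the candidate
#' pool.  The total number of fitted parameters is capped at `max_params`
#' (default `n - 10`) to preserve residual degrees of freedom when the
#' combinatorial candidate pool is large relative to the line count.
#'
#' @param design a [build_design()] result.
#' @param y named numeric trait vector.
#' @param max_params cap on total fitted coefficients (intercept included).
#' @param verbose print each stepwise move.
#' @return A pruned `model_design` containing the intercept, all additive
#'   terms and the selected interaction terms; attributes
#'   `n_interaction_candidates` (size of the candidate pool) and
#'   `stepwise_trace` (data frame of accepted moves with AIC before/after)
#'   record the search.
#' @export
stage3_interaction_select <- function(design, y, max_params = NULL,
                                      verbose = FALSE) {
  stopifnot(inherits(design, "model_design"))
  n <- design$n
  p <- length(design$selected_markers)
  inter <- design$terms$term[design$terms$order >= 2L]
  if (length(inter) == 0L) {
    # p < 2: nothing to select, the design is returned unchanged
    attr(design, "n_interaction_candidates") <- 0L
    attr(design, "stepwise_trace") <- data.frame(
      action = character(), term = character(),
      aic_before = numeric(), aic_after = numeric())
    return(design)
  }
  if (is.null(max_params)) max_params <- n - 10L
  if (max_params < p + 1L) {
    te_stop("te_config_error", "max_params (", max_params,
            ") below additive model size (", p + 1L, ")")
  }
  base_cols <- design$terms$term[design$terms$order <= 1L]
  res <- .step_aic(y, design$G[, base_cols, drop = FALSE],
                   design$G[, inter, drop = FALSE],
                   max_params = max_params, verbose = verbose)
  keep <- c(base_cols, res$selected)
  keep <- design$terms$term[design$terms$term %in% keep]
  pruned <- design
  pruned$G <- design$G[, keep, drop = FALSE]
  pruned$terms <- design$terms[design$terms$term %in% keep, , drop = FALSE]
  rownames(pruned$terms) <- NULL
  attr(pruned, "n_interaction_candidates") <- length(inter)
  attr(pruned, "stepwise_trace") <- res$trace
  pruned
}

#' Ordinary least-squares fit of a model design
#'
#' Solves the normal equations for the design by pivoted QR decomposition.
#' If the model matrix is rank deficient, aliased columns are dropped
#' deterministically (the first linearly independent column in canonical
#' term order is kept) and recorded in `dropped_terms` with `rank_ok =
#' FALSE`.  Per-term t statistics and two-sided p values use the residual
#' degrees of freedom; the AIC is the Gaussian log-likelihood form, equal
#' to `stats::AIC()` on the corresponding `lm` fit.
#'
#' @param design a `model_design`.
#' @param y named numeric trait vector, `length(y) >= ncol(design$G)`.
#' @return Object of class `fit_result`: list with `coefficients` (data
#'   frame: `term`, `order`, `markers`, `estimate`, `se`, `t`, `p_value`),
#'   `residual_variance`, `df_residual`, `rss`, `aic`, `rank_ok`,
#'   `dropped_terms`, `n`.
#' @export
fit_ols <- function(design, y) {
  stopifnot(inherits(design, "model_design"))
  G <- design$G
  n <- nrow(G)
  if (length(y) != n) {
    te_stop("te_alignment_error", "y length ", length(y),
            " does not match design rows ", n)
  }
  if (ncol(G) > n) {
    te_stop("te_domain_error", "more model columns (", ncol(G),
            ") than observations (", n, ")")
  }
  fit <- stats::lm.fit(G, y)
  rank <- fit$rank
  piv <- fit$qr$pivot
  kept_idx <- sort(piv[seq_len(rank)])
  dropped <- setdiff(colnames(G), colnames(G)[kept_idx])
  rss <- sum(fit$residuals^2)
  df <- n - rank
  sigma2 <- if (df > 0) rss / df else NA_real_
  R <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
  xtx_inv_diag <- rep(NA_real_, ncol(G))
  xtx_inv_diag[piv[seq_len(rank)]] <- diag(chol2inv(R))
  est <- fit$coefficients
  se <- sqrt(sigma2 * xtx_inv_diag)
  tval <- est / se
  # exact fits: zero residual variance makes nonzero effects certain
  if (!is.na(sigma2) && sigma2 == 0) {
    tval <- ifelse(est == 0, 0, sign(est) * Inf)
  }
  pval <- if (df > 0) 2 * stats::pt(-abs(tval), df) else
    rep(NA_real_, ncol(G))
  coefs <- data.frame(
    term = colnames(G),
    order = design$terms$order[match(colnames(G), design$terms$term)],
    markers = design$terms$markers[match(colnames(G), design$terms$term)],
    estimate = unname(est),
    se = unname(se),
    t = unname(tval),
    p_value = unname(pval),
    stringsAsFactors = FALSE
  )
  coefs$dropped <- coefs$term %in% dropped
  structure(
    list(coefficients = coefs, residual_variance = sigma2,
         df_residual = df, rss = rss,
         aic = .gauss_aic(rss, n, rank), rank_ok = length(dropped) == 0L,
         dropped_terms = dropped, n = n,
         n_interaction_candidates = {
           # without a stage-3 search every interaction term in the
           # design was a candidate, so the pool is the design itself
           nc <- attr(design, "n_interaction_candidates")
           if (is.null(nc)) sum(design$terms$order >= 2L) else nc
         }),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("OLS fit: n = ", x$n, ", ", sum(!x$coefficients$dropped),
      " terms, AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  if (!x$rank_ok) {
    cat("  aliased terms dropped:",
        paste(x$dropped_terms, collapse = ", "), "\n")
  }
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Total genotypic aaa effect with Bonferroni-corrected significance
#'
#' Sums the estimated coefficients of all triple-product (aaa) terms
#' retained in the final model.  Each triple is tested at the
#' Bonferroni-corrected per-test level `alpha / m`.  By default `m` is
#' the number of interaction candidates scored during stage-3 selection
#' (`m_rule = "candidates"`), which corrects for the selection
#' multiplicity: stepwise selection inflates the t statistics of the
#' terms it keeps, and correcting only over the survivors does not
#' control the family-wise error over the pool that was actually
#' searched.  The alternative `m_rule = "model"` corrects only over the
#' interaction (pairwise + triple) terms present in the final model.
#' When no triple term is significant the estimate is reported as NS
#' (non-significant) by the comparison layer.
#'
#' @param fit a [fit_ols()] result.
#' @param alpha family-wise significance level (default 0.05).
#' @param m_rule `"candidates"` (default) or `"model"` (see above).
#' @return Object of class `genotypic_estimate`: list with `aaa_g`,
#'   `per_triple` (data frame: `markers`, `estimate`, `se`, `t`,
#'   `p_value`, `significant`), `n_markers_included`,
#'   `n_significant_aaa`, `ns_flag`, `m_tests`, `alpha`.
#' @export
total_aaa_genotypic <- function(fit, alpha = 0.05,
                                m_rule = c("candidates", "model")) {
  stopifnot(inherits(fit, "fit_result"))
  m_rule <- match.arg(m_rule)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    te_stop("te_config_error", "alpha must be in (0, 1)")
  }
  co <- fit$coefficients
  inter <- co[!co$dropped & co$order >= 2L, , drop = FALSE]
  triples <- co[!co$dropped & co$order == 3L, , drop = FALSE]
  m <- if (m_rule == "model") nrow(inter) else {
    nc <- fit$n_interaction_candidates
    # fits built without a selection step scored exactly the fitted
    # interaction terms, so the two rules coincide
    if (is.null(nc) || is.na(nc)) nrow(inter) else nc
  }
  sig <- if (nrow(triples) > 0L && m > 0L) {
    !is.na(triples$p_value) & triples$p_value < alpha / m
  } else {
    logical(0)
  }
  per_triple <- data.frame(
    markers = triples$markers, estimate = triples$estimate,
    se = triples$se, t = triples$t, p_value = triples$p_value,
    significant = sig, stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(aaa_g = sum(triples$estimate),
         per_triple = per_triple,
         n_markers_included = sum(!co$dropped & co$order == 1L),
         n_significant_aaa = sum(sig),
         ns_flag = sum(sig) == 0L,
         m_tests = m, alpha = alpha),
    class = "genotypic_estimate"
  )
}

#' @export
print.genotypic_estimate <- function(x, ...) {
  if (x$ns_flag) {
    cat(sprintf("Total aaa (genotypic): NS (%d | %d)\n",
                x$n_markers_included, x$n_significant_aaa))
  } else {
    cat(sprintf("Total aaa (genotypic): %.4g (%d | %d)\n", x$aaa_g,
                x$n_markers_included, x$n_significant_aaa))
  }
  invisible(x)
}

.normalize_triples <- function(triples) {
  if (inherits(triples, "genotypic_estimate")) {
    triples <- triples$per_triple$markers
  }
  if (is.data.frame(triples)) triples <- triples$markers
  if (is.character(triples)) triples <- strsplit(triples, ":", fixed = TRUE)
  lapply(triples, function(t) {
    if (length(t) != 3L || anyDuplicated(t)) {
      te_stop("te_config_error", "each triple needs 3 distinct markers, got ",
              paste(t, collapse = ":"))
    }
    as.character(t)
  })
}

#' Balanced-design contrast form of the aaa effect
#'
#' Under the simplifying assumptions of unlinked markers and exact 1:1
#' segregation, the genotypic total aaa estimate reduces to a sum over
#' triples of `(ybar_plus + ybar_minus) / 2 - ybar`, where `ybar_plus`
#' (`ybar_minus`) is the trait mean over lines whose three markers are all
#' +1 (all -1) and `ybar` is the overall mean.  This symmetric form is
#' computed exactly as printed; note that for a pure odd-order triple
#' effect on a balanced full factorial it vanishes, so the difference form
#' `(ybar_plus - ybar_minus) / 2` is additionally reported as a
#' diagnostic when `include_difference = TRUE`.
#'
#' @param pop a [dh_population()] with complete genotypes.
#' @param y named numeric trait vector.
#' @param triples triples of marker ids: a list of length-3 character
#'   vectors, a character vector of `"A:B:C"` strings, or a
#'   [total_aaa_genotypic()] result.
#' @param include_difference also compute the difference form.
#' @return Object of class `contrast_estimate`: list with `per_triple`
#'   (data frame: `markers`, `n_plus`, `n_minus`, `contrast`, and
#'   optionally `difference`), `total` (sum of symmetric contrasts) and
#'   optionally `total_difference`.
#' @export
contrast_aaa <- function(pop, y, triples, include_difference = TRUE) {
  stopifnot(inherits(pop, "dh_population"))
  .require_complete(pop$geno)
  triples <- .normalize_triples(triples)
  ybar <- mean(y)
  rows <- lapply(triples, function(mk) {
    unknown <- setdiff(mk, colnames(pop$geno))
    if (length(unknown) > 0L) {
      te_stop("te_alignment_error", "unknown marker(s) in triple ",
              paste(mk, collapse = ":"))
    }
    sub <- pop$geno[, mk, drop = FALSE]
    plus <- rowSums(sub > 0) == 3L
    minus <- rowSums(sub < 0) == 3L
    if (!any(plus) || !any(minus)) {
      te_stop("te_degenerate_error", "triple ", paste(mk, collapse = ":"),
              ": no lines with all markers ",
              if (!any(plus)) "+1" else "-1")
    }
    yp <- mean(y[plus])
    ym <- mean(y[minus])
    data.frame(markers = paste(mk, collapse = ":"),
               n_plus = sum(plus), n_minus = sum(minus),
               contrast = 0.5 * (yp + ym) - ybar,
               difference = 0.5 * (yp - ym),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  out <- list(per_triple = per, total = sum(per$contrast))
  if (include_difference) {
    out$total_difference <- sum(per$difference)
  } else {
    per$difference <- NULL
    out$per_triple <- per
  }
  structure(out, class = "contrast_estimate")
}

#' One-call genotypic estimation pipeline for a single trait
#'
#' Convenience wrapper chaining [stage1_chromosome_select()],
#' [stage2_combined_select()], [build_design()],
#' [stage3_interaction_select()], [fit_ols()] and
#' [total_aaa_genotypic()].
#'
#' @inheritParams stage1_chromosome_select
#' @inheritParams stage3_interaction_select
#' @inheritParams total_aaa_genotypic
#' @return List with elements `estimate` (a `genotypic_estimate`), `fit`,
#'   `design` and `selected_markers`.
#' @export
estimate_aaa_genotypic <- function(pop, y, alpha = 0.05, max_params = NULL,
                                   m_rule = c("candidates", "model"),
                                   verbose = FALSE) {
  m_rule <- match.arg(m_rule)
  s1 <- stage1_chromosome_select(pop, y, verbose = verbose)
  sel <- stage2_combined_select(pop, y, s1, verbose = verbose)
  design <- build_design(pop, sel)
  design <- stage3_interaction_select(design, y, max_params = max_params,
                                      verbose = verbose)
  fit <- fit_ols(design, y)
  est <- total_aaa_genotypic(fit, alpha = alpha, m_rule = m_rule)
  list(estimate = est, fit = fit, design = design, selected_markers = sel)
}
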