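#' Simulate correlated traits with planted causal variants
#'
#' Each trait is built as fixed covariate effects + planted variant effects +
#' a GRM-structured polygenic term + residual noise correlated across traits.
#' Genetic variance is split between the planted causal variants (share
#' `prop_h2_causal`) and the polygenic background, and each realized
#' component is rescaled to its target so the per-trait heritability matches
#' `config$h2` up to the trait's unit variance. One trait is binarised by
#' thresholding its latent liability at the configured quantile (the
#' pregnancy-status analogue); downstream analysis treats it with the same
#' linear model, as is standard for binary traits in livestock GWAS.
#'
#' Traits are on a standardized (unit latent variance) scale; none of the
#' downstream statistics depend on trait units.
#'
#' @param geno A `geno_matrix` from [simulate_genotypes()].
#' @param config The [sim_config()] used to generate `geno`.
#' @param effects Optional tibble (`id`, `trait`, `beta`) planting exact
#'   per-allele effects in phenotypic-SD units. When supplied it replaces the
#'   random causal architecture and `h2` applies to the polygenic background
#'   only.
#' @return A list with `traits` (tibble: sample_id, one column per trait,
#'   fixed covariates year_of_birth, contemporary_group, age_at_joining) and
#'   `truth` (a `sim_truth` with `causal_variants` and `varcomp` tibbles).
#' @export
simulate_traits <- function(geno, config, effects = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  n <- length(geno$sample_ids)
  if (n != config$n_samples) {
    abort("`geno` and `config` disagree on the number of samples")
  }
  m <- nrow(geno$variants)
  k <- config$n_traits
  need <- config$n_causal_shared + k * config$n_causal_private
  if (is.null(effects) && need > m) {
    abort("more causal variants requested than variants available")
  }
  withr::with_seed(sub_seed(config$seed, 2L), {
    # planted causal architecture
    if (is.null(effects)) {
      picked <- sample.int(m, need)
      shared <- picked[seq_len(config$n_causal_shared)]
      private <- matrix(picked[config$n_causal_shared + seq_len(k * config$n_causal_private)],
                        ncol = k)
      effects <- dplyr::bind_rows(
        tidyr::expand_grid(idx = shared, trait = config$trait_names),
        purrr::map_dfr(seq_len(k), function(t) {
          tibble(idx = private[, t], trait = config$trait_names[t])
        })
      )
      effects$beta <- rnorm(nrow(effects))
      effects$id <- geno$variants$id[effects$idx]
      rescale_causal <- TRUE
    } else {
      effects <- as_tibble(effects)
      stopifnot(all(c("id", "trait", "beta") %in% names(effects)))
      effects$idx <- match(effects$id, geno$variants$id)
      if (anyNA(effects$idx)) abort("`effects` references unknown variant ids")
      rescale_causal <- FALSE
    }

    # polygenic background via the GRM (skipped when no trait needs it)
    L <- NULL
    if (any(config$h2 > 0)) {
      G <- compute_grm(geno, maf_min = 0)$values
      L <- chol(G + diag(1e-6, n))
    }

    scale_to <- function(v, target) {
      s <- stats::var(v)
      if (s > 0 && target > 0) v * sqrt(target / s) else v * 0
    }

    Rchol <- chol(config$residual_corr)
    E <- matrix(rnorm(n * k), n, k) %*% Rchol

    Y <- matrix(0, n, k, dimnames = list(geno$sample_ids, config$trait_names))
    varcomp <- tibble(trait = config$trait_names,
                      sigma_g2 = NA_real_, sigma_e2 = NA_real_)
    for (t in seq_len(k)) {
      h2 <- config$h2[t]
      eff_t <- effects[effects$trait == config$trait_names[t], ]
      causal <- if (nrow(eff_t)) {
        as.vector(geno$dosage[, eff_t$idx, drop = FALSE] %*% eff_t$beta)
      } else {
        numeric(n)
      }
      if (rescale_causal && nrow(eff_t)) {
        target_c <- h2 * config$prop_h2_causal
        sc <- if (stats::var(causal) > 0) sqrt(target_c / stats::var(causal)) else 0
        causal <- causal * sc
        effects$beta[effects$trait == config$trait_names[t]] <- eff_t$beta * sc
        var_poly <- h2 * (1 - config$prop_h2_causal)
      } else {
        var_poly <- h2
      }
      poly <- if (is.null(L)) numeric(n) else
        scale_to(drop(crossprod(L, rnorm(n))), var_poly)
      resid <- scale_to(E[, t], 1 - h2)
      Y[, t] <- causal + poly + resid
      varcomp$sigma_g2[t] <- stats::var(causal + poly)
      varcomp$sigma_e2[t] <- stats::var(resid)
    }

    # fixed covariates, added on top (removed by X downstream)
    yob <- sample(as.character(2014:2018), n, replace = TRUE)
    cg <- sample(sprintf("cg%d", 1:7), n, replace = TRUE)
    age_join <- rnorm(n, 400, 30)
    yob_eff <- setNames(rnorm(5, 0, 0.3), as.character(2014:2018))
    cg_eff <- setNames(rnorm(7, 0, 0.3), sprintf("cg%d", 1:7))
    for (t in seq_len(k)) {
      Y[, t] <- Y[, t] + yob_eff[yob] + cg_eff[cg] +
        0.002 * (age_join - mean(age_join))
    }

    # liability-threshold binary trait
    lt <- config$liability_trait
    if (!is.na(lt) && lt >= 1 && lt <= k) {
      thr <- quantile(Y[, lt], config$liability_threshold)
      Y[, lt] <- as.numeric(Y[, lt] > thr)
    }

    # optional missingness
    if (config$missing_prop > 0) {
      for (t in seq_len(k)) {
        Y[runif(n) < config$missing_prop, t] <- NA_real_
      }
    }

    traits <- tibble(sample_id = geno$sample_ids)
    for (t in seq_len(k)) traits[[config$trait_names[t]]] <- unname(Y[, t])
    traits$year_of_birth <- yob
    traits$contemporary_group <- cg
    traits$age_at_joining <- age_join

    truth <- structure(
      list(causal_variants = dplyr::select(effects, "id", "trait", "beta"),
           varcomp = dplyr::mutate(varcomp,
                                   h2 = .data$sigma_g2 / (.data$sigma_g2 + .data$sigma_e2))),
      class = "sim_truth")
    list(traits = traits, truth = truth)
  })
}
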