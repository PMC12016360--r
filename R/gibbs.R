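# Spike-and-slab Gibbs sampler over summary statistics with internal
# inference of heritability (h2) and polygenicity (p), plus the closed-form
# infinitesimal solver used as oracle and fallback.

#' Standardize marginal effects
#'
#' Converts per-probe marginal effects to the standardized scale the sampler
#' works on: `beta_std = (beta / se) / sqrt(n)`, i.e. the z-score over
#' `sqrt(n)`, whose sampling variance is approximately `1/n`. On synthetic
#' data this approximates the sample correlation between the standardized
#' probe and the phenotype.
#'
#' @param stats Summary-statistics tibble (`probe_id`, `beta`, `se`, `n`).
#' @return Tibble with `probe_id`, `beta_std`, `n`, in the input probe order.
#' @export
standardize_effects <- function(stats) {
  stats <- validate_summary_stats(stats)
  beta_std <- (stats$beta / stats$se) / sqrt(stats$n)
  bad <- which(!is.finite(beta_std))
  if (length(bad)) {
    stop_validation("non-finite standardized effect for probe(s): %s",
                    paste(head(stats$probe_id[bad], 5), collapse = ", "))
  }
  tibble(probe_id = stats$probe_id, beta_std = beta_std,
         n = as.integer(stats$n))
}

#' Moment estimator for the heritability initialization
#'
#' An LD-score-regression-style moment estimator: with per-probe chi-squared
#' statistics `chi2_j = n_j * beta_std_j^2` and correlation scores
#' `l_j = sum_k R_jk^2` (within block), returns
#' `M * (mean(chi2) - 1) / (mean(n) * mean(l))`.
#'
#' The estimate can legitimately be negative or zero — e.g. under a null, or
#' with ill-conditioned correlation blocks — in which case [ldpred_auto()]
#' refuses to start unless an explicit `h2_init` override is supplied (the
#' documented workaround sets it to `1e-5`).
#'
#' @param eff Standardized effects ([standardize_effects()]), aligned to
#'   `bcorr$probe_order`.
#' @param bcorr A `block_corr`.
#' @return Scalar heritability estimate (may be <= 0).
#' @export
estimate_h2_init <- function(eff, bcorr) {
  assert_probe_alignment(sort(eff$probe_id), sort(bcorr$probe_order),
                         "standardized effects", "correlation matrix")
  m <- nrow(eff)
  chi2 <- eff$n * eff$beta_std^2
  ell <- numeric(m)
  for (bl in bcorr$blocks) {
    ell[match(bl$probe_ids, eff$probe_id)] <- rowSums(bl$R^2)
  }
  m * (mean(chi2) - 1) / (mean(eff$n) * mean(ell))
}

#' Sampler configuration
#'
#' @param burn_in,n_iter Burn-in and retained sweep counts (>= 1).
#' @param p_init Initial polygenicity in `(0, 1]`.
#' @param h2_init Optional heritability override (> 0); required when the
#'   moment estimate is non-positive.
#' @param h2_floor Lower clamp applied to the heritability chain each sweep
#'   (default `1e-5`, the documented override value for a negative estimate).
#' @param seed Integer seed (mandatory; every run is reproducible).
#' @param sparse_output If `TRUE`, posterior means with inclusion probability
#'   below `1/n_iter` are zeroed in the output.
#' @param beta_bound Divergence guard: the run aborts, naming the sweep, if
#'   any per-probe effect exceeds this magnitude.
#' @param fix_p,fix_h2 Optional fixed values for p and h2; when set, the
#'   corresponding update is skipped (used for oracle comparisons against
#'   [ldpred_inf()]).
#' @param return_beta_draws Keep the full post-burn-in draw matrix
#'   (`n_iter` x probes); memory-hungry, intended for diagnostics on small
#'   problems.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(burn_in = 500, n_iter = 500, p_init = 0.1,
                         h2_init = NULL, h2_floor = 1e-5, seed,
                         sparse_output = FALSE, beta_bound = 5,
                         fix_p = NULL, fix_h2 = NULL,
                         return_beta_draws = FALSE) {
  stopifnot(burn_in >= 1, n_iter >= 1, p_init > 0, p_init <= 1,
            h2_floor > 0, beta_bound > 0)
  if (missing(seed)) stop_validation("gibbs_config: seed is mandatory")
  if (!is.null(h2_init) && h2_init <= 0) {
    stop_validation("h2_init override must be > 0")
  }
  structure(list(burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 p_init = p_init, h2_init = h2_init, h2_floor = h2_floor,
                 seed = as.integer(seed), sparse_output = sparse_output,
                 beta_bound = beta_bound, fix_p = fix_p, fix_h2 = fix_h2,
                 return_beta_draws = return_beta_draws),
            class = "gibbs_config")
}

# Sort blocks (and probes within blocks) into the canonical order of `ord`,
# so the sampler's RNG stream is invariant to block-list permutations.
sort_blocks_canonically <- function(bcorr, ord) {
  blocks <- lapply(bcorr$blocks, function(bl) {
    pos <- match(bl$probe_ids, ord)
    o <- order(pos)
    list(probe_ids = bl$probe_ids[o],
         R = bl$R[o, o, drop = FALSE],
         first = min(pos))
  })
  blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "first"))]
  lapply(blocks, function(bl) bl[c("probe_ids", "R")])
}

#' Spike-and-slab Gibbs sampler with internal h2/p inference
#'
#' Fits the point-normal model: each standardized effect is zero with
#' probability `1 - p` and `Normal(0, sigma^2)` otherwise, with
#' `sigma^2 = h2 / (M * p)`. Each sweep performs a block-local residual
#' update per probe, then refreshes the hyperparameters from all blocks:
#' `p ~ Beta(1 + Mc, 1 + M - Mc)` with `Mc` the current nonzero count, and
#' `h2 = beta' R beta` (blockwise quadratic form) clamped below at
#' `h2_floor`. The posterior effect is the post-burn-in mean of the chain.
#'
#' @param eff Standardized effects ([standardize_effects()]); probe set must
#'   match `bcorr`, any order.
#' @param bcorr A `block_corr` prior.
#' @param cfg A [gibbs_config()].
#' @return An object of class `mrs_posterior`: per-probe `estimates`
#'   (posterior mean `beta_post`, Monte-Carlo `beta_sd`, inclusion
#'   probability `pip`), per-sweep `chains` (`p`, `h2`, `m_c`), the
#'   heritability initialization used, and the config.
#' @seealso [ldpred_inf()] for the closed-form infinitesimal solver,
#'   [tidy.mrs_posterior()], [glance.mrs_posterior()], [autoplot.mrs_posterior()].
#' @export
ldpred_auto <- function(eff, bcorr, cfg) {
  stopifnot(inherits(cfg, "gibbs_config"))
  # the caller's effect order is the canonical sweep order; blocks are
  # remapped onto it, so results do not depend on the block-list order
  assert_probe_alignment(sort(eff$probe_id), sort(bcorr$probe_order),
                         "standardized effects", "correlation matrix")
  blocks <- sort_blocks_canonically(bcorr, eff$probe_id)

  h2_init <- cfg$h2_init
  h2_est <- estimate_h2_init(eff, bcorr)
  if (is.null(h2_init)) {
    if (h2_est <= 0) {
      stop_validation(paste0(
        "heritability moment estimate is non-positive (%.3g); supply an ",
        "explicit h2_init override (e.g. 1e-5) to proceed"), h2_est)
    }
    h2_init <- h2_est
  }

  set.seed(cfg$seed)
  fit <- gibbs_core(
    block_idx = lapply(blocks, function(bl) match(bl$probe_ids, eff$probe_id) - 1L),
    block_R = lapply(blocks, `[[`, "R"),
    beta_hat = eff$beta_std, n = as.numeric(eff$n),
    h2_init = h2_init, p_init = cfg$p_init,
    burn_in = cfg$burn_in, n_iter = cfg$n_iter,
    h2_floor = cfg$h2_floor, beta_bound = cfg$beta_bound,
    fix_p = !is.null(cfg$fix_p), p_fixed = cfg$fix_p %||% 0,
    fix_h2 = !is.null(cfg$fix_h2), h2_fixed = cfg$fix_h2 %||% 0,
    keep_draws = cfg$return_beta_draws
  )

  beta_post <- fit$beta_post
  if (cfg$sparse_output) beta_post[fit$pip < 1 / cfg$n_iter] <- 0

  structure(list(
    estimates = tibble(probe_id = eff$probe_id, beta_hat_std = eff$beta_std,
                       n = eff$n, beta_post = beta_post,
                       beta_sd = fit$beta_sd, pip = fit$pip),
    chains = tibble(sweep = seq_len(cfg$n_iter), p = fit$p_chain,
                    h2 = fit$h2_chain, m_c = fit$mc_chain),
    h2_init = h2_init, h2_est = h2_est, config = cfg, method = "auto",
    beta_draws = fit$draws
  ), class = "mrs_posterior")
}

#' Closed-form infinitesimal-model solver
#'
#' The `p = 1` limit of the point-normal model has a closed form: per block,
#' the posterior mean solves `(R + (M / (n_mean * h2)) I) beta = beta_hat`,
#' where `n_mean` is the mean per-probe sample size (the per-probe sizes are
#' collapsed to their mean — a documented approximation). Deterministic; used
#' as the independent oracle for the sampler and as a fallback solver.
#'
#' @param eff Standardized effects aligned (as a set) with `bcorr`.
#' @param bcorr A `block_corr`.
#' @param h2 Heritability (> 0).
#' @return An `mrs_posterior` with `method = "inf"` and no chains.
#' @export
ldpred_inf <- function(eff, bcorr, h2) {
  stopifnot(h2 > 0)
  assert_probe_alignment(sort(eff$probe_id), sort(bcorr$probe_order),
                         "standardized effects", "correlation matrix")
  m <- nrow(eff)
  lambda <- m / (mean(eff$n) * h2)
  beta_post <- numeric(m)
  for (bl in bcorr$blocks) {
    idx <- match(bl$probe_ids, eff$probe_id)
    A <- bl$R + diag(lambda, nrow(bl$R))
    sol <- tryCatch(solve(A, eff$beta_std[idx]), error = function(e) {
      stop_validation("infinitesimal solver: singular block system (%s)",
                      conditionMessage(e))
    })
    beta_post[idx] <- sol
  }
  structure(list(
    estimates = tibble(probe_id = eff$probe_id, beta_hat_std = eff$beta_std,
                       n = eff$n, beta_post = beta_post,
                       beta_sd = rep(0, m), pip = rep(1, m)),
    chains = tibble(sweep = integer(), p = numeric(), h2 = numeric(),
                    m_c = integer()),
    h2_init = h2, h2_est = h2, config = NULL, method = "inf",
    beta_draws = NULL
  ), class = "mrs_posterior")
}

#' @export
print.mrs_posterior <- function(x, ...) {
  cat(sprintf("<mrs_posterior (%s): %d probes", x$method, nrow(x$estimates)))
  if (nrow(x$chains)) {
    cat(sprintf(", %d sweeps kept; posterior mean h2 = %.4g, p = %.4g",
                nrow(x$chains), mean(x$chains$h2), mean(x$chains$p)))
  }
  cat(">\n")
  invisible(x)
}

#' Export posterior effects and chains
#'
#' @param fit An `mrs_posterior`.
#' @param effects_path,chains_path Output TSV paths (`NULL` to skip either).
#' @return `fit`, invisibly.
#' @export
write_posterior <- function(fit, effects_path = NULL, chains_path = NULL) {
  if (!is.null(effects_path)) {
    readr::write_tsv(fit$estimates, effects_path, progress = FALSE)
  }
  if (!is.null(chains_path)) {
    readr::write_tsv(fit$chains, chains_path, progress = FALSE)
  }
  invisible(fit)
}
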