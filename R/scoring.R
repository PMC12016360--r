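# Score computation S = M'B, logistic-regression evaluation (Nagelkerke R2,
# Wald p, AIC) and the clump+threshold baseline.

#' Compute methylation scores
#'
#' Per-sample weighted sum of methylation values: `score_i = sum_j M_ji b_j`,
#' i.e. the matrix product `S = M'B` with `M` probes x samples.
#'
#' @param mat Methylation matrix (probes x samples).
#' @param eff Either an `mrs_posterior` (the posterior means are used) or a
#'   tibble with columns `probe_id` and a single effect column (`beta_post`
#'   or `beta`).
#' @return Tibble with `sample_id` and `score`.
#' @export
compute_scores <- function(mat, eff) {
  if (inherits(eff, "mrs_posterior")) eff <- eff$estimates
  beta_col <- intersect(c("beta_post", "beta"), names(eff))[1]
  if (is.na(beta_col)) {
    stop_validation("effects input has no 'beta_post' or 'beta' column")
  }
  assert_probe_alignment(sort(rownames(mat)), sort(eff$probe_id),
                         "methylation matrix", "effects")
  b <- eff[[beta_col]][match(rownames(mat), eff$probe_id)]
  scores <- drop(crossprod(mat, b))
  tibble(sample_id = colnames(mat), score = unname(scores))
}

#' Evaluate scores against a binary phenotype
#'
#' Fits `logit(Pr(y = 1)) = a + b * score` by maximum likelihood and reports
#' the Wald p-value for `b`, `AIC = 2k - 2 * l1` with `k = 2`, a
#' likelihood-ratio p-value, and the Nagelkerke pseudo-R-squared
#' `[1 - exp(2 (l0 - l1) / n)] / [1 - exp(2 l0 / n)]`, where `l0` is the
#' intercept-only log-likelihood. Complete separation is flagged (not fatal):
#' the result carries `separation = TRUE` and R2 is reported as `1 - 1e-8`
#' with a warning.
#'
#' @param scores Score tibble ([compute_scores()]).
#' @param pheno Phenotype tibble (`sample_id`, `y` in 0/1); both classes must
#'   have >= 2 samples among the scored samples.
#' @return An `mrs_eval` object; see [glance.mrs_eval()].
#' @export
evaluate_scores <- function(scores, pheno) {
  pheno <- validate_phenotypes(pheno)
  dat <- dplyr::inner_join(scores, pheno, by = "sample_id")
  if (!nrow(dat)) stop_validation("no overlapping samples between scores and phenotypes")
  counts <- table(factor(dat$y, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop_validation("need >= 2 samples per phenotype class (got %d controls, %d cases)",
                    counts[1], counts[2])
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ score, data = dat, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # perfect separation drives the residual deviance to zero without
  # necessarily triggering the glm warning
  if (fit$deviance < 1e-6) separation <- TRUE
  fit0 <- glm(y ~ 1, data = dat, family = binomial())
  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(fit0))
  n <- nrow(dat)
  r2 <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  co <- summary(fit)$coefficients
  # a constant score is dropped by the fit (NA coefficient): no evidence
  wald_p <- if ("score" %in% rownames(co)) unname(co["score", "Pr(>|z|)"]) else 1
  lr_p <- pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
  if (separation) {
    warn("complete separation in logistic evaluation; R2 reported as 1 - 1e-8")
    r2 <- 1 - 1e-8
  }
  structure(list(
    fit = fit,
    nagelkerke_r2 = r2, wald_p = wald_p, lr_p = lr_p,
    aic = 2 * 2 - 2 * ll1,
    loglik = ll1, loglik_null = ll0,
    n_samples = n, n_cases = as.integer(counts[2]),
    separation = separation
  ), class = "mrs_eval")
}

#' @export
print.mrs_eval <- function(x, ...) {
  cat(sprintf(
    "<mrs_eval: n = %d (%d cases); Nagelkerke R2 = %.4g, Wald p = %.3g, AIC = %.1f%s>\n",
    x$n_samples, x$n_cases, x$nagelkerke_r2, x$wald_p, x$aic,
    if (x$separation) "; SEPARATION" else ""))
  invisible(x)
}

#' Clump-and-threshold baseline scores
#'
#' A generic pruning-and-thresholding comparator: within each cluster, probes
#' are visited in order of ascending p-value and greedily kept unless their
#' absolute correlation with an already-kept probe exceeds `sqrt(r2_prune)`;
#' survivors with `p <= p_thresh` are then scored with their raw marginal
#' effects (not posterior means) via [compute_scores()].
#'
#' @param stats Summary-statistics tibble.
#' @param mat Methylation matrix (probes x samples) used both for pruning
#'   correlations and scoring.
#' @param cs A `cluster_set` over the same probes.
#' @param r2_prune Squared-correlation pruning threshold in `(0, 1]`.
#' @param p_thresh P-value inclusion threshold in `(0, 1]`.
#' @return Score tibble with the kept probe ids in `attr(x, "kept_probes")`.
#' @export
clump_threshold_baseline <- function(stats, mat, cs, r2_prune = 0.1,
                                     p_thresh = 1) {
  stopifnot(r2_prune > 0, r2_prune <= 1, p_thresh > 0, p_thresh <= 1)
  assert_probe_alignment(sort(stats$probe_id), sort(cs$probe_id),
                         "summary statistics", "cluster set")
  assert_probe_alignment(sort(rownames(mat)), sort(cs$probe_id),
                         "methylation matrix", "cluster set")
  r_max <- sqrt(r2_prune)
  kept <- character(0)
  for (cl in sort(unique(cs$cluster_id))) {
    probes <- cs$probe_id[cs$cluster_id == cl]
    sub <- stats[match(probes, stats$probe_id), , drop = FALSE]
    sub <- sub[order(sub$p, sub$probe_id), , drop = FALSE]
    kept_cl <- character(0)
    for (pid in sub$probe_id) {
      if (length(kept_cl)) {
        r <- abs(cor(mat[pid, ], t(mat[kept_cl, , drop = FALSE])))
        if (any(r > r_max, na.rm = TRUE)) next
      }
      kept_cl <- c(kept_cl, pid)
    }
    kept <- c(kept, kept_cl)
  }
  kept <- kept[stats$p[match(kept, stats$probe_id)] <= p_thresh]
  if (!length(kept)) {
    stop_validation("no probes survive clump+threshold (r2_prune = %g, p_thresh = %g); loosen the thresholds",
                    r2_prune, p_thresh)
  }
  eff <- tibble(probe_id = kept,
                beta = stats$beta[match(kept, stats$probe_id)])
  out <- compute_scores(mat[kept, , drop = FALSE], eff)
  attr(out, "kept_probes") <- kept
  out
}

#' Write a score table
#' @param scores Score tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}
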