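# End-to-end orchestration: cluster -> block correlation -> fit -> score ->
# evaluate, for each requested structural prior, with a comparison report.

#' Run the scoring pipeline for one or more structural priors
#'
#' For each requested prior, builds the cluster set, assembles the
#' block-diagonal correlation matrix from the test methylation matrix (the
#' same matrix later scored — mirroring the reference analysis; pass
#' `ref_mat` to use an independent reference instead), fits the sampler,
#' scores the test samples, and evaluates against the phenotype. The
#' comparison report has one row per model.
#'
#' Recognized prior labels:
#' \describe{
#'   \item{`"cmr"`}{CMR chaining at the documented preset
#'     (`corlo = 0.2`, `maxprbdst = 100000`, `corlodst = 800`).}
#'   \item{`"cmr-nosingleton"`}{As `"cmr"`, then [drop_singletons()]; the
#'     heritability moment estimate often turns non-positive here, and the
#'     `h2_init` override in `gibbs` (e.g. `1e-5`) is honored.}
#'   \item{`"window:<bp>"`}{[sliding_window_clusters()] at the given window.}
#'   \item{`"tad"`}{[tad_clusters()] against `tads`.}
#'   \item{`"random:<k>"`}{k-th random-cluster null set (seeded from `seed`).}
#'   \item{`"baseline-pt"`}{[clump_threshold_baseline()] scored with raw
#'     marginal effects (no sampler).}
#' }
#'
#' @param stats Training summary statistics.
#' @param test_mat Test methylation matrix (probes x samples).
#' @param ann Probe annotation.
#' @param pheno Test phenotype table.
#' @param priors Character vector of prior labels (above).
#' @param gibbs A [gibbs_config()].
#' @param tads Interval tibble, required for the `"tad"` prior.
#' @param cpg_positions Optional reference CpG map for the CMR priors.
#' @param ref_mat Optional independent matrix for the correlation blocks.
#' @param seed Seed for the random-cluster sets.
#' @param r2_prune,p_thresh Baseline thresholds.
#' @return An `mrs_report` tibble with columns `model`, `p_value`,
#'   `nagelkerke_r2`, `aic`, `pct_probes_clustered`; the per-model fits are
#'   kept in `attr(x, "fits")` and evaluations in `attr(x, "evals")`.
#' @export
run_pipeline <- function(stats, test_mat, ann, pheno,
                         priors = c("window:5000"), gibbs, tads = NULL,
                         cpg_positions = NULL, ref_mat = NULL, seed = 1,
                         r2_prune = 0.1, p_thresh = 1) {
  stopifnot(inherits(gibbs, "gibbs_config"))
  stage <- function(name, model, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed for model '%s': %s",
                    name, model, conditionMessage(e)),
            class = "methylscore_pipeline_error")
    })
  }
  common <- intersect_probes(stats, test_mat, ann)
  corr_mat <- if (is.null(ref_mat)) common$mat else {
    ref_mat[common$annotation$probe_id, , drop = FALSE]
  }

  rows <- list(); fits <- list(); evals <- list()
  for (prior in priors) {
    cs <- stage("cluster", prior, build_prior_clusters(
      prior, common$annotation, corr_mat, tads, cpg_positions, seed))
    pct <- cluster_summary(cs)$pct_nonsingleton_probes

    if (identical(prior, "baseline-pt")) {
      scores <- stage("score", prior, clump_threshold_baseline(
        common$stats, common$mat, cs, r2_prune = r2_prune,
        p_thresh = p_thresh))
      fit <- NULL
    } else {
      sub <- common
      if (nrow(cs) < nrow(common$annotation)) {  # e.g. singletons dropped
        keep_ann <- common$annotation[common$annotation$probe_id %in% cs$probe_id, ]
        sub <- intersect_probes(common$stats, common$mat, keep_ann)
      }
      bc_mat <- if (is.null(ref_mat)) sub$mat else {
        ref_mat[sub$annotation$probe_id, , drop = FALSE]
      }
      bcorr <- stage("corr", prior, build_block_correlation(bc_mat, cs))
      eff <- stage("fit", prior, standardize_effects(sub$stats))
      fit <- stage("fit", prior, ldpred_auto(eff, bcorr, gibbs))
      scores <- stage("score", prior, compute_scores(sub$mat, fit))
    }
    ev <- stage("evaluate", prior, evaluate_scores(scores, pheno))
    rows[[prior]] <- tibble(model = prior, p_value = ev$wald_p,
                            nagelkerke_r2 = ev$nagelkerke_r2, aic = ev$aic,
                            pct_probes_clustered = pct)
    fits[[prior]] <- fit
    evals[[prior]] <- ev
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "fits") <- fits
  attr(report, "evals") <- evals
  class(report) <- c("mrs_report", class(report))
  report
}

build_prior_clusters <- function(prior, ann, corr_mat, tads, cpg_positions,
                                 seed) {
  if (identical(prior, "cmr") || identical(prior, "baseline-pt")) {
    # the baseline prunes within CMR-preset clusters
    return(cmr_clusters(ann, corr_mat, cpg_positions = cpg_positions))
  }
  if (identical(prior, "cmr-nosingleton")) {
    return(drop_singletons(
      cmr_clusters(ann, corr_mat, cpg_positions = cpg_positions)))
  }
  if (grepl("^window:", prior)) {
    return(sliding_window_clusters(ann, as.integer(sub("^window:", "", prior))))
  }
  if (identical(prior, "tad")) {
    if (is.null(tads)) stop_validation("prior 'tad' needs a TAD scaffold")
    return(tad_clusters(ann, tads))
  }
  if (grepl("^random:", prior)) {
    k <- as.integer(sub("^random:", "", prior))
    return(random_clusters(ann, n_sets = k, seed = seed)[[k]])
  }
  stop_validation("unknown prior label '%s'", prior)
}

#' Write the model-comparison report
#'
#' @param report An `mrs_report`.
#' @param path Output TSV path (columns `model`, `p_value`, `nagelkerke_r2`,
#'   `aic`, `pct_probes_clustered`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}
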