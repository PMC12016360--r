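# Synthetic studies with the statistical structure the pipeline assumes:
# block-correlated methylation, sparse point-normal effects, a
# liability-threshold binary phenotype, and training-side marginal summary
# statistics.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 2,000 probes in
#' compound-symmetric blocks of 10 with within-block correlation 0.5, a
#' training cohort of 5,000 and a test cohort of 1,000 samples, heritability
#' 0.3 spread over 2% of probes, and a liability-threshold phenotype with
#' prevalence 0.4.
#'
#' @param m_probes Number of probes.
#' @param n_train,n_test Training / test cohort sizes.
#' @param block_size Probes per correlation block.
#' @param rho Within-block correlation in `[0, 1)`.
#' @param h2_true Liability-scale heritability in `[0, 1)`.
#' @param p_true Fraction of causal probes in `(0, 1]`.
#' @param prevalence Phenotype prevalence in `(0, 1)`.
#' @param probe_spacing Basepair spacing between probes within a block;
#'   consecutive blocks are separated by ten times this spacing so that
#'   proximity-based clustering at window `probe_spacing` recovers the true
#'   blocks exactly.
#' @param chrom_blocks Blocks per synthetic chromosome.
#' @param seed Integer seed; the same seed reproduces the study byte-for-byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_probes = 2000, n_train = 5000, n_test = 1000,
                       block_size = 10, rho = 0.5, h2_true = 0.3,
                       p_true = 0.02, prevalence = 0.4, probe_spacing = 500,
                       chrom_blocks = 50, seed = 1) {
  stopifnot(m_probes >= 2, n_train >= 3, n_test >= 3, block_size >= 1,
            rho >= 0, rho < 1, h2_true >= 0, h2_true < 1,
            p_true > 0, p_true <= 1, prevalence > 0, prevalence < 1,
            probe_spacing >= 1, chrom_blocks >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a complete synthetic study
#'
#' Draws a full two-cohort study under the generative model the pipeline
#' assumes:
#' \itemize{
#'   \item probes laid out on synthetic chromosomes, regularly spaced within
#'     correlation blocks, with a 10x-spacing gap between blocks;
#'   \item methylation values with block-compound-symmetric correlation
#'     (within-block off-diagonal `rho`), each probe standardized across
#'     samples — emulating residualized methylation levels;
#'   \item a causal set of exactly `round(p_true * m_probes)` probes with
#'     effects `Normal(0, h2_true / (m_probes * p_true))`;
#'   \item a liability `l = sum_j x_j beta_j + e`, `e ~ Normal(0, 1 - h2_true)`,
#'     thresholded at the theoretical `(1 - prevalence)` Gaussian quantile to
#'     give the binary phenotype;
#'   \item per-probe marginal summary statistics computed from the training
#'     half only ([per_probe_mwas()]).
#' }
#' Train and test cohorts are independent draws given the config.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_study` list: `annotation`, `train` / `test` (each
#'   with `mat` and `pheno`), `true_beta` tibble, and `summary` (training
#'   summary statistics).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m_probes
  n_blocks <- ceiling(m / cfg$block_size)
  block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(m)]
  within <- sequence(rle(block_of)$lengths) - 1L

  chrom <- as.character((block_of - 1L) %/% cfg$chrom_blocks + 1L)
  block_in_chrom <- (block_of - 1L) %% cfg$chrom_blocks
  # regular spacing within blocks, 10x gap between blocks
  pos <- 1L + block_in_chrom * as.integer(cfg$probe_spacing) *
    (cfg$block_size + 9L) + within * as.integer(cfg$probe_spacing)
  annotation <- tibble(probe_id = sprintf("cg%08d", seq_len(m)),
                       chrom = chrom, pos = as.integer(pos))

  m_causal <- max(1L, round(cfg$p_true * m))
  true_beta <- numeric(m)
  if (cfg$h2_true > 0) {
    causal <- sort(sample.int(m, m_causal))
    true_beta[causal] <- rnorm(m_causal, 0,
                               sqrt(cfg$h2_true / (m * cfg$p_true)))
  }

  draw_cohort <- function(n, prefix) {
    X <- matrix(rnorm(n * m), n, m)
    if (cfg$rho > 0) {
      shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
      X <- sqrt(cfg$rho) * shared[, block_of, drop = FALSE] +
        sqrt(1 - cfg$rho) * X
    }
    X <- scale(X)  # standardize each probe across samples
    liab <- drop(X %*% true_beta) + rnorm(n, 0, sqrt(1 - cfg$h2_true))
    y <- as.integer(liab > qnorm(1 - cfg$prevalence))
    mat <- t(X)
    dimnames(mat) <- list(annotation$probe_id, sprintf("%s%05d", prefix, seq_len(n)))
    list(mat = mat,
         pheno = tibble(sample_id = colnames(mat), y = y))
  }
  train <- draw_cohort(cfg$n_train, "tr")
  test <- draw_cohort(cfg$n_test, "te")

  structure(list(
    annotation = annotation,
    train = train, test = test,
    true_beta = tibble(probe_id = annotation$probe_id, true_beta = true_beta),
    summary = per_probe_mwas(train$mat, train$pheno),
    config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_study: %d probes, %d train / %d test samples, h2 = %g, p = %g, seed = %d>\n",
    cfg$m_probes, cfg$n_train, cfg$n_test, cfg$h2_true, cfg$p_true, cfg$seed))
  invisible(x)
}

#' Per-probe marginal association scan
#'
#' For each probe, ordinary least squares of the phenotype on the
#' standardized probe: slope, its standard error, the per-probe sample size
#' and the two-sided t-test p-value. Vectorized closed-form simple
#' regression; a linear (not logistic) scan, consistent with the
#' standardized-effect bridge of [standardize_effects()].
#'
#' @param mat Methylation matrix (probes x samples), >= 3 samples.
#' @param pheno Phenotype tibble covering the matrix's samples.
#' @return Summary-statistics tibble (`probe_id`, `beta`, `se`, `n`, `p`).
#' @export
per_probe_mwas <- function(mat, pheno) {
  pheno <- validate_phenotypes(pheno)
  n <- ncol(mat)
  if (n < 3) stop_validation("marginal scan needs >= 3 samples (got %d)", n)
  y <- pheno$y[match(colnames(mat), pheno$sample_id)]
  if (anyNA(y)) {
    stop_validation("phenotype missing for sample(s): %s",
                    paste(head(colnames(mat)[is.na(y)], 5), collapse = ", "))
  }
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    stop_validation("zero-variance probe(s): %s",
                    paste(head(rownames(mat)[sds == 0], 5), collapse = ", "))
  }
  x <- (mat - rowMeans(mat)) / sds  # standardized probes
  yc <- y - mean(y)
  sxx <- rep(n - 1, nrow(mat))
  sxy <- drop(x %*% yc)
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble(probe_id = rownames(mat), beta = unname(beta), se = unname(se),
         n = n, p = pmax(unname(p), .Machine$double.xmin))
}

#' Write all study files
#'
#' Writes the complete study in the pipeline's on-disk layouts (annotation,
#' train/test matrices and phenotypes, training summary statistics, and a
#' truth table `probe_id`/`true_beta`).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_probe_annotation(study$annotation, p("annotation.tsv"))
  write_methylation_matrix(study$train$mat, p("train_methylation.tsv"))
  write_methylation_matrix(study$test$mat, p("test_methylation.tsv"))
  write_phenotypes(study$train$pheno, p("train_phenotypes.tsv"))
  write_phenotypes(study$test$pheno, p("test_phenotypes.tsv"))
  write_summary_stats(study$summary, p("summary_stats.tsv"))
  readr::write_tsv(study$true_beta, p("true_beta.tsv"), progress = FALSE)
  invisible(dir)
}
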