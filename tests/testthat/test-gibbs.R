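identity_bcorr <- function(probe_ids) {
  blocks <- lapply(probe_ids, function(p) {
    list(probe_ids = p, R = matrix(1, 1, 1, dimnames = list(p, p)))
  })
  methylscore:::new_block_corr(blocks)
}

std_effects <- function(beta_std, n, probe_ids = sprintf("p%02d", seq_along(beta_std))) {
  tibble::tibble(probe_id = probe_ids, beta_std = beta_std, n = as.integer(n))
}

test_that("effect standardization is z over sqrt(n)", {
  stats <- tibble::tibble(probe_id = c("a", "b"), beta = c(0, 0.05),
                          se = c(0.1, 0.05), n = c(50L, 100L), p = c(0.5, 0.3))
  eff <- standardize_effects(stats)
  expect_equal(eff$beta_std, c(0, (0.05 / 0.05) / sqrt(100)))
  expect_equal(eff$beta_std[2], 0.1)
})

test_that("standardized effects approximate the probe-phenotype correlation", {
  cfg <- sim_config(m_probes = 60, n_train = 3000, n_test = 10, h2_true = 0.3,
                    p_true = 0.2, block_size = 5, seed = 12)
  st <- generate_study(cfg)
  eff <- standardize_effects(st$summary)
  y <- st$train$pheno$y
  direct <- apply(st$train$mat, 1, function(x) cor(x, y))
  expect_equal(eff$beta_std, unname(direct), tolerance = 5 / sqrt(cfg$n_train))
})

test_that("the heritability moment estimator has its closed form at R = I", {
  set.seed(2)
  m <- 40
  eff <- std_effects(rnorm(m, 0, 0.05), n = 400)
  bc <- identity_bcorr(eff$probe_id)
  est <- estimate_h2_init(eff, bc)
  chi2 <- eff$n * eff$beta_std^2
  expect_equal(est, m * (mean(chi2) - 1) / 400)
})

test_that("the heritability moment estimator recovers a simulated h2 of 0.3", {
  cfg <- sim_config(m_probes = 1000, n_train = 4000, n_test = 800,
                    h2_true = 0.3, seed = 5)
  st <- generate_study(cfg)
  cm <- intersect_probes(st$summary, st$test$mat, st$annotation)
  cs <- sliding_window_clusters(cm$annotation, cfg$probe_spacing)
  bc <- build_block_correlation(cm$mat, cs)
  eff <- standardize_effects(cm$stats)
  est <- estimate_h2_init(eff, bc)
  expect_gt(est, 0.15)
  expect_lt(est, 0.45)
})

test_that("null input keeps posterior effects near zero and p near its prior mean", {
  m <- 50
  eff <- std_effects(rep(0, m), n = 1000)
  bc <- identity_bcorr(eff$probe_id)
  fit <- ldpred_auto(eff, bc, gibbs_config(burn_in = 200, n_iter = 500,
                                           h2_init = 0.1, fix_h2 = 0.1,
                                           seed = 1))
  expect_lt(max(abs(tidy(fit)$beta_post)), 5e-3)
  # with no signal the spike dominates: Mc stays near 0 and the p chain
  # settles in the sparse regime near its Beta(1, 1 + M) prior
  expect_lt(mean(fit$chains$p), 0.1)
  expect_lt(mean(fit$chains$m_c), 0.1 * m)
})

test_that("a single probe shrinks to its closed-form posterior mean", {
  eff <- std_effects(0.2, n = 100, probe_ids = "p1")
  bc <- identity_bcorr("p1")
  h2 <- 0.05
  fit <- ldpred_auto(eff, bc, gibbs_config(burn_in = 500, n_iter = 4000,
                                           fix_p = 1, fix_h2 = h2, seed = 2,
                                           return_beta_draws = TRUE))
  sigma2 <- h2 / 1  # M = 1, p = 1
  expected <- 0.2 / (1 + 1 / (100 * sigma2))
  mcse <- batch_mcse(fit$beta_draws[, 1])
  expect_lt(abs(tidy(fit)$beta_post - expected), 3 * mcse + 1e-6)
})

test_that("with p = 1 and fixed h2 the sampler matches elementwise shrinkage at R = I", {
  set.seed(6)
  m <- 20
  eff <- std_effects(rnorm(m, 0, 0.1), n = 500)
  bc <- identity_bcorr(eff$probe_id)
  h2 <- 0.2
  fit <- ldpred_auto(eff, bc, gibbs_config(burn_in = 300, n_iter = 2000,
                                           fix_p = 1, fix_h2 = h2, seed = 3,
                                           return_beta_draws = TRUE))
  expected <- eff$beta_std / (1 + m / (500 * h2))
  mcse <- apply(fit$beta_draws, 2, batch_mcse)
  expect_mc_agreement(tidy(fit)$beta_post, expected, mcse)
})

test_that("the infinitesimal solver has its closed forms and a linear-algebra oracle", {
  m <- 4
  eff <- std_effects(c(0.1, -0.2, 0.05, 0.3), n = 100)
  bc <- identity_bcorr(eff$probe_id)
  # lambda = M / (n h2) = 1 when h2 = M / n
  fit <- ldpred_inf(eff, bc, h2 = m / 100)
  expect_equal(tidy(fit)$beta_post, eff$beta_std / 2)

  # h2 -> infinity limit: beta -> R^{-1} beta_hat
  set.seed(7)
  mat <- matrix(rnorm(5 * 200), 5, 200,
                dimnames = list(sprintf("p%02d", 1:5), paste0("s", 1:200)))
  cs <- new_cluster_set(rownames(mat), rep(1, 5), "one")
  bc5 <- build_block_correlation(mat, cs)
  eff5 <- std_effects(rnorm(5, 0, 0.1), n = 300, probe_ids = rownames(mat))
  fit_inf <- ldpred_inf(eff5, bc5, h2 = 1e8)
  expect_equal(tidy(fit_inf)$beta_post,
               unname(drop(solve(bc5$blocks[[1]]$R, eff5$beta_std))),
               tolerance = 1e-4)

  # random 5x5 block vs explicit inversion
  h2 <- 0.3
  lambda <- 5 / (300 * h2)
  explicit <- unname(drop(solve(bc5$blocks[[1]]$R + diag(lambda, 5)) %*% eff5$beta_std))
  expect_equal(tidy(ldpred_inf(eff5, bc5, h2))$beta_post, explicit)
})

test_that("sampler runs are bit-identical under seed and block reordering", {
  set.seed(10)
  mat <- matrix(rnorm(12 * 60), 12, 60,
                dimnames = list(sprintf("p%02d", 1:12), paste0("s", 1:60)))
  cs <- new_cluster_set(rownames(mat), rep(1:3, each = 4), "b")
  bc <- build_block_correlation(mat, cs)
  eff <- std_effects(rnorm(12, 0, 0.08), n = 400, probe_ids = rownames(mat))
  cfg <- gibbs_config(burn_in = 50, n_iter = 100, h2_init = 0.1, seed = 42)
  fit1 <- ldpred_auto(eff, bc, cfg)
  fit2 <- ldpred_auto(eff, bc, cfg)
  expect_identical(fit1$estimates, fit2$estimates)
  expect_identical(fit1$chains, fit2$chains)

  bc_shuffled <- methylscore:::new_block_corr(bc$blocks[c(3, 1, 2)])
  fit3 <- ldpred_auto(eff, bc_shuffled, cfg)
  expect_identical(fit1$estimates, fit3$estimates)
})

test_that("hyperparameter chains respect their supports", {
  set.seed(13)
  mat <- matrix(rnorm(10 * 50), 10, 50,
                dimnames = list(sprintf("p%02d", 1:10), paste0("s", 1:50)))
  bc <- build_block_correlation(mat, new_cluster_set(rownames(mat),
                                                     rep(1:2, each = 5), "b"))
  eff <- std_effects(rnorm(10, 0, 0.05), n = 300, probe_ids = rownames(mat))
  floor <- 1e-5
  fit <- ldpred_auto(eff, bc, gibbs_config(burn_in = 100, n_iter = 400,
                                           h2_init = 1e-3, h2_floor = floor,
                                           seed = 9))
  expect_true(all(fit$chains$h2 >= floor))
  expect_true(all(fit$chains$p > 0 & fit$chains$p < 1))
  expect_true(all(is.finite(tidy(fit)$beta_post)))
})

test_that("a non-positive heritability estimate demands an explicit override", {
  m <- 30
  eff <- std_effects(rep(0, m), n = 2000)  # chi2 = 0 => estimate < 0
  bc <- identity_bcorr(eff$probe_id)
  expect_lt(estimate_h2_init(eff, bc), 0)
  expect_error(ldpred_auto(eff, bc, gibbs_config(seed = 1)),
               "h2_init", class = "methylscore_validation_error")
  fit <- ldpred_auto(eff, bc, gibbs_config(burn_in = 50, n_iter = 50,
                                           h2_init = 1e-5, seed = 1))
  expect_equal(fit$h2_init, 1e-5)
  expect_lt(fit$h2_est, 0)
})

test_that("the divergence guard aborts with the sweep in the message", {
  eff <- std_effects(c(0.5, -0.5), n = 10000)
  bc <- identity_bcorr(eff$probe_id)
  expect_error(
    ldpred_auto(eff, bc, gibbs_config(burn_in = 10, n_iter = 10, h2_init = 0.5,
                                      seed = 4, beta_bound = 1e-4)),
    "diverged at sweep")
})
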