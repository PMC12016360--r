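# broom-style tidiers for fitted objects.

#' Tidy a sampler fit
#'
#' @param x An `mrs_posterior`.
#' @param ... Unused.
#' @return Per-probe tibble: `probe_id`, `beta_hat_std`, `beta_post`,
#'   `beta_sd` (Monte-Carlo spread), `pip` (posterior inclusion probability).
#' @export
#' @exportS3Method generics::tidy
tidy.mrs_posterior <- function(x, ...) {
  x$estimates
}

#' One-row summary of a sampler fit
#'
#' @param x An `mrs_posterior`.
#' @param ... Unused.
#' @return Tibble with posterior means of `h2` and `p`, the mean nonzero
#'   count, the initialization used, and sweep counts.
#' @export
#' @exportS3Method generics::glance
glance.mrs_posterior <- function(x, ...) {
  if (!nrow(x$chains)) {
    return(tibble(method = x$method, h2_mean = x$h2_init, p_mean = 1,
                  m_c_mean = nrow(x$estimates), h2_init = x$h2_init,
                  n_iter = 0L, burn_in = 0L))
  }
  tibble(
    method = x$method,
    h2_mean = mean(x$chains$h2),
    p_mean = mean(x$chains$p),
    m_c_mean = mean(x$chains$m_c),
    h2_init = x$h2_init,
    n_iter = x$config$n_iter,
    burn_in = x$config$burn_in
  )
}

#' Tidy a score evaluation
#'
#' @param x An `mrs_eval`.
#' @param ... Unused.
#' @return Coefficient-level tibble of the logistic fit (term, estimate,
#'   std.error, statistic, p.value).
#' @export
#' @exportS3Method generics::tidy
tidy.mrs_eval <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' One-row summary of a score evaluation
#'
#' @param x An `mrs_eval`.
#' @param ... Unused.
#' @return Tibble: `nagelkerke_r2`, `wald_p`, `lr_p`, `aic`, `loglik`,
#'   `loglik_null`, `n_samples`, `n_cases`, `separation`.
#' @export
#' @exportS3Method generics::glance
glance.mrs_eval <- function(x, ...) {
  tibble(nagelkerke_r2 = x$nagelkerke_r2, wald_p = x$wald_p, lr_p = x$lr_p,
         aic = x$aic, loglik = x$loglik, loglik_null = x$loglik_null,
         n_samples = x$n_samples, n_cases = x$n_cases,
         separation = x$separation)
}

#' Export an evaluation as JSON
#'
#' @param x An `mrs_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(x, path) {
  jsonlite::write_json(as.list(glance(x)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
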