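# Sparse block-diagonal probe-probe correlation matrix. Only within-block
# entries are represented; probes in different blocks are structurally
# uncorrelated. Representation size grows with sum(block size^2), never with
# (total probes)^2.

#' Build a block-diagonal correlation matrix
#'
#' Computes one dense Pearson-correlation block per cluster, across samples of
#' the methylation matrix. Singleton clusters become 1x1 unit blocks. The
#' probe order of the result is the matrix's row order restricted to each
#' block (blocks ordered by cluster id).
#'
#' @param mat Methylation matrix (probes x samples), >= 3 samples.
#' @param cs A `cluster_set` partitioning exactly the matrix's probes.
#' @return A `block_corr` object: list with `blocks` (each a list of
#'   `probe_ids` and symmetric matrix `R`) and `probe_order`.
#' @export
build_block_correlation <- function(mat, cs) {
  if (ncol(mat) < 3) {
    stop_validation("correlation needs >= 3 samples (got %d)", ncol(mat))
  }
  assert_probe_alignment(sort(rownames(mat)), sort(cs$probe_id),
                         "methylation matrix", "cluster set")
  zero_var <- rownames(mat)[apply(mat, 1, sd) == 0]
  if (length(zero_var)) {
    stop_validation("zero-variance methylation row(s), correlation undefined: %s",
                    paste(head(zero_var, 5), collapse = ", "))
  }
  row_order <- rownames(mat)
  ids <- sort(unique(cs$cluster_id))
  blocks <- lapply(ids, function(cl) {
    probes <- cs$probe_id[cs$cluster_id == cl]
    probes <- row_order[row_order %in% probes]  # keep matrix row order
    if (length(probes) == 1) {
      R <- matrix(1, 1, 1, dimnames = list(probes, probes))
    } else {
      R <- cor(t(mat[probes, , drop = FALSE]))
    }
    list(probe_ids = probes, R = R)
  })
  new_block_corr(blocks)
}

new_block_corr <- function(blocks) {
  structure(
    list(blocks = blocks,
         probe_order = unlist(lapply(blocks, `[[`, "probe_ids"), use.names = FALSE)),
    class = "block_corr"
  )
}

#' @export
print.block_corr <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) length(b$probe_ids), integer(1))
  cat(sprintf("<block_corr: %d probes in %d blocks (max block %d)>\n",
              length(x$probe_order), length(sizes), max(sizes)))
  invisible(x)
}

#' Blockwise quadratic form
#'
#' Computes `b' R b` exploiting the block structure; equals the dense
#' masked-matrix quadratic form. Used for the heritability update of the
#' Gibbs sampler.
#'
#' @param bcorr A `block_corr`.
#' @param b Numeric vector aligned to `bcorr$probe_order`.
#' @return Scalar `b' R b`.
#' @export
block_quad_form <- function(bcorr, b) {
  stopifnot(length(b) == length(bcorr$probe_order))
  offsets <- c(0L, cumsum(vapply(bcorr$blocks, function(bl) length(bl$probe_ids),
                                 integer(1))))
  total <- 0
  for (i in seq_along(bcorr$blocks)) {
    idx <- (offsets[i] + 1L):offsets[i + 1L]
    bb <- b[idx]
    total <- total + drop(crossprod(bb, bcorr$blocks[[i]]$R %*% bb))
  }
  total
}

#' Eigenvalue conditioning report
#'
#' Per-block symmetric eigendecomposition; blocks whose minimum eigenvalue
#' falls below `tol` are flagged. Near-singular blocks (e.g. duplicated
#' probes) are the known failure mode that drives the heritability estimate
#' negative and can destabilize the sampler.
#'
#' @param bcorr A `block_corr`.
#' @param tol Non-negative tolerance (default `1e-8`).
#' @return Tibble with one row per block (`block`, `size`, `min_eigenvalue`,
#'   `flagged`); attributes `n_flagged` and `ill_conditioned`.
#' @export
conditioning_report <- function(bcorr, tol = 1e-8) {
  stopifnot(tol >= 0)
  min_ev <- vapply(bcorr$blocks, function(bl) {
    min(eigen(bl$R, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  rep <- tibble(
    block = seq_along(bcorr$blocks),
    size = vapply(bcorr$blocks, function(bl) length(bl$probe_ids), integer(1)),
    min_eigenvalue = min_ev,
    flagged = min_ev < tol
  )
  attr(rep, "n_flagged") <- sum(rep$flagged)
  attr(rep, "ill_conditioned") <- any(rep$flagged)
  rep
}

#' Shrink correlation blocks toward the identity
#'
#' Replaces each block `B` by `(1 - shrink) * B + shrink * I`, which raises
#' each block's minimum eigenvalue by `shrink * (1 - min_eigenvalue)` while
#' keeping a unit diagonal. A mitigation for ill-conditioned blocks; off by
#' default in the pipeline (the documented alternative is overriding the
#' heritability initialization instead).
#'
#' @param bcorr A `block_corr`.
#' @param shrink Shrinkage weight in `[0, 1]`.
#' @return A `block_corr` with shrunken blocks.
#' @export
regularize_blocks <- function(bcorr, shrink) {
  if (!is.numeric(shrink) || length(shrink) != 1 || shrink < 0 || shrink > 1) {
    stop_validation("shrink must be a single value in [0, 1]")
  }
  blocks <- lapply(bcorr$blocks, function(bl) {
    bl$R <- (1 - shrink) * bl$R + shrink * diag(nrow(bl$R))
    dimnames(bl$R) <- list(bl$probe_ids, bl$probe_ids)
    bl
  })
  new_block_corr(blocks)
}

# Dense expansion, for small problems and tests only.
as_dense_matrix <- function(bcorr) {
  p <- length(bcorr$probe_order)
  out <- matrix(0, p, p, dimnames = list(bcorr$probe_order, bcorr$probe_order))
  for (bl in bcorr$blocks) out[bl$probe_ids, bl$probe_ids] <- bl$R
  out
}
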