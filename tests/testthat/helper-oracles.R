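# Independent reference implementations used as oracles. These deliberately
# use the dumbest correct algorithm (exhaustive scans, dense matrices,
# explicit Newton-Raphson) and never share code with the package internals.

# Connected components of the gap<=window relation on one chromosome,
# computed as an explicit transitive closure over all pairs.
oracle_window_components <- function(pos, window) {
  n <- length(pos)
  link <- abs(outer(pos, pos, "-")) <= window
  diag(link) <- TRUE
  # Floyd-Warshall-style closure
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (link[i, k] && link[k, j]) link[i, j] <- TRUE
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[link[i, ]] <- cid
    }
  }
  comp
}

# CMR adjacency: evaluate the three predicates on sorted consecutive pairs,
# then chain.
oracle_cmr_components <- function(pos, rows, corlo, maxprbdst, corlodst,
                                  cpg_pos = NULL) {
  o <- order(pos)
  n <- length(pos)
  linked <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    a <- o[i]; b <- o[i + 1]
    ok <- (pos[b] - pos[a]) <= maxprbdst
    if (ok) {
      ok <- sd(rows[a, ]) > 0 && sd(rows[b, ]) > 0 &&
        cor(rows[a, ], rows[b, ]) >= corlo
    }
    if (ok && !is.null(cpg_pos)) {
      mids <- cpg_pos[cpg_pos > pos[a] & cpg_pos < pos[b]]
      ok <- all(diff(c(pos[a], mids, pos[b])) <= corlodst)
    }
    linked[i] <- ok
  }
  comp_sorted <- cumsum(c(1L, as.integer(!linked)))
  comp <- integer(n)
  comp[o] <- comp_sorted
  comp
}

# Exhaustive probe-in-interval scan; smallest start then smallest end wins.
oracle_tad_assign <- function(ann, tads) {
  vapply(seq_len(nrow(ann)), function(i) {
    p0 <- ann$pos[i] - 1L
    best <- NA_character_
    best_start <- Inf; best_end <- Inf
    for (k in seq_len(nrow(tads))) {
      if (tads$chrom[k] != ann$chrom[i]) next
      if (p0 >= tads$start[k] && p0 < tads$end[k]) {
        if (tads$start[k] < best_start ||
            (tads$start[k] == best_start && tads$end[k] < best_end)) {
          best <- tads$interval_id[k]
          best_start <- tads$start[k]; best_end <- tads$end[k]
        }
      }
    }
    best
  }, character(1))
}

# Newton-Raphson logistic MLE for y ~ 1 + x, with the pseudo-R2s.
oracle_logistic <- function(y, x, max_iter = 200, tol = 1e-12) {
  X <- cbind(1, x)
  b <- c(log(mean(y) / (1 - mean(y))), 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X * W, X)
    step <- solve(H, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  ll1 <- sum(y * eta - log(1 + exp(eta)))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  n <- length(y)
  se <- sqrt(diag(solve(crossprod(X * (1 / (1 + exp(-drop(X %*% b)))) *
                                    (1 - 1 / (1 + exp(-drop(X %*% b)))), X))))
  z <- unname(b[2] / se[2])
  list(coef = b, ll0 = ll0, ll1 = ll1,
       wald_p = 2 * pnorm(-abs(z)),
       aic = 4 - 2 * ll1,
       nagelkerke = (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n)))
}

# Greedy clump reference: per cluster, ascending p, drop on |r| > r_max.
oracle_greedy_clump <- function(stats, mat, assignment, r_max) {
  kept <- character(0)
  for (cl in sort(unique(assignment$cluster_id))) {
    probes <- assignment$probe_id[assignment$cluster_id == cl]
    sub <- stats[stats$probe_id %in% probes, ]
    sub <- sub[order(sub$p, sub$probe_id), ]
    kept_cl <- character(0)
    for (pid in sub$probe_id) {
      drop <- FALSE
      for (q in kept_cl) {
        if (abs(cor(mat[pid, ], mat[q, ])) > r_max) { drop <- TRUE; break }
      }
      if (!drop) kept_cl <- c(kept_cl, pid)
    }
    kept <- c(kept, kept_cl)
  }
  kept
}

# Monte-Carlo agreement check for a vector of posterior means against a
# deterministic oracle: per-probe z = |dev| / MCSE should look standard
# normal. A per-probe 3-SE cut has a ~5% familywise false-alarm rate over a
# 20-probe block, so the hard bound is the Sidak-adjusted 99% Gaussian
# envelope; at least 90% of probes must additionally sit within 3 MCSE.
expect_mc_agreement <- function(got, oracle, mcse, label = "MC agreement") {
  z <- abs(got - oracle) / pmax(mcse, 1e-12)
  k <- length(z)
  fam_bound <- qnorm(1 - (1 - 0.99^(1 / k)) / 2)
  testthat::expect_lt(max(z), fam_bound, label = paste(label, "max z"))
  testthat::expect_gte(mean(z <= 3), 0.9, label = paste(label, "3-SE coverage"))
}

# Batch-means Monte-Carlo standard error of a chain's mean.
batch_mcse <- function(chain, n_batches = 20) {
  n <- length(chain)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(chain[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  sd(means) / sqrt(n_batches)
}

# Small random annotation on a couple of chromosomes.
random_annotation <- function(m, chroms = c("1", "2"), max_pos = 1e6) {
  tibble::tibble(
    probe_id = sprintf("p%03d", seq_len(m)),
    chrom = sample(chroms, m, replace = TRUE),
    pos = sample.int(max_pos, m)
  )
}

components_to_partition <- function(ann_sorted, comp_by_row) {
  split(ann_sorted$probe_id, comp_by_row)
}

# Compare two partitions (sets of probe-id sets), ignoring labels.
same_partition <- function(cs, probe_id, comp) {
  a <- unname(lapply(split(cs$probe_id, cs$cluster_id), sort))
  b <- unname(lapply(split(probe_id, comp), sort))
  setequal(lapply(a, paste, collapse = "|"), lapply(b, paste, collapse = "|"))
}
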