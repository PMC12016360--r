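# Structural priors: partitions of the probe set used as blocks of the
# probe-probe correlation matrix. Four constructions are provided:
# co-methylated-region (CMR) chaining, sliding windows, TAD interval
# assignment, and a random-cluster null model.

#' Construct a cluster set
#'
#' A cluster set is a partition of the probe universe: a tibble with columns
#' `probe_id` and `cluster_id` (dense integers `0..n_clusters-1`), carrying a
#' `label` attribute naming the prior and its parameters. Raw cluster keys are
#' densified in order of first appearance.
#'
#' @param probe_id Character vector of probe ids (each appearing once).
#' @param cluster_key Vector of arbitrary per-probe cluster keys.
#' @param label Human-readable prior label, e.g. `"window:5000"`.
#' @return A `cluster_set` tibble.
#' @export
new_cluster_set <- function(probe_id, cluster_key, label) {
  if (anyDuplicated(probe_id)) {
    stop_validation("cluster set is not a partition: duplicated probe id(s)")
  }
  if (length(probe_id) != length(cluster_key)) {
    stop_validation("probe_id and cluster_key lengths differ")
  }
  dense <- match(cluster_key, unique(cluster_key)) - 1L
  cs <- tibble(probe_id = as.character(probe_id), cluster_id = dense)
  structure(cs, label = label, class = c("cluster_set", class(cs)))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set '%s': %d probes in %d clusters>\n",
              attr(x, "label"), nrow(x), n_clusters(x)))
  NextMethod()
}

#' Number of clusters in a cluster set
#' @param cs A `cluster_set`.
#' @return Integer count of clusters.
#' @export
n_clusters <- function(cs) {
  length(unique(cs$cluster_id))
}

cluster_sizes <- function(cs) {
  as.integer(table(cs$cluster_id))
}

#' Sliding-window clusters
#'
#' Chains position-sorted probes per chromosome: two consecutive probes join
#' the same cluster iff their gap is at most `window` basepairs; clusters are
#' maximal such runs. This reproduces the proximity-only degeneration of CMR
#' chaining (see [cmr_clusters()]) in which the correlation test is bypassed.
#' Window sizes of 5 kb, 10 kb, 20 kb, 100 kb, 500 kb and 1 Mb are the
#' documented presets.
#'
#' @param ann Probe annotation tibble (`probe_id`, `chrom`, `pos`).
#' @param window Window size in basepairs (>= 1).
#' @return A `cluster_set` labelled `"window:<bp>"`.
#' @export
sliding_window_clusters <- function(ann, window) {
  stopifnot(window >= 1)
  ann <- validate_probe_annotation(ann)
  ann <- ann[canonical_probe_order(ann), , drop = FALSE]
  key <- chain_key_by_chrom(ann, function(sub) {
    gaps <- diff(sub$pos)
    cumsum(c(TRUE, gaps > window))
  })
  new_cluster_set(ann$probe_id, key, sprintf("window:%d", as.integer(window)))
}

# Apply a per-chromosome run-labeller and return globally unique keys.
chain_key_by_chrom <- function(ann, labeller) {
  unlist(lapply(split(seq_len(nrow(ann)), ann$chrom), function(idx) {
    sub <- ann[idx, , drop = FALSE]
    paste(sub$chrom[1], labeller(sub), sep = "#")
  })[unique(ann$chrom)], use.names = FALSE)
}

#' Co-methylated-region (CMR) clusters
#'
#' Chains position-sorted consecutive probes per chromosome into co-methylated
#' regions. Two consecutive probes join one cluster iff (a) their genomic gap
#' is at most `maxprbdst`, (b) the Pearson correlation of their methylation
#' rows is at least `corlo`, and (c) when a reference CpG map is supplied,
#' every gap between consecutive reference CpGs lying between the two probes
#' (taking the probes' own positions as endpoints) is at most `corlodst`.
#' Clusters are maximal chains. Probes with zero-variance methylation rows
#' have undefined correlation and fail predicate (b).
#'
#' The documented preset (lenient, to cluster as many probes as possible) is
#' `corlo = 0.2`, `maxprbdst = 100000`, `corlodst = 800`. Setting
#' `corlo = 1e-10` with `corlodst = maxprbdst = w` and no CpG map degenerates
#' to [sliding_window_clusters()] with window `w`.
#'
#' @param ann Probe annotation tibble.
#' @param mat Methylation matrix (probes x samples) covering all annotated
#'   probes; at least 3 samples.
#' @param corlo Probe-probe correlation threshold in `[0, 1]`.
#' @param maxprbdst Maximum distance between consecutive probes (bp).
#' @param corlodst Maximum distance between inter-probe reference CpGs (bp).
#' @param cpg_positions Optional named list: per (normalized) chromosome, a
#'   sorted integer vector of reference CpG positions.
#' @return A `cluster_set`.
#' @export
cmr_clusters <- function(ann, mat, corlo = 0.2, maxprbdst = 100000,
                         corlodst = 800, cpg_positions = NULL) {
  stopifnot(corlo >= 0, corlo <= 1, maxprbdst >= 1, corlodst >= 1)
  ann <- validate_probe_annotation(ann)
  if (ncol(mat) < 3) {
    stop_validation("CMR construction needs >= 3 samples (got %d)", ncol(mat))
  }
  missing_probes <- setdiff(ann$probe_id, rownames(mat))
  if (length(missing_probes)) {
    stop_validation("methylation matrix lacks annotated probe(s): %s",
                    paste(head(missing_probes, 5), collapse = ", "))
  }
  ann <- ann[canonical_probe_order(ann), , drop = FALSE]
  key <- chain_key_by_chrom(ann, function(sub) {
    n <- nrow(sub)
    if (n == 1) return(1L)
    linked <- vapply(seq_len(n - 1), function(i) {
      cmr_pair_linked(sub$pos[i], sub$pos[i + 1],
                      mat[sub$probe_id[i], ], mat[sub$probe_id[i + 1], ],
                      corlo, maxprbdst, corlodst,
                      cpg_positions[[sub$chrom[1]]])
    }, logical(1))
    cumsum(c(TRUE, !linked))
  })
  label <- sprintf("cmr(corlo=%g,maxprbdst=%d,corlodst=%d)",
                   corlo, as.integer(maxprbdst), as.integer(corlodst))
  new_cluster_set(ann$probe_id, key, label)
}

cmr_pair_linked <- function(pos1, pos2, row1, row2, corlo, maxprbdst,
                            corlodst, cpg_pos) {
  if (pos2 - pos1 > maxprbdst) return(FALSE)
  if (sd(row1) == 0 || sd(row2) == 0) return(FALSE)  # undefined r: fail corlo
  if (cor(row1, row2) < corlo) return(FALSE)
  if (!is.null(cpg_pos)) {
    between <- cpg_pos[cpg_pos > pos1 & cpg_pos < pos2]
    gaps <- diff(c(pos1, between, pos2))
    if (any(gaps > corlodst)) return(FALSE)
  }
  TRUE
}

#' TAD interval clusters
#'
#' Assigns each probe to the topologically-associating-domain interval
#' containing it: same normalized chromosome and 0-based position
#' (`pos - 1`) within the half-open interval `[start, end)`. Probes contained
#' in no interval become singleton clusters. Probes contained in several
#' (overlapping) intervals go to the interval with the smallest start,
#' breaking ties by smallest end.
#'
#' @param ann Probe annotation tibble.
#' @param tads Interval tibble from [read_tad_scaffold()].
#' @return A `cluster_set` labelled `"tad"`.
#' @export
tad_clusters <- function(ann, tads) {
  ann <- validate_probe_annotation(ann)
  ann <- ann[canonical_probe_order(ann), , drop = FALSE]
  tads$chrom <- normalize_chrom(tads$chrom)
  key <- rep(NA_character_, nrow(ann))
  for (ch in unique(ann$chrom)) {
    pi <- which(ann$chrom == ch)
    sub <- tads[tads$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    # 1-based closed IRanges; probe pos converted to 0-based before lookup
    probes_ir <- IRanges::IRanges(start = ann$pos[pi] - 1L, width = 1L)
    tads_ir <- IRanges::IRanges(start = sub$start, end = sub$end - 1L)
    hits <- IRanges::findOverlaps(probes_ir, tads_ir)
    if (!length(hits)) next
    h <- tibble(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
    h <- dplyr::arrange(h, .data$q, sub$start[.data$s], sub$end[.data$s])
    h <- h[!duplicated(h$q), , drop = FALSE]
    key[pi[h$q]] <- paste0("tad#", sub$interval_id[h$s])
  }
  unassigned <- is.na(key)
  key[unassigned] <- paste0("singleton#", ann$probe_id[unassigned])
  new_cluster_set(ann$probe_id, key, "tad")
}

#' Raw draws from the random-cluster null distributions
#'
#' The random-cluster null model draws, per random set, a cluster count
#' `C ~ Normal(mean = 2880, SD = 144)` and per-cluster probe counts
#' `P ~ LogNormal(meanlog = log(82), sdlog = 0.7)` — a rough match to the
#' observed TAD cluster-size distribution (min 1, Q1 45, median 82, mean 118,
#' Q3 138, max 2690 over 2,880 clusters). These helpers expose the raw
#' continuous draws, before the integer rounding/clamping that
#' [random_clusters()] applies.
#'
#' @param n Number of draws.
#' @param meanlog,sdlog Log-scale parameters of the size distribution.
#' @return Numeric vector of draws.
#' @export
rcluster_size_draws <- function(n, meanlog = log(82), sdlog = 0.7) {
  rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' @rdname rcluster_size_draws
#' @param mean,sd Parameters of the cluster-count distribution.
#' @export
rcluster_count_draws <- function(n, mean = 2880, sd = 144) {
  rnorm(n, mean = mean, sd = sd)
}

#' Random-cluster null model
#'
#' Generates `n_sets` random partitions of the probe universe, used as a null
#' model against structured priors. Per set: the cluster count is drawn from
#' `Normal(2880, 144)` rounded to the nearest positive integer (non-positive
#' roundings are resampled); per-cluster target sizes are drawn from
#' `LogNormal(log(82), 0.7)`, rounded with a floor of 1; probes are assigned
#' by a single random permutation partitioned according to the drawn sizes.
#' If the drawn sizes exhaust the probes, later clusters are truncated or
#' dropped; leftover probes become singleton clusters. Chromosome coherence
#' is deliberately not enforced — the null model must lack genomic structure.
#'
#' Each set uses its own seeded stream (`seed + set_index - 1`), so the sets
#' are individually reproducible.
#'
#' @param ann Probe annotation tibble.
#' @param n_sets Number of random sets (the reference analysis used ten).
#' @param seed Integer seed.
#' @param count_mean,count_sd Cluster-count distribution parameters.
#' @param size_meanlog,size_sdlog Cluster-size distribution parameters.
#' @return A list of `cluster_set`s, labelled `"random:<i>"`.
#' @export
random_clusters <- function(ann, n_sets = 10, seed,
                            count_mean = 2880, count_sd = 144,
                            size_meanlog = log(82), size_sdlog = 0.7) {
  stopifnot(n_sets >= 1)
  ann <- validate_probe_annotation(ann)
  m <- nrow(ann)
  lapply(seq_len(n_sets), function(i) {
    set.seed(seed + i - 1L)
    n_cl <- 0L
    while (n_cl < 1L) {
      n_cl <- as.integer(round(rcluster_count_draws(1, count_mean, count_sd)))
    }
    sizes <- pmax(1L, as.integer(round(
      rcluster_size_draws(n_cl, size_meanlog, size_sdlog))))
    perm <- sample(ann$probe_id)
    key <- character(m)
    pos <- 1L
    for (k in seq_along(sizes)) {
      if (pos > m) break
      take <- min(sizes[k], m - pos + 1L)
      key[pos:(pos + take - 1L)] <- sprintf("r%d", k)
      pos <- pos + take
    }
    if (pos <= m) {  # size draws fell short: leftovers become singletons
      key[pos:m] <- sprintf("left%d", pos:m)
    }
    # store in canonical annotation order for downstream alignment
    key_by_probe <- setNames(key, perm)
    new_cluster_set(ann$probe_id, unname(key_by_probe[ann$probe_id]),
                    sprintf("random:%d", i))
  })
}

#' Summarize a cluster-size distribution
#'
#' Quartiles of the probes-per-cluster distribution plus the percentage of
#' probes lying in non-singleton clusters (clusters of two or more probes),
#' the bookkeeping used to compare structural priors.
#'
#' @param cs A `cluster_set`.
#' @return One-row tibble: `n_clusters`, `min`, `q1`, `median`, `mean`, `q3`,
#'   `max`, `pct_nonsingleton_probes`.
#' @export
cluster_summary <- function(cs) {
  sizes <- cluster_sizes(cs)
  if (!length(sizes)) stop_validation("empty cluster set")
  q <- unname(quantile(sizes, c(0.25, 0.5, 0.75)))
  tibble(
    n_clusters = length(sizes),
    min = min(sizes), q1 = q[1], median = q[2], mean = mean(sizes),
    q3 = q[3], max = max(sizes),
    pct_nonsingleton_probes = 100 * sum(sizes[sizes >= 2]) / sum(sizes)
  )
}

#' Drop singleton clusters
#'
#' Removes probes that sit in singleton clusters from the analysis universe;
#' the count removed is stored as `attr(x, "n_dropped")`. Downstream inputs
#' (matrix, summary statistics) are restricted via [intersect_probes()].
#'
#' @param cs A `cluster_set`.
#' @return A `cluster_set` containing only clusters of size >= 2.
#' @export
drop_singletons <- function(cs) {
  sizes <- table(cs$cluster_id)
  keep_ids <- as.integer(names(sizes)[sizes >= 2])
  keep <- cs$cluster_id %in% keep_ids
  if (!any(keep)) stop_validation("dropping singletons leaves no probes")
  out <- new_cluster_set(cs$probe_id[keep], cs$cluster_id[keep],
                         paste0(attr(cs, "label"), ",nosingleton"))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read / write cluster assignments
#'
#' @param path TSV with header columns `probe_id`, `cluster_id`.
#' @param label Label to attach on read (defaults to the file name).
#' @return A `cluster_set`.
#' @export
read_cluster_assignments <- function(path, label = basename(path)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("probe_id", "cluster_id"), names(tab))
  if (length(missing_cols)) {
    stop_format("cluster assignment file '%s' lacks column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  new_cluster_set(tab$probe_id, tab$cluster_id, label)
}

#' @rdname read_cluster_assignments
#' @param cs A `cluster_set`.
#' @export
write_cluster_assignments <- function(cs, path) {
  readr::write_tsv(as_tibble(cs)[c("probe_id", "cluster_id")], path,
                   progress = FALSE)
  invisible(path)
}
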