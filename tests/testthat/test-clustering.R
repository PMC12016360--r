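one_chrom_ann <- function(pos, chrom = "1") {
  tibble::tibble(probe_id = sprintf("p%02d", seq_along(pos)),
                 chrom = chrom, pos = as.integer(pos))
}

test_that("sliding windows chain probes by gap and stay a partition", {
  ann <- one_chrom_ann(c(100, 3000, 20000))
  cs <- sliding_window_clusters(ann, 5000)
  expect_equal(n_clusters(cs), 2L)
  expect_true(same_partition(cs, ann$probe_id, c(1, 1, 2)))

  cs1 <- sliding_window_clusters(ann, 1)
  expect_equal(n_clusters(cs1), nrow(ann))
  expect_equal(sort(cs1$cluster_id), 0:2)
})

test_that("sliding windows equal the brute-force transitive-closure oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    ann <- random_annotation(40, chroms = c("1", "2"), max_pos = 50000)
    window <- sample(c(100, 1000, 5000, 20000), 1)
    cs <- sliding_window_clusters(ann, window)
    expect_equal(sum(table(cs$cluster_id)), nrow(ann))
    for (ch in unique(ann$chrom)) {
      sub <- ann[ann$chrom == ch, ]
      comp <- oracle_window_components(sub$pos, window)
      cs_sub <- cs[cs$probe_id %in% sub$probe_id, ]
      expect_true(same_partition(cs_sub, sub$probe_id, comp))
    }
  }
})

test_that("enlarging the window never increases the cluster count", {
  set.seed(11)
  ann <- random_annotation(60, max_pos = 2e5)
  windows <- c(10, 100, 1000, 10000, 1e5)
  counts <- vapply(windows, function(w) {
    n_clusters(sliding_window_clusters(ann, w))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("CMR chaining respects correlation, distance and CpG-gap predicates", {
  ann <- one_chrom_ann(c(1000, 1500))
  row <- rnorm(10)
  mat <- rbind(p01 = row, p02 = row)
  colnames(mat) <- paste0("s", 1:10)
  cs <- cmr_clusters(ann, mat, corlo = 0.2, maxprbdst = 1e5, corlodst = 800)
  expect_equal(n_clusters(cs), 1L)

  mat2 <- rbind(p01 = row, p02 = -row)
  colnames(mat2) <- colnames(mat)
  cs2 <- cmr_clusters(ann, mat2, corlo = 0.2, maxprbdst = 1e5, corlodst = 800)
  expect_equal(n_clusters(cs2), 2L)

  # CpG-gap predicate: 1000 bp apart, corlodst 800: split without an
  # intermediate reference CpG, joined with one at the midpoint
  ann3 <- one_chrom_ann(c(1000, 2000))
  cs3 <- cmr_clusters(ann3, mat, corlo = 0.2, maxprbdst = 1e5, corlodst = 800,
                      cpg_positions = list("1" = integer(0)))
  expect_equal(n_clusters(cs3), 2L)
  cs4 <- cmr_clusters(ann3, mat, corlo = 0.2, maxprbdst = 1e5, corlodst = 800,
                      cpg_positions = list("1" = 1500L))
  expect_equal(n_clusters(cs4), 1L)

  expect_error(cmr_clusters(ann, mat[, 1:2]), ">= 3 samples")
})

test_that("CMR chaining equals the brute-force three-predicate oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    pos <- sort(sample.int(50000, 20))
    ann <- one_chrom_ann(pos)
    mat <- matrix(rnorm(20 * 15), 20, 15,
                  dimnames = list(ann$probe_id, paste0("s", 1:15)))
    # induce some correlated neighbours
    for (i in seq(1, 19, by = 4)) mat[i + 1, ] <- mat[i, ] + rnorm(15, sd = 0.4)
    cpgs <- sort(sample.int(50000, 200))
    cs <- cmr_clusters(ann, mat, corlo = 0.3, maxprbdst = 5000, corlodst = 900,
                       cpg_positions = list("1" = cpgs))
    comp <- oracle_cmr_components(pos, mat, 0.3, 5000, 900, cpgs)
    expect_true(same_partition(cs, ann$probe_id, comp))
  }
})

test_that("CMR with a vanishing correlation threshold reduces to sliding windows", {
  set.seed(4)
  ann <- random_annotation(50, max_pos = 1e5)
  # co-methylated data: a shared positive component keeps every adjacent
  # sample correlation above any vanishing threshold, which is the regime
  # in which the proximity-only degeneration is exact
  shared <- rnorm(40)
  mat <- sqrt(0.5) * matrix(rep(shared, each = 50), 50, 40) +
    sqrt(0.5) * matrix(rnorm(50 * 40), 50, 40)
  dimnames(mat) <- list(ann$probe_id, paste0("s", 1:40))
  w <- 3000
  cs_cmr <- cmr_clusters(ann, mat, corlo = 1e-10, maxprbdst = w, corlodst = w)
  cs_win <- sliding_window_clusters(ann, w)
  expect_equal(cs_cmr$probe_id, cs_win$probe_id)
  expect_true(same_partition(cs_cmr, cs_win$probe_id, cs_win$cluster_id))
})

test_that("TAD assignment matches the exhaustive containment scan", {
  tads <- tibble::tibble(chrom = "1", start = 0L, end = 1000L,
                         interval_id = "t1")
  ann <- one_chrom_ann(500)
  cs <- tad_clusters(ann, tads)
  expect_equal(n_clusters(cs), 1L)

  ann_off <- one_chrom_ann(500, chrom = "9")
  expect_equal(n_clusters(tad_clusters(ann_off, tads)), 1L)  # singleton

  set.seed(21)
  ann50 <- random_annotation(50, chroms = c("1", "2"), max_pos = 10000)
  tads5 <- tibble::tibble(
    chrom = c("1", "1", "1", "2", "2"),
    start = c(0L, 2000L, 1500L, 0L, 5000L),
    end = c(2000L, 6000L, 2500L, 5000L, 9000L),
    interval_id = paste0("t", 1:5)
  )
  cs50 <- tad_clusters(ann50, tads5)
  expected <- oracle_tad_assign(ann50, tads5)
  expected[is.na(expected)] <- paste0("single_", ann50$probe_id[is.na(expected)])
  expect_true(same_partition(cs50, ann50$probe_id, expected))
})

test_that("random clusters partition the probes reproducibly per seed", {
  set.seed(99)
  ann <- random_annotation(200)
  sets <- random_clusters(ann, n_sets = 3, seed = 7)
  expect_length(sets, 3)
  for (cs in sets) {
    expect_setequal(cs$probe_id, ann$probe_id)
    expect_equal(sum(cluster_summary(cs)$n_clusters >= 1), 1)
    expect_equal(nrow(cs), 200)
  }
  again <- random_clusters(ann, n_sets = 3, seed = 7)
  for (i in 1:3) expect_identical(sets[[i]], again[[i]])
  # different set index => different stream
  expect_false(identical(sets[[1]]$cluster_id, sets[[2]]$cluster_id))
  # set i of a shorter run equals set i of a longer run (per-set streams)
  expect_identical(random_clusters(ann, n_sets = 1, seed = 7)[[1]], sets[[1]])
})

test_that("cluster summaries report quartiles and the non-singleton percentage", {
  cs <- new_cluster_set(c("a", "b", "c", "d"), c(1, 2, 3, 3), "toy")
  s <- cluster_summary(cs)
  expect_equal(s$min, 1)
  expect_equal(s$max, 2)
  expect_equal(s$pct_nonsingleton_probes, 50)

  all_single <- new_cluster_set(letters[1:5], 1:5, "singles")
  expect_equal(cluster_summary(all_single)$pct_nonsingleton_probes, 0)

  set.seed(8)
  sizes <- sample.int(50, 1000, replace = TRUE)
  cs_big <- new_cluster_set(sprintf("p%05d", seq_len(sum(sizes))),
                            rep(seq_along(sizes), sizes), "big")
  s_big <- cluster_summary(cs_big)
  sorted <- sort(sizes)
  q <- unname(quantile(sorted, c(0.25, 0.5, 0.75)))
  expect_equal(c(s_big$q1, s_big$median, s_big$q3), q)
  expect_true(s_big$min <= s_big$q1 && s_big$q1 <= s_big$median &&
                s_big$median <= s_big$q3 && s_big$q3 <= s_big$max)
})

test_that("dropping singletons removes exactly the right probes", {
  cs <- new_cluster_set(c("a", "b", "c", "d"), c(1, 2, 2, 2), "toy")
  out <- drop_singletons(cs)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_dropped"), 1L)

  no_single <- new_cluster_set(c("a", "b", "c", "d"), c(1, 1, 2, 2), "toy")
  out2 <- drop_singletons(no_single)
  expect_equal(out2$probe_id, no_single$probe_id)
  expect_equal(attr(out2, "n_dropped"), 0L)

  set.seed(3)
  ann <- random_annotation(100)
  cs_r <- random_clusters(ann, 1, seed = 5)[[1]]
  sizes <- table(cs_r$cluster_id)
  n_single <- sum(table(cs_r$cluster_id)[as.character(cs_r$cluster_id)] == 1)
  out3 <- drop_singletons(cs_r)
  expect_equal(nrow(out3), 100 - n_single)

  only_singles <- new_cluster_set(c("a", "b"), 1:2, "s")
  expect_error(drop_singletons(only_singles), "no probes")
})

test_that("cluster assignments round-trip through TSV", {
  cs <- new_cluster_set(c("a", "b", "c"), c("x", "x", "y"), "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_assignments(cs, path)
  back <- read_cluster_assignments(path, label = "toy")
  expect_equal(back$probe_id, cs$probe_id)
  expect_equal(back$cluster_id, cs$cluster_id)
})
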