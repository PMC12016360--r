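# Readers/writers for the on-disk artifacts of the scoring pipeline, with
# strict validation. Conventions: probe annotation positions are 1-based
# (manifest convention); BED intervals are 0-based half-open; tab vs comma is
# auto-detected from the header line of each file.

sumstats_cols <- c("probe_id", "beta", "se", "n", "p")

#' Read marginal association summary statistics
#'
#' Reads a delimited table of per-probe marginal (MWAS) summary statistics:
#' effect estimate, standard error, per-probe sample size and p-value. Column
#' order is free; extra columns (e.g. `chrom`, `pos`) are carried through.
#'
#' @param path Path to a TSV/CSV file with header columns `probe_id`, `beta`,
#'   `se`, `n`, `p`.
#' @return A tibble with one row per probe.
#' @seealso [write_summary_stats()], [intersect_probes()]
#' @export
read_summary_stats <- function(path) {
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(sumstats_cols, names(tab))
  if (length(missing_cols)) {
    stop_format("summary statistics file '%s' lacks required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  validate_summary_stats(as_tibble(tab))
}

validate_summary_stats <- function(stats) {
  incomplete <- which(!complete.cases(stats[sumstats_cols]))
  if (length(incomplete)) {
    stop_validation("summary statistics row(s) %s have missing required fields",
                    paste(head(incomplete, 5), collapse = ", "))
  }
  dup <- stats$probe_id[duplicated(stats$probe_id)]
  if (length(dup)) {
    stop_validation("duplicated probe id(s) in summary statistics: %s",
                    paste(unique(head(dup, 5)), collapse = ", "))
  }
  bad_se <- which(stats$se <= 0)
  if (length(bad_se)) {
    stop_validation("non-positive standard error for probe(s): %s (row %s)",
                    paste(stats$probe_id[head(bad_se, 5)], collapse = ", "),
                    paste(head(bad_se, 5), collapse = ", "))
  }
  bad_n <- which(stats$n < 2)
  if (length(bad_n)) {
    stop_validation("per-probe sample size < 2 for probe(s): %s",
                    paste(stats$probe_id[head(bad_n, 5)], collapse = ", "))
  }
  bad_p <- which(stats$p <= 0 | stats$p > 1)
  if (length(bad_p)) {
    stop_validation("p-value outside (0, 1] for probe(s): %s",
                    paste(stats$probe_id[head(bad_p, 5)], collapse = ", "))
  }
  if ("chrom" %in% names(stats)) stats$chrom <- normalize_chrom(stats$chrom)
  stats
}

#' Write summary statistics
#'
#' @param stats Summary-statistics tibble as returned by
#'   [read_summary_stats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats, path, progress = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' @param path TSV/CSV with header columns `probe_id`, `chrom`, `pos`
#'   (1-based basepair position).
#' @return Tibble with normalized chromosome labels (no `"chr"` prefix).
#' @export
read_probe_annotation <- function(path) {
  delim <- detect_delim(path)
  ann <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(c("probe_id", "chrom", "pos"), names(ann))
  if (length(missing_cols)) {
    stop_format("annotation file '%s' lacks required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  validate_probe_annotation(as_tibble(ann))
}

validate_probe_annotation <- function(ann) {
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup)) {
    stop_validation("duplicated probe id(s) in annotation: %s",
                    paste(unique(head(dup, 5)), collapse = ", "))
  }
  if (any(ann$pos < 1)) {
    stop_validation("annotation positions must be >= 1 (1-based); offending probe(s): %s",
                    paste(head(ann$probe_id[ann$pos < 1], 5), collapse = ", "))
  }
  ann$chrom <- normalize_chrom(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  ann
}

#' @rdname read_probe_annotation
#' @param ann Annotation tibble.
#' @export
write_probe_annotation <- function(ann, path) {
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(path)
}

#' Read a methylation matrix
#'
#' Reads a probes-by-samples matrix of (residualized) methylation values. The
#' first column holds probe ids; the header row holds sample ids.
#'
#' @param path TSV/CSV path.
#' @return Numeric matrix (probes x samples) with probe ids as rownames and
#'   sample ids as colnames.
#' @export
read_methylation_matrix <- function(path) {
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    stop_format("malformed methylation matrix '%s': %s (line %d)",
                path, probs$expected[1], probs$row[1] + 1L)
  }
  probe_ids <- as.character(tab[[1]])
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) {
    stop_validation("duplicated probe id(s) in methylation matrix: %s",
                    paste(unique(head(dup, 5)), collapse = ", "))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop_format("methylation matrix '%s' contains non-numeric cells", path)
  }
  rownames(mat) <- probe_ids
  validate_methylation_matrix(mat)
}

validate_methylation_matrix <- function(mat) {
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation("missing/non-finite methylation value at probe '%s', sample '%s'",
                    rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]])
  }
  mat
}

#' Write a methylation matrix
#'
#' @param mat Numeric probes-by-samples matrix with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(mat, path) {
  tab <- as_tibble(mat, rownames = "probe_id")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a TAD scaffold (BED)
#'
#' Reads a BED3/BED4 interval file of topologically associating domains (or any
#' interval scaffold). Intervals are 0-based half-open `[start, end)`. When no
#' fourth column is present, ids are generated as `"chrom:start-end"`.
#' Overlapping interval pairs are permitted but counted, and a warning reports
#' the count (retrievable as `attr(x, "n_overlaps")`).
#'
#' @param path BED file path (whitespace- or tab-separated, no header).
#' @return Tibble with columns `chrom`, `start`, `end`, `interval_id`.
#' @export
read_tad_scaffold <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("BED file '%s' is empty", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_format("BED line %d has fewer than 3 columns", which(nf < 3)[1])
  }
  chrom <- normalize_chrom(vapply(fields, `[[`, "", 1L))
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop_format("non-integer start/end on BED line %d",
                which(is.na(start) | is.na(end))[1])
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop_validation("BED line %d: start (%d) >= end (%d)",
                    bad[1], start[bad[1]], end[bad[1]])
  }
  interval_id <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                        sprintf("%s:%d-%d", chrom, start, end))
  tads <- tibble(chrom = chrom, start = start, end = end,
                 interval_id = interval_id)
  n_overlaps <- count_interval_overlaps(tads)
  if (n_overlaps > 0) {
    warn(sprintf("TAD scaffold contains %d overlapping interval pair(s)", n_overlaps))
  }
  attr(tads, "n_overlaps") <- n_overlaps
  tads
}

count_interval_overlaps <- function(tads) {
  total <- 0L
  for (ch in unique(tads$chrom)) {
    sub <- tads[tads$chrom == ch, ]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    total <- total + length(hits)
  }
  total
}

#' Read / write a binary phenotype table
#'
#' @param path TSV/CSV with header columns `sample_id` and `y` (0/1).
#' @return Tibble with `sample_id` (character) and `y` (integer 0/1).
#' @export
read_phenotypes <- function(path) {
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "y"), names(tab))
  if (length(missing_cols)) {
    stop_format("phenotype file '%s' lacks required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  validate_phenotypes(as_tibble(tab))
}

validate_phenotypes <- function(pheno) {
  dup <- pheno$sample_id[duplicated(pheno$sample_id)]
  if (length(dup)) {
    stop_validation("duplicated sample id(s) in phenotypes: %s",
                    paste(unique(head(dup, 5)), collapse = ", "))
  }
  if (!all(pheno$y %in% c(0L, 1L))) {
    stop_validation("phenotype values must be 0/1; offending sample(s): %s",
                    paste(head(pheno$sample_id[!pheno$y %in% c(0L, 1L)], 5),
                          collapse = ", "))
  }
  pheno$y <- as.integer(pheno$y)
  pheno
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Restrict all inputs to the common probe set
#'
#' Restricts summary statistics, methylation matrix and annotation to the
#' probes present in all three, in a single canonical order: sorted by
#' (chromosome, position), ties broken lexicographically by probe id. This
#' mirrors the training/test intersection rule: only probes common to both
#' sides enter the model.
#'
#' @param stats Summary-statistics tibble ([read_summary_stats()]).
#' @param mat Methylation matrix (probes x samples).
#' @param ann Probe annotation tibble ([read_probe_annotation()]).
#' @return A list with elements `stats`, `mat`, `annotation` (all restricted
#'   and canonically ordered) and `dropped`, a tibble reporting the number of
#'   probes dropped from each input.
#' @export
intersect_probes <- function(stats, mat, ann) {
  ann <- validate_probe_annotation(ann)
  common <- intersect(intersect(stats$probe_id, rownames(mat)), ann$probe_id)
  if (!length(common)) {
    stop_validation("no probes are common to summary statistics, methylation matrix and annotation")
  }
  ann_c <- ann[ann$probe_id %in% common, , drop = FALSE]
  ann_c <- ann_c[canonical_probe_order(ann_c), , drop = FALSE]
  ord <- ann_c$probe_id
  dropped <- tibble(
    input = c("stats", "mat", "annotation"),
    n_dropped = c(nrow(stats), nrow(mat), nrow(ann)) - length(common)
  )
  list(
    stats = stats[match(ord, stats$probe_id), , drop = FALSE],
    mat = mat[ord, , drop = FALSE],
    annotation = ann_c,
    dropped = dropped
  )
}
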