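# Internal helpers shared across modules.

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` (case-insensitive) so that manifest-style
#' (`"chr1"`) and plain (`"1"`) labels compare equal. All genomic inputs are
#' normalized on read, so downstream joins never mix dialects.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector without the `"chr"` prefix.
#' @examples
#' normalize_chrom(c("chr1", "2", "chrX"))
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

# Canonical probe order: (chrom, pos, probe_id), all ties broken
# lexicographically by probe_id. Deterministic regardless of input order.
canonical_probe_order <- function(ann) {
  order(ann$chrom, ann$pos, ann$probe_id, method = "radix")
}

# Guess the field separator of a delimited text file from its header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methylscore_validation_error")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methylscore_format_error")
}

assert_probe_alignment <- function(a, b, what_a = "first", what_b = "second") {
  if (identical(a, b)) return(invisible(TRUE))
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b)) {
    stop_validation(
      "probe sets differ between %s and %s input: %d only in %s (e.g. %s), %d only in %s (e.g. %s)",
      what_a, what_b,
      length(only_a), what_a, paste(head(only_a, 3), collapse = ", "),
      length(only_b), what_b, paste(head(only_b, 3), collapse = ", ")
    )
  }
  stop_validation("probe orders differ between %s and %s input (same set, different order)",
                  what_a, what_b)
}
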