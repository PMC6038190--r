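# Shared fixture builders: tiny in-code references and on-disk FASTA/TSV
# files written to tempdir at test time.

# A reference from explicit sequences; origin classes default to UNKNOWN.
tiny_reference <- function(sequences, origin = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%d", seq_along(sequences))
  if (is.null(origin)) origin <- rep("UNKNOWN", length(sequences))
  new_reference(ids, sequences, origin)
}

# Random sequence of given length over ACGU.
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(ids, seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_tmp_annotation <- function(ids, classes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ann.tsv")
  writeLines(c("id\torigin_class", paste0(ids, "\t", classes)), path)
  path
}

# Brute-force Hamming matcher, deliberately independent of the package's
# vectorised path: per-read, per-reference character comparison.
oracle_match <- function(read, ref_ids, ref_seqs, max_mm = 1L) {
  hits <- character(0)
  rs <- strsplit(read, "")[[1]]
  for (i in seq_along(ref_seqs)) {
    ss <- strsplit(ref_seqs[i], "")[[1]]
    if (length(ss) != length(rs)) next
    if (sum(ss != rs) <= max_mm) hits <- c(hits, ref_ids[i])
  }
  hits
}

# Closed-form one-vs-rest goodness-of-fit statistic, written as the
# two-cell sum (a different arithmetic path from chisq.test).
oracle_gof_chi2 <- function(k, n, p0) {
  e1 <- n * p0
  e2 <- n * (1 - p0)
  (k - e1)^2 / e1 + ((n - k) - e2)^2 / e2
}
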