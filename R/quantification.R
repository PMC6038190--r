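# Read-to-reference assignment with at most one substitution, count-matrix
# construction, RPKM, marker-content covariate and positional composition.

# Integer-code a set of equal-length sequences as an L x n matrix for fast
# vectorised Hamming comparison.
seq_int_matrix <- function(seqs, len) {
  matrix(unlist(lapply(seqs, utf8ToInt), use.names = FALSE),
         nrow = len, ncol = length(seqs))
}

# Split reference row indices by sequence length and pre-encode each bucket.
index_reference <- function(ref) {
  by_len <- split(seq_len(nrow(ref)), ref$length)
  lapply(by_len, function(idx) {
    len <- ref$length[idx[1]]
    list(idx = idx, mat = seq_int_matrix(ref$sequence[idx], len))
  })
}

#' Match one read against a piRNA reference
#'
#' A read is assigned to every reference piRNA of identical length whose
#' Hamming distance to the read is at most `max_mismatch` (substitutions
#' only; reads of different length never match, and reads containing N never
#' match). This mirrors small-RNA mapping that allows a single mismatch.
#'
#' @param read A single read sequence (T tolerated, normalised to U).
#' @param ref A `pirna_reference`.
#' @param max_mismatch Maximum number of substitutions (default 1).
#' @return Character vector of matching feature ids, in reference order.
#' @export
match_read <- function(read, ref, max_mismatch = 1L) {
  stopifnot(inherits(ref, "pirna_reference"), length(read) == 1L)
  read <- normalize_rna(read)
  if (grepl("[^ACGU]", read)) return(character(0))
  len <- nchar(read)
  same <- which(ref$length == len)
  if (length(same) == 0L) return(character(0))
  rint <- utf8ToInt(read)
  mm <- colSums(seq_int_matrix(ref$sequence[same], len) != rint)
  ref$id[same[mm <= max_mismatch]]
}

#' Quantify one sample's reads against a reference
#'
#' Assigns each adapter-trimmed read to all reference piRNAs within one
#' substitution (see [match_read()]) and accumulates per-feature counts.
#' Multi-matching reads are handled by `mode`: `"all"` credits every matched
#' feature (the default, because piRNA references contain near-duplicate
#' sequences and per-piRNA counts are reported), `"unique"` discards reads
#' matching more than one feature, `"fractional"` splits the read 1/m ways
#' and rounds the final totals half-to-even so the count matrix stays
#' integral.
#'
#' @param reads Character vector of read sequences, or a list with elements
#'   `sample_id` and `reads`.
#' @param ref A `pirna_reference`.
#' @param mode One of `"all"`, `"unique"`, `"fractional"`.
#' @param max_mismatch Maximum substitutions per match (default 1).
#' @return Integer count vector named by reference feature id.
#' @export
quantify_sample <- function(reads, ref, mode = c("all", "unique", "fractional"),
                            max_mismatch = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "pirna_reference"))
  if (is.list(reads)) reads <- reads$reads
  counts <- stats::setNames(numeric(nrow(ref)), ref$id)
  if (length(reads) == 0L) return(stats::setNames(as.integer(counts), ref$id))
  reads <- normalize_rna(reads)
  reads <- reads[!grepl("[^ACGU]", reads)]
  idx <- index_reference(ref)
  tab <- table(reads)
  uniq <- names(tab)
  nrep <- as.numeric(tab)
  lens <- nchar(uniq)
  for (i in seq_along(uniq)) {
    bucket <- idx[[as.character(lens[i])]]
    if (is.null(bucket)) next
    mm <- colSums(bucket$mat != utf8ToInt(uniq[i]))
    hit <- bucket$idx[mm <= max_mismatch]
    m <- length(hit)
    if (m == 0L) next
    if (mode == "all") {
      counts[hit] <- counts[hit] + nrep[i]
    } else if (mode == "unique") {
      if (m == 1L) counts[hit] <- counts[hit] + nrep[i]
    } else {
      counts[hit] <- counts[hit] + nrep[i] / m
    }
  }
  if (mode == "fractional") counts <- round(counts)
  stats::setNames(as.integer(counts), ref$id)
}

#' Assemble a count matrix from per-sample count vectors
#'
#' @param per_sample_counts Named list of count vectors, each aligned to the
#'   reference feature order (as returned by [quantify_sample()]).
#' @param ref A `pirna_reference`.
#' @param sample_order Optional character vector fixing column order
#'   (defaults to list order).
#' @return Integer matrix, features x samples, with dimnames.
#' @export
build_count_matrix <- function(per_sample_counts, ref, sample_order = NULL) {
  stopifnot(inherits(ref, "pirna_reference"))
  if (is.null(sample_order)) sample_order <- names(per_sample_counts)
  miss <- setdiff(sample_order, names(per_sample_counts))
  if (length(miss) > 0L) {
    stop("missing count vector for sample(s): ", paste(miss, collapse = ", "))
  }
  cols <- lapply(sample_order, function(s) {
    v <- per_sample_counts[[s]]
    if (length(v) != nrow(ref)) {
      stop("count vector for sample ", s, " has length ", length(v),
           ", expected ", nrow(ref))
    }
    v
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(ref$id, sample_order)
  storage.mode(m) <- "integer"
  m
}

#' Reads per kilobase of model per million mapped reads
#'
#' `count / ((length / 1000) * (column_total / 1e6))`, with the mature piRNA
#' sequence length as the per-feature model length.
#'
#' @param counts Numeric matrix, features x samples.
#' @param lengths Per-feature lengths in nt, recycled along rows.
#' @return Numeric matrix of RPKM values, same dimensions as `counts`.
#' @export
rpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), length(lengths) == nrow(counts),
            all(lengths > 0))
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("zero total mapped counts in sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts / (lengths / 1e3), 2L, totals / 1e6, "/")
}

#' Mean marker-set RPKM per sample
#'
#' Arithmetic mean RPKM over a marker gene/feature set, one value per
#' sample; used as the neuronal-content covariate when bulk tissue samples
#' vary in cell-type composition.
#'
#' @param rpkm_matrix RPKM matrix from [rpkm()].
#' @param marker_ids Feature ids of the marker set; all must be present.
#' @return Named numeric vector, one score per sample.
#' @export
marker_content_score <- function(rpkm_matrix, marker_ids) {
  if (length(marker_ids) == 0L) stop("empty marker list")
  miss <- setdiff(marker_ids, rownames(rpkm_matrix))
  if (length(miss) > 0L) {
    stop("marker id(s) absent from matrix: ", paste(miss, collapse = ", "))
  }
  colMeans(rpkm_matrix[marker_ids, , drop = FALSE])
}

#' Positional base-composition profile
#'
#' For each position k (1-based from the 5' end), the fraction of sequences
#' of length >= k whose k-th base equals `base`. Denominators shrink with k
#' as shorter sequences drop out; positions with a zero denominator get
#' `NaN`.
#'
#' @param sequences Character vector of RNA sequences.
#' @param base One of A, C, G, U.
#' @param max_pos Number of positions profiled (default 29).
#' @return Data frame with columns `position`, `fraction`, `denominator`.
#' @export
positional_base_content <- function(sequences, base, max_pos = 29L) {
  if (length(sequences) == 0L) stop("empty sequence collection")
  base <- normalize_rna(base)
  if (!base %in% c("A", "C", "G", "U") || nchar(base) != 1L) {
    stop("base must be one of A, C, G, U")
  }
  sequences <- normalize_rna(sequences)
  lens <- nchar(sequences)
  pos <- seq_len(max_pos)
  denom <- vapply(pos, function(k) sum(lens >= k), integer(1))
  frac <- vapply(pos, function(k) {
    keep <- lens >= k
    if (!any(keep)) return(NaN)
    mean(substr(sequences[keep], k, k) == base)
  }, numeric(1))
  data.frame(position = pos, fraction = frac, denominator = denom)
}

#' Trim a 3' adapter from reads (convenience helper, non-core)
#'
#' Finds the leftmost occurrence of the adapter prefix (at least
#' `min_overlap` bases, or the full remaining read at the 3' end) and trims
#' from there. Inputs are assumed adapter-trimmed in the core pipeline; this
#' helper exists for raw FASTQ convenience only and performs exact matching,
#' not error-tolerant trimming.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum adapter prefix length to trigger trimming.
#' @return Character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 10L) {
  adapter <- toupper(adapter)
  stopifnot(nchar(adapter) >= min_overlap)
  vapply(toupper(reads), function(r) {
    n <- nchar(r)
    # full-adapter (or longer-prefix) internal hit first
    hit <- regexpr(substr(adapter, 1L, min(nchar(adapter), n)), r,
                   fixed = TRUE)
    if (hit > 0L) return(substr(r, 1L, hit - 1L))
    # partial adapter prefix flush with the 3' end
    kmax <- min(nchar(adapter), n)
    if (kmax >= min_overlap) {
      for (k in kmax:min_overlap) {
        if (substr(r, n - k + 1L, n) == substr(adapter, 1L, k)) {
          return(substr(r, 1L, n - k))
        }
      }
    }
    r
  }, character(1), USE.NAMES = FALSE)
}
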