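#' Element-of-origin classes recognised by the reference annotation
#'
#' piRNAs are classified by the repeat/gene element they derive from:
#' SINE, LINE and LTR retrotransposons, genic (exonic/intronic) origin,
#' anything else, and UNKNOWN for records without an annotation row.
#'
#' @format Character vector of the six class labels.
#' @export
ORIGIN_CLASSES <- c("SINE", "LINE", "LTR", "GENIC", "OTHER", "UNKNOWN")

# Uppercase and convert DNA-style T to RNA U.
normalize_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Load a piRNA reference with element-of-origin annotation
#'
#' Reads a small-RNA reference FASTA together with a two-column tab-separated
#' annotation (`id`, `origin_class`) mapping each sequence identifier to the
#' genomic element class it derives from, in the style of piRBase. Sequences
#' are stored in the RNA alphabet (T normalised to U). Records whose id has
#' no annotation row get class `UNKNOWN`; annotation strings outside
#' SINE/LINE/LTR/GENIC map to `OTHER`. A record is flagged canonical when its
#' length falls in the 24-32 nt range typical of mature piRNAs; shorter
#' piRNA-like species remain in the reference with `is_canonical = FALSE`.
#'
#' @param fasta_path Path to the reference FASTA (plain or gzip).
#' @param annotation_path Path to the tab-separated annotation with header
#'   columns `id` and `origin_class`.
#' @return A `pirna_reference` data frame with columns `id`, `sequence`,
#'   `length`, `origin_class` (factor over [ORIGIN_CLASSES]) and
#'   `is_canonical`.
#' @export
load_reference <- function(fasta_path, annotation_path) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in reference FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw <- as.character(seqs)
  bad <- grepl("[^ACGTUacgtu]", raw)
  if (any(bad)) {
    stop("sequence with characters outside {A,C,G,T,U}: ",
         paste(ids[bad][seq_len(min(5L, sum(bad)))], collapse = ", "))
  }
  sequence <- normalize_rna(raw)
  len <- nchar(sequence)
  if (any(len < 15L | len > 45L)) {
    off <- ids[len < 15L | len > 45L]
    stop("sequence length outside the 15-45 nt sanity range: ",
         paste(off[seq_len(min(5L, length(off)))], collapse = ", "))
  }
  ann <- utils::read.delim(annotation_path, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "origin_class") %in% names(ann))) {
    stop("annotation must have columns 'id' and 'origin_class'")
  }
  cls <- toupper(ann$origin_class[match(ids, ann$id)])
  cls[is.na(cls)] <- "UNKNOWN"
  cls[!cls %in% ORIGIN_CLASSES] <- "OTHER"
  new_reference(ids, sequence, cls)
}

#' Construct a piRNA reference from in-memory vectors
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of sequences (T is normalised to U).
#' @param origin_class Character vector of origin classes; unknown strings
#'   map to `OTHER`, `NA` to `UNKNOWN`.
#' @return A `pirna_reference` data frame.
#' @export
new_reference <- function(id, sequence,
                          origin_class = rep("UNKNOWN", length(id))) {
  stopifnot(length(id) == length(sequence),
            length(id) == length(origin_class))
  if (length(id) == 0L) stop("reference must be non-empty")
  if (anyDuplicated(id)) stop("duplicate reference ids")
  sequence <- normalize_rna(sequence)
  origin_class <- toupper(as.character(origin_class))
  origin_class[is.na(origin_class)] <- "UNKNOWN"
  origin_class[!origin_class %in% ORIGIN_CLASSES] <- "OTHER"
  len <- nchar(sequence)
  ref <- data.frame(
    id = as.character(id),
    sequence = sequence,
    length = len,
    origin_class = factor(origin_class, levels = ORIGIN_CLASSES),
    is_canonical = len >= 24L & len <= 32L,
    stringsAsFactors = FALSE
  )
  class(ref) <- c("pirna_reference", "data.frame")
  ref
}

#' Element-of-origin proportions over a reference universe
#'
#' Computes, for each origin class, its fraction among a universe of piRNA
#' ids. With the default universe (all records) this is the genome-wide null
#' proportion used by [origin_enrichment()]. UNKNOWN-origin records are kept
#' in the universe by default because the null of interest is "all piRNAs
#' analysed"; set `drop_unknown = TRUE` to exclude them.
#'
#' @param ref A `pirna_reference`.
#' @param universe Optional character vector of ids (subset of the
#'   reference) over which proportions are computed.
#' @param drop_unknown Exclude UNKNOWN-origin records from the universe.
#' @return Named numeric vector over [ORIGIN_CLASSES], summing to 1.
#' @export
origin_proportions <- function(ref, universe = NULL, drop_unknown = FALSE) {
  stopifnot(inherits(ref, "pirna_reference"))
  if (is.null(universe)) universe <- ref$id
  if (length(universe) == 0L) stop("empty universe")
  miss <- setdiff(universe, ref$id)
  if (length(miss) > 0L) {
    stop("universe ids not in reference: ",
         paste(miss[seq_len(min(5L, length(miss)))], collapse = ", "))
  }
  cls <- ref$origin_class[match(universe, ref$id)]
  if (drop_unknown) {
    cls <- cls[cls != "UNKNOWN"]
    if (length(cls) == 0L) stop("empty universe after dropping UNKNOWN")
  }
  tab <- table(cls)
  out <- stats::setNames(numeric(length(ORIGIN_CLASSES)), ORIGIN_CLASSES)
  out[names(tab)] <- as.numeric(tab) / length(cls)
  out
}

#' Fraction of sequences with a 5' uridine
#'
#' The 1U bias -- over-representation of U at the first position -- is a
#' hallmark of primary piRNAs and is used here as a sequence-level QC check
#' on the reference or on any deregulated subset.
#'
#' @param sequences Character vector of RNA sequences (T tolerated).
#' @return Fraction in \[0, 1\].
#' @export
u1_fraction <- function(sequences) {
  if (length(sequences) == 0L) stop("empty sequence collection")
  mean(substr(normalize_rna(sequences), 1L, 1L) == "U")
}

#' Fraction of canonical-length (24-32 nt) records in a reference
#'
#' @param ref A `pirna_reference`.
#' @return Fraction in \[0, 1\].
#' @export
canonical_fraction <- function(ref) {
  stopifnot(inherits(ref, "pirna_reference"))
  mean(ref$is_canonical)
}

#' Screen a piRNA reference for snoRNA-embedded sequences
#'
#' snoRNA degradation fragments are a known contaminant of piRNA catalogs.
#' A reference piRNA counts as overlapping when its full sequence occurs as
#' an exact substring of at least one snoRNA (given strand only) -- the most
#' conservative reproducible matching rule.
#'
#' @param ref A `pirna_reference`.
#' @param sno_fasta Path to a snoRNA FASTA.
#' @return List with `n_overlapping`, `fraction_overlapping` and the
#'   overlapping `ids`.
#' @export
snorna_overlap <- function(ref, sno_fasta) {
  stopifnot(inherits(ref, "pirna_reference"))
  if (!file.exists(sno_fasta)) stop("snoRNA FASTA not found: ", sno_fasta)
  sno <- normalize_rna(as.character(Biostrings::readBStringSet(sno_fasta)))
  hit <- vapply(ref$sequence, function(s) {
    any(grepl(s, sno, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  list(
    n_overlapping = sum(hit),
    fraction_overlapping = sum(hit) / nrow(ref),
    ids = ref$id[hit]
  )
}

#' Write a reference to FASTA
#'
#' @param ref A `pirna_reference`.
#' @param path Output path.
#' @param alphabet `"RNA"` (U) or `"DNA"` (T).
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, alphabet = c("RNA", "DNA")) {
  stopifnot(inherits(ref, "pirna_reference"))
  alphabet <- match.arg(alphabet)
  seqs <- ref$sequence
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  x <- Biostrings::BStringSet(stats::setNames(seqs, ref$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a reference annotation table
#'
#' @param ref A `pirna_reference`.
#' @param path Output path for the tab-separated `id`/`origin_class` table.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ref, path) {
  stopifnot(inherits(ref, "pirna_reference"))
  utils::write.table(
    data.frame(id = ref$id, origin_class = as.character(ref$origin_class)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
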