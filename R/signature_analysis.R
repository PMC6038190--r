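# Downstream signature statistics: element-of-origin enrichment against the
# genome-wide null, positional cytosine-composition comparison, memory
# fractions across differentiation stages, direction-stratified overlaps and
# TOP-N hierarchical clustering with group-separation scoring.

# One-vs-rest goodness-of-fit statistic (1 df) for k successes out of n at
# null proportion p0, in its collapsed single-term form
# (k - n p0)^2 / (n p0 (1 - p0)).
gof_chi2 <- function(k, n, p0) {
  (k - n * p0)^2 / (n * p0 * (1 - p0))
}

#' Element-of-origin enrichment against a genome-wide null
#'
#' For each origin class, a one-vs-rest goodness-of-fit chi-square test
#' (1 df, no continuity correction) compares the observed class count among
#' a query set (e.g. the downregulated piRNAs) with the expectation under a
#' fixed null proportion (the class's genome-wide share among all piRNAs
#' analysed). Classes whose null proportion is exactly 0 or 1 cannot be
#' tested and are flagged untestable. The p-value is the upper-tail
#' chi-square probability, the conventional reading of a two-sided
#' chi-square test; no cross-class multiplicity correction is applied by
#' default (mirroring per-class reporting), but `bh_across_classes = TRUE`
#' adds a BH-adjusted column.
#'
#' @param query_ids Character vector of query feature ids (subset of the
#'   reference).
#' @param ref A `pirna_reference`.
#' @param null_props Named null proportions from [origin_proportions()].
#' @param bh_across_classes Add a `padj` column across classes.
#' @return Data frame with one row per class: `origin_class`, `k`, `n`,
#'   `p0`, `expected`, `chi2`, `p`, `direction` (enriched/depleted/none),
#'   `untestable`.
#' @export
origin_enrichment <- function(query_ids, ref, null_props,
                              bh_across_classes = FALSE) {
  stopifnot(inherits(ref, "pirna_reference"))
  n <- length(query_ids)
  if (n == 0L) stop("empty query set")
  miss <- setdiff(query_ids, ref$id)
  if (length(miss) > 0L) {
    stop("query ids not in reference: ",
         paste(miss[seq_len(min(5L, length(miss)))], collapse = ", "))
  }
  cls <- ref$origin_class[match(query_ids, ref$id)]
  classes <- names(null_props)
  rows <- lapply(classes, function(cl) {
    k <- sum(cls == cl)
    p0 <- unname(null_props[cl])
    expected <- n * p0
    if (p0 <= 0 || p0 >= 1) {
      return(data.frame(origin_class = cl, k = k, n = n, p0 = p0,
                        expected = expected, chi2 = NA_real_, p = NA_real_,
                        direction = "none", untestable = TRUE,
                        stringsAsFactors = FALSE))
    }
    chi2 <- gof_chi2(k, n, p0)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    direction <- if (k > expected) "enriched"
                 else if (k < expected) "depleted" else "none"
    data.frame(origin_class = cl, k = k, n = n, p0 = p0,
               expected = expected, chi2 = chi2, p = p,
               direction = direction, untestable = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh_across_classes) out$padj <- bh_adjust(out$p)
  out
}

#' Positional composition bias of deregulated sets versus all piRNAs
#'
#' Profiles the per-position content of `base` (default cytosine) over the
#' upregulated set, the downregulated set and the reference universe, and
#' reports the up-minus-all and down-minus-all differences — the statistic
#' behind the observation that upregulated disease piRNAs carry excess
#' cytosines at positions 2-9.
#'
#' @param up_ids,down_ids Deregulated feature id sets (disjoint; either may
#'   be empty).
#' @param universe_ids Reference universe ids (non-empty).
#' @param ref A `pirna_reference`.
#' @param base Queried base (default `"C"`).
#' @param max_pos Number of positions (default 29).
#' @param diff_threshold Absolute difference that flags a position as
#'   biased in the `flagged_*` attributes (default 0.1; display aid only).
#' @return Data frame with columns `position`, `frac_up`, `frac_down`,
#'   `frac_all`, `denom_up`, `denom_down`, `denom_all`, `diff_up`,
#'   `diff_down`; attributes `flagged_up` / `flagged_down` list positions
#'   exceeding the threshold.
#' @export
composition_bias <- function(up_ids, down_ids, universe_ids, ref,
                             base = "C", max_pos = 29L,
                             diff_threshold = 0.1) {
  stopifnot(inherits(ref, "pirna_reference"))
  if (length(universe_ids) == 0L) stop("empty universe")
  if (length(intersect(up_ids, down_ids)) > 0L) {
    stop("up and down sets must be disjoint")
  }
  get_seq <- function(ids) {
    miss <- setdiff(ids, ref$id)
    if (length(miss) > 0L) {
      stop("ids not in reference: ",
           paste(miss[seq_len(min(5L, length(miss)))], collapse = ", "))
    }
    ref$sequence[match(ids, ref$id)]
  }
  prof <- function(ids) {
    if (length(ids) == 0L) {
      return(data.frame(position = seq_len(max_pos), fraction = NA_real_,
                        denominator = 0L))
    }
    positional_base_content(get_seq(ids), base, max_pos)
  }
  p_up <- prof(up_ids)
  p_down <- prof(down_ids)
  p_all <- prof(universe_ids)
  out <- data.frame(
    position = p_all$position,
    frac_up = p_up$fraction, frac_down = p_down$fraction,
    frac_all = p_all$fraction,
    denom_up = p_up$denominator, denom_down = p_down$denominator,
    denom_all = p_all$denominator
  )
  out$diff_up <- out$frac_up - out$frac_all
  out$diff_down <- out$frac_down - out$frac_all
  attr(out, "flagged_up") <-
    out$position[!is.na(out$diff_up) & abs(out$diff_up) > diff_threshold]
  attr(out, "flagged_down") <-
    out$position[!is.na(out$diff_down) & abs(out$diff_down) > diff_threshold]
  out
}

#' Memory fraction: deregulated features already deregulated in fibroblasts
#'
#' Epigenetic memory at the small-RNA level: the fraction of features
#' deregulated at a differentiated stage (iPSC or neuron, PD vs control)
#' that were already deregulated in the parental fibroblasts. The default
#' is direction-agnostic membership; `direction_matched = TRUE` additionally
#' requires the same direction of change in both stages.
#'
#' @param stage_call `pirsig_call` at the differentiated stage (non-empty).
#' @param fibro_call `pirsig_call` in the parental fibroblasts.
#' @param direction_matched Require matching direction.
#' @param stage Stage label carried through to the report.
#' @return List with `stage`, `n_memory`, `n_total_deregulated`, `fraction`
#'   and the memory `ids`.
#' @export
memory_fraction <- function(stage_call, fibro_call, direction_matched = FALSE,
                            stage = "stage") {
  stopifnot(inherits(stage_call, "pirsig_call"),
            inherits(fibro_call, "pirsig_call"))
  stage_all <- union(stage_call$up, stage_call$down)
  if (length(stage_all) == 0L) stop("empty stage call")
  mem <- if (direction_matched) {
    union(intersect(stage_call$up, fibro_call$up),
          intersect(stage_call$down, fibro_call$down))
  } else {
    intersect(stage_all, union(fibro_call$up, fibro_call$down))
  }
  list(stage = stage, n_memory = length(mem),
       n_total_deregulated = length(stage_all),
       fraction = length(mem) / length(stage_all), ids = mem)
}

#' Direction-stratified overlap between two deregulation calls
#'
#' Counts features upregulated in both calls and downregulated in both
#' calls (Venn-style, per direction); a feature up in one cohort and down
#' in the other does not count as shared.
#'
#' @param call_a,call_b `pirsig_call` objects.
#' @return List with `up_shared`, `down_shared`, `n_up_shared`,
#'   `n_down_shared`, per-set sizes and `n_shared` (union of the two
#'   direction-matched intersections).
#' @export
direction_overlap <- function(call_a, call_b) {
  stopifnot(inherits(call_a, "pirsig_call"), inherits(call_b, "pirsig_call"))
  up <- intersect(call_a$up, call_b$up)
  down <- intersect(call_a$down, call_b$down)
  list(
    up_shared = up, down_shared = down,
    n_up_shared = length(up), n_down_shared = length(down),
    sizes = c(a_up = length(call_a$up), a_down = length(call_a$down),
              b_up = length(call_b$up), b_down = length(call_b$down)),
    n_shared = length(union(up, down))
  )
}

#' Hierarchical clustering of samples over selected features
#'
#' Clusters samples by 1 - Pearson correlation over the selected features
#' (typically the TOP100 deregulated piRNAs), average linkage, cut into two
#' clusters, and scores separation of the known groups with the adjusted
#' Rand index.
#'
#' @param log_matrix Log-transformed expression matrix.
#' @param feature_ids Features to cluster on (must be rows of the matrix).
#' @param sheet Sample sheet aligned to columns (matched by `sample_id`
#'   when present).
#' @param group_col Sheet column holding the reference labels (default
#'   `"group"`).
#' @param k Number of clusters to cut (default 2).
#' @return List with the `hclust` object, integer `clusters` per sample,
#'   the reference `groups` and `ari`.
#' @export
hcluster <- function(log_matrix, feature_ids, sheet, group_col = "group",
                     k = 2L) {
  miss <- setdiff(feature_ids, rownames(log_matrix))
  if (length(miss) > 0L) {
    stop("features not in matrix: ",
         paste(miss[seq_len(min(5L, length(miss)))], collapse = ", "))
  }
  if (ncol(log_matrix) < 2L) stop("need >= 2 samples")
  if (!is.null(sheet$sample_id) && !is.null(colnames(log_matrix))) {
    sheet <- sheet[match(colnames(log_matrix), sheet$sample_id), ,
                   drop = FALSE]
  }
  sub <- log_matrix[feature_ids, , drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample column(s): ",
         paste(colnames(sub)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(sub))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  groups <- sheet[[group_col]]
  list(hclust = hc, clusters = cl, groups = groups,
       ari = mclust::adjustedRandIndex(cl, groups))
}
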