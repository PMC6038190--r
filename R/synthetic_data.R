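# Seeded synthetic-data generator: references with planted sequence biases,
# NB count matrices with planted group effects, FASTQ reads, and ground
# truth tables for parameter-recovery testing.

#' Simulation parameters
#'
#' Bundles every knob of the synthetic small-RNA study: reference
#' composition (origin-class mixture, canonical-length share, 5'U
#' probability, positional cytosine bias of the planted upregulated set),
#' count model (NB with log-normal baseline means, per-sample library-size
#' multipliers, planted log2 fold changes, optional sex effects) and group
#' layout. All randomness flows from the single integer `seed`.
#'
#' @param n_features Number of reference piRNAs.
#' @param origin_probs Named probabilities over SINE/LINE/LTR/GENIC/OTHER
#'   (must sum to 1) used for non-planted and planted-up features.
#' @param sine_prob_in_down SINE probability for planted-down features; the
#'   other classes share the remainder proportionally. Emulates the
#'   SINE/LINE over-representation among downregulated piRNAs.
#' @param canonical_frac Share of features with canonical 24-32 nt lengths;
#'   the rest are 18-23 nt piRNA-like species.
#' @param u1_prob Probability that position 1 is U (exactly; the non-U
#'   branch draws from A/C/G).
#' @param c_bias_positions Positions carrying the cytosine bias in planted
#'   upregulated features (default 2:9).
#' @param c_bias_prob P(C) at biased positions of planted-up features
#'   (exactly; non-C branch draws from A/G/U).
#' @param background_base_probs Base probabilities (A,C,G,U) elsewhere.
#' @param n_per_group Named sample sizes for the two groups.
#' @param group_labels The two group labels, reference level first.
#' @param baseline_log2_mean,baseline_log2_sd Normal parameters of the
#'   per-feature baseline log2 mean.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param de_frac Fraction of features with planted effects.
#' @param lfc Planted |log2 fold change|.
#' @param frac_de_down Fraction of planted features that are downregulated.
#' @param sex_effect_sd SD of per-feature additive sex effects (log2).
#' @param cell_type Cell-type label written to the sample sheet.
#' @param seed Integer seed (mandatory).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_features = 5000L,
                       origin_probs = c(SINE = 0.20, LINE = 0.15, LTR = 0.10,
                                        GENIC = 0.30, OTHER = 0.25),
                       sine_prob_in_down = 0.20,
                       canonical_frac = 0.6,
                       u1_prob = 0.8,
                       c_bias_positions = 2:9,
                       c_bias_prob = 0.25,
                       background_base_probs = c(A = 0.25, C = 0.25,
                                                 G = 0.25, U = 0.25),
                       n_per_group = c(CTRL = 8L, PD = 8L),
                       group_labels = names(n_per_group),
                       baseline_log2_mean = log2(100),
                       baseline_log2_sd = 1,
                       dispersion = 0.1,
                       de_frac = 0,
                       lfc = 1.5,
                       frac_de_down = 0.6,
                       sex_effect_sd = 0,
                       cell_type = "neuron",
                       seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability simplex")
    }
  }
  check_simplex(origin_probs, "origin_probs")
  check_simplex(background_base_probs, "background_base_probs")
  stopifnot(u1_prob >= 0, u1_prob <= 1, c_bias_prob >= 0, c_bias_prob <= 1,
            canonical_frac >= 0, canonical_frac <= 1,
            de_frac >= 0, de_frac <= 1, frac_de_down >= 0, frac_de_down <= 1,
            dispersion >= 0, all(n_per_group >= 2L),
            length(n_per_group) == 2L)
  structure(as.list(environment())[
    c("n_features", "origin_probs", "sine_prob_in_down", "canonical_frac",
      "u1_prob", "c_bias_positions", "c_bias_prob", "background_base_probs",
      "n_per_group", "group_labels", "baseline_log2_mean", "baseline_log2_sd",
      "dispersion", "de_frac", "lfc", "frac_de_down", "sex_effect_sd",
      "cell_type", "seed")],
    class = "sim_params")
}

#' Preset simulation scenarios
#'
#' * `null`: no planted effects; 2000 features, 8 vs 8 samples, dispersion
#'   0.1 — calibration of the type-I error of the DE stage.
#' * `pd_neuron`: a PD-vs-control neuronal comparison at the study's scale:
#'   5000 features, 8 vs 8, 4% planted effects at |log2FC| 1.5 (60% down),
#'   SINE probability 0.5 among planted-down features against a genome-wide
#'   0.2, cytosine probability 0.6 at positions 2-9 of planted-up features,
#'   and a modest sex covariate.
#' * `differentiation`: two stage contrasts (fibroblast vs iPSC, iPSC vs
#'   neuron) with 8% planted effects each and 8% of the second stage's
#'   planted set shared (same direction) with the first — the ground truth
#'   for memory-fraction recovery. Consumed by [simulate_differentiation()].
#'
#' @param name One of `"null"`, `"pd_neuron"`, `"differentiation"`.
#' @param seed Integer seed.
#' @return A `sim_params` object; for `differentiation` it carries an
#'   additional `shared_frac` field.
#' @export
scenario <- function(name = c("null", "pd_neuron", "differentiation"),
                     seed = 1L) {
  name <- match.arg(name)
  switch(name,
    null = sim_params(n_features = 2000L, de_frac = 0, dispersion = 0.1,
                      seed = seed),
    pd_neuron = sim_params(n_features = 5000L, de_frac = 0.04, lfc = 1.5,
                           frac_de_down = 0.6, sine_prob_in_down = 0.5,
                           c_bias_prob = 0.6, sex_effect_sd = 0.2,
                           dispersion = 0.1, seed = seed),
    differentiation = {
      p <- sim_params(n_features = 5000L, de_frac = 0.08, lfc = 1.5,
                      frac_de_down = 0.5, c_bias_prob = 0.6,
                      dispersion = 0.1,
                      n_per_group = c(stageA = 8L, stageB = 8L),
                      cell_type = "mixed", seed = seed)
      p$shared_frac <- 0.08
      p
    })
}

#' Plant ground-truth effects
#'
#' Chooses the planted feature set and directions for one contrast.
#'
#' @param params A `sim_params`.
#' @param forced Optional data frame (`feature_id`, `direction`) of
#'   features whose assignment is fixed up front (used to share planted
#'   sets across differentiation stages).
#' @param exclude Optional feature ids kept null (so the overlap between
#'   two stages' planted sets is exactly the forced share).
#' @return A truth data frame: `feature_id`, `direction` (up/down/null),
#'   `true_log2fc`.
#' @keywords internal
plant_truth <- function(params, forced = NULL, exclude = NULL) {
  ids <- sprintf("pir%05d", seq_len(params$n_features))
  direction <- rep("null", params$n_features)
  names(direction) <- ids
  n_de <- round(params$n_features * params$de_frac)
  if (!is.null(forced)) {
    direction[forced$feature_id] <- forced$direction
    n_de <- n_de - nrow(forced)
  }
  free <- setdiff(names(direction)[direction == "null"], exclude)
  if (n_de > 0L) {
    chosen <- sample(free, n_de)
    n_down <- round(n_de * params$frac_de_down)
    direction[chosen[seq_len(n_down)]] <- "down"
    if (n_de > n_down) direction[chosen[(n_down + 1L):n_de]] <- "up"
  }
  data.frame(
    feature_id = ids,
    direction = unname(direction[ids]),
    true_log2fc = ifelse(direction[ids] == "up", params$lfc,
                         ifelse(direction[ids] == "down", -params$lfc, 0)),
    stringsAsFactors = FALSE
  )
}

# Draw one sequence; planted-up features get the positional C bias.
draw_sequence <- function(len, is_up, params) {
  bases <- c("A", "C", "G", "U")
  s <- character(len)
  s[1] <- if (stats::runif(1) < params$u1_prob) "U"
          else sample(c("A", "C", "G"), 1L)
  for (k in seq_len(len)[-1]) {
    if (is_up && k %in% params$c_bias_positions) {
      s[k] <- if (stats::runif(1) < params$c_bias_prob) "C"
              else sample(c("A", "G", "U"), 1L)
    } else {
      s[k] <- sample(bases, 1L, prob = params$background_base_probs)
    }
  }
  paste(s, collapse = "")
}

#' Simulate a piRNA reference with planted sequence structure
#'
#' Generates `n_features` reference sequences: canonical features draw
#' lengths uniformly on 24-32 nt, piRNA-like features on 18-23 nt; position
#' 1 is U with probability `u1_prob`; planted upregulated features carry
#' the positional cytosine bias; planted downregulated features draw their
#' origin class from the SINE-enriched mixture, all others from the
#' genome-wide mixture. The same seed yields identical output.
#'
#' @param params A `sim_params`.
#' @param truth Optional pre-built truth table from an earlier call (for
#'   multi-stage designs); generated internally when `NULL`.
#' @return List with `reference` (a `pirna_reference`) and `truth` (truth
#'   table extended with `origin_class` and `c_biased`).
#' @export
simulate_reference <- function(params, truth = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  if (is.null(truth)) truth <- plant_truth(params)
  n <- params$n_features
  canonical <- stats::runif(n) < params$canonical_frac
  lens <- ifelse(canonical, sample(24:32, n, replace = TRUE),
                 sample(18:23, n, replace = TRUE))
  is_up <- truth$direction == "up"
  seqs <- vapply(seq_len(n), function(i) {
    draw_sequence(lens[i], is_up[i], params)
  }, character(1))
  down_probs <- params$origin_probs
  not_sine <- setdiff(names(down_probs), "SINE")
  down_probs[not_sine] <- down_probs[not_sine] /
    sum(down_probs[not_sine]) * (1 - params$sine_prob_in_down)
  down_probs["SINE"] <- params$sine_prob_in_down
  origin <- character(n)
  is_down <- truth$direction == "down"
  origin[!is_down] <- sample(names(params$origin_probs), sum(!is_down),
                             replace = TRUE, prob = params$origin_probs)
  if (any(is_down)) {
    origin[is_down] <- sample(names(down_probs), sum(is_down),
                              replace = TRUE, prob = down_probs)
  }
  truth$origin_class <- origin
  truth$c_biased <- is_up
  list(reference = new_reference(truth$feature_id, seqs, origin),
       truth = truth)
}

#' Simulate an NB count matrix with planted group effects
#'
#' Per feature i: baseline mean `mu_i = 2^Normal(m, s)`; the second group's
#' mean is `mu_i * 2^true_log2fc_i`; optional per-feature sex effects shift
#' log2 means; per-sample library-size multipliers are log-uniform on
#' \[0.5, 2\]; counts are NB(mu, alpha) (Poisson in the alpha -> 0 limit).
#'
#' @param ref A `pirna_reference` (from [simulate_reference()]).
#' @param params A `sim_params`.
#' @param truth Truth table aligned to `ref` (from [simulate_reference()]).
#' @param seed_offset Added to `params$seed` so reference and counts use
#'   distinct streams (default 1).
#' @return List with `counts` (integer matrix), `sample_sheet`, `truth` and
#'   `size_multipliers` (the true per-sample library-size factors, for
#'   ground-truth checks).
#' @export
simulate_counts <- function(ref, params, truth, seed_offset = 1L) {
  stopifnot(inherits(ref, "pirna_reference"), inherits(params, "sim_params"))
  set.seed(params$seed + seed_offset)
  n <- nrow(ref)
  stopifnot(nrow(truth) == n)
  groups <- rep(params$group_labels, params$n_per_group)
  ns <- length(groups)
  sample_ids <- sprintf("s%02d", seq_len(ns))
  size_mult <- 2^stats::runif(ns, -1, 1)
  sex <- unlist(lapply(params$n_per_group, function(m) {
    rep_len(c("F", "M"), m)
  }), use.names = FALSE)
  passage <- sample(5:30, ns, replace = TRUE)
  log2mu <- stats::rnorm(n, params$baseline_log2_mean, params$baseline_log2_sd)
  beta_sex <- if (params$sex_effect_sd > 0) {
    stats::rnorm(n, 0, params$sex_effect_sd)
  } else numeric(n)
  is_g2 <- as.integer(groups == params$group_labels[2])
  is_m <- as.integer(sex == "M")
  counts <- matrix(0L, n, ns, dimnames = list(ref$id, sample_ids))
  for (j in seq_len(ns)) {
    mu_j <- 2^(log2mu + truth$true_log2fc * is_g2[j] + beta_sex * is_m[j]) *
      size_mult[j]
    counts[, j] <- as.integer(if (params$dispersion < 1e-12) {
      stats::rpois(n, mu_j)
    } else {
      stats::rnbinom(n, size = 1 / params$dispersion, mu = mu_j)
    })
  }
  sheet <- data.frame(
    sample_id = sample_ids,
    group = groups,
    cell_type = params$cell_type,
    sex = sex,
    passage = passage,
    patient_id = sprintf("P%02d", seq_len(ns)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, sample_sheet = sheet, truth = truth,
       size_multipliers = stats::setNames(size_mult, sample_ids))
}

#' Simulate a two-stage differentiation design with shared planted effects
#'
#' Builds one reference and two contrasts (stage 1: fibroblast vs iPSC;
#' stage 2: iPSC vs neuron) whose planted DE sets share a fixed fraction of
#' features with matching directions — the generator truth against which
#' [memory_fraction()] recovery is tested.
#'
#' @param params A `sim_params` from `scenario("differentiation")` (must
#'   carry `shared_frac`).
#' @return List with `reference`, `truth1`, `truth2`, `stage1`, `stage2`
#'   (each a `simulate_counts()` result) and `shared_ids`.
#' @export
simulate_differentiation <- function(params) {
  stopifnot(inherits(params, "sim_params"), !is.null(params$shared_frac))
  set.seed(params$seed)
  truth2 <- plant_truth(params)
  planted2 <- truth2[truth2$direction != "null", ]
  n_shared <- round(nrow(planted2) * params$shared_frac)
  shared <- planted2[sample(nrow(planted2), n_shared), c("feature_id",
                                                         "direction")]
  truth1 <- plant_truth(params, forced = shared,
                        exclude = setdiff(planted2$feature_id,
                                          shared$feature_id))
  simref <- simulate_reference(params, truth = truth2)
  stage1 <- simulate_counts(simref$reference, params, truth1,
                            seed_offset = 1L)
  stage1$sample_sheet$cell_type <- rep(c("fibroblast", "iPSC"),
                                       params$n_per_group)
  stage2 <- simulate_counts(simref$reference, params, truth2,
                            seed_offset = 2L)
  stage2$sample_sheet$cell_type <- rep(c("iPSC", "neuron"),
                                       params$n_per_group)
  list(reference = simref$reference, truth1 = truth1,
       truth2 = simref$truth, stage1 = stage1, stage2 = stage2,
       shared_ids = shared$feature_id)
}

#' Simulate sequencing reads for one sample
#'
#' Emits each reference sequence as many times as its count, substituting
#' each base independently with probability `error_rate` (substitutions
#' only). Reads are returned in the DNA alphabet (U written as T), as a
#' sequencer would emit them.
#'
#' @param ref A `pirna_reference`.
#' @param counts_column Non-negative integer count per reference feature.
#' @param error_rate Per-base substitution probability in \[0, 0.05\].
#' @param seed Integer seed.
#' @return Data frame with `read_id`, `sequence` (DNA alphabet) and
#'   `quality` (constant "I"); zero rows when all counts are zero.
#' @export
simulate_reads <- function(ref, counts_column, error_rate = 0, seed = 1L) {
  stopifnot(inherits(ref, "pirna_reference"),
            length(counts_column) == nrow(ref),
            error_rate >= 0, error_rate <= 0.05)
  set.seed(seed)
  counts_column <- as.integer(counts_column)
  stopifnot(all(counts_column >= 0))
  idx <- rep(seq_len(nrow(ref)), counts_column)
  if (length(idx) == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0)))
  }
  seqs <- ref$sequence[idx]
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "U")
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      hit <- which(stats::runif(n) < error_rate)
      if (length(hit) > 0L) {
        ch <- strsplit(s, "")[[1]]
        for (k in hit) ch[k] <- sample(setdiff(bases, ch[k]), 1L)
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(
    read_id = sprintf("read%07d", seq_along(idx)),
    sequence = chartr("U", "T", seqs),
    quality = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE
  )
}

#' Write simulated reads to FASTQ
#'
#' @param reads Data frame from [simulate_reads()].
#' @param path Output FASTQ path (gzip when the name ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read vector
#'
#' @param path FASTQ path (plain or gzip).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  lines[seq(2L, length(lines), by = 4L)]
}

#' Write a count matrix to TSV
#'
#' First column `feature_id`, remaining columns the sample ids.
#'
#' @param counts Count matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV with a `feature_id` first column.
#' @return Integer matrix with dimnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") {
    stop("count table must have a 'feature_id' first column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write / read a sample sheet
#'
#' @param sheet Sample sheet data frame.
#' @param path TSV path.
#' @return `path` (write) or the sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("sample sheet must have a 'sample_id' column")
  }
  df
}

#' Write a truth table to TSV
#'
#' @param truth Truth data frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
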