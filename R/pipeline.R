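# Orchestration: flat key-value run configuration, the end-to-end signature
# workflow (DE -> call -> enrichment -> composition -> clustering, plus
# optional memory and cross-cohort overlap), and TSV report writing. All
# result files are plain TSV with '#'-prefixed header comments so runs are
# diff-able; identical config + seed reproduces identical bytes.

config_defaults <- function() {
  list(
    reference = NULL, annotation = NULL, counts = NULL, sample_sheet = NULL,
    snorna = NULL, baseline_calls = NULL, compare_calls = NULL,
    contrast = "group", covariates = "",
    lfc_min = 0.6, padj_max = 0.1,
    top_n_variable = 2000L, top_n_de = 100L, top_n_abundant = 20L,
    mode = "all", direction_matched_memory = FALSE,
    seed = 1L, out_dir = NULL
  )
}

#' Validate a flat key-value run configuration
#'
#' Config files are plain text, one `key = value` per line, `#` comments
#' allowed. Unknown keys are rejected; defaults are applied for absent keys
#' (deregulation thresholds default to |log2FC| >= 0.6 and padj < 0.1).
#'
#' @param path Path to the config file, or a named list of settings.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                    lines))
    bad <- vapply(kv, length, integer(1)) != 3L
    if (any(bad)) stop("unparseable config line(s): ",
                       paste(lines[bad], collapse = "; "))
    stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  num_keys <- c("lfc_min", "padj_max", "seed",
                "top_n_variable", "top_n_de", "top_n_abundant")
  for (k in num_keys) {
    v <- suppressWarnings(as.numeric(cfg[[k]]))
    if (is.na(v)) stop("config key '", k, "' must be numeric")
    cfg[[k]] <- v
  }
  if (cfg$lfc_min <= 0 || cfg$padj_max <= 0) {
    stop("thresholds lfc_min and padj_max must be positive")
  }
  cfg$direction_matched_memory <-
    tolower(as.character(cfg$direction_matched_memory)) %in%
    c("true", "1", "yes")
  if (!cfg$mode %in% c("all", "unique", "fractional")) {
    stop("mode must be one of all, unique, fractional")
  }
  for (k in c("counts", "sample_sheet", "reference", "annotation",
              "out_dir")) {
    if (is.null(cfg[[k]])) stop("mandatory config key missing: ", k)
  }
  for (k in c("counts", "sample_sheet", "reference", "annotation",
              "snorna", "baseline_calls", "compare_calls")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("config path for '", k, "' does not exist: ", cfg[[k]])
    }
  }
  structure(cfg, class = "run_config")
}

write_tsv_report <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0L) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "call") %in% names(df)))
  structure(list(up = df$feature_id[df$call == "up"],
                 down = df$feature_id[df$call == "down"]),
            class = "pirsig_call")
}

#' Run the full piRNA signature workflow
#'
#' Executes reference loading, differential expression, the deregulation
#' call, element-of-origin enrichment (down- and up-set against the
#' genome-wide null), positional cytosine composition, TOP-N hierarchical
#' clustering, and — when baseline/comparison calls are configured — the
#' memory fraction and direction-stratified overlap. Writes
#' `de_results.tsv`, `enrichment.tsv`, `composition.tsv`, `clusters.tsv`,
#' optional `memory.tsv` / `overlap.tsv`, a machine-readable
#' `manifest.tsv` and a human-readable `summary.txt` into `out_dir`. Any
#' stage error aborts the run, removes partial outputs and names the stage.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list
#'   accepted by it).
#' @return Invisible list with the in-memory results (`de`, `call`,
#'   `enrichment`, `composition`, `cluster`, `memory`, `overlap`, `files`).
#' @export
run_signature <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  result <- tryCatch({
    stage <- "reference"
    ref <- load_reference(config$reference, config$annotation)
    null_props <- origin_proportions(ref)

    stage <- "input"
    counts <- read_counts(config$counts)
    sheet <- read_sample_sheet(config$sample_sheet)
    covars <- trimws(strsplit(config$covariates, ",")[[1]])
    covars <- covars[nzchar(covars)]
    design <- design_spec(config$contrast, covars)

    stage <- "differential_expression"
    de <- nb_wald(counts, sheet, design)
    call <- call_deregulated(de, config$lfc_min, config$padj_max)
    de_out <- de
    de_out$call <- ifelse(de$status == "untested", "untested",
                   ifelse(de$feature_id %in% call$up, "up",
                   ifelse(de$feature_id %in% call$down, "down", "ns")))
    hdr <- c(paste0("contrast=", config$contrast,
                    " levels=", paste(attr(de, "contrast_levels"),
                                      collapse = "_vs_")),
             paste0("lfc_min=", config$lfc_min,
                    " padj_max=", config$padj_max),
             paste0("seed=", config$seed))
    written <- c(written, write_tsv_report(
      de_out, file.path(config$out_dir, "de_results.tsv"), hdr))

    stage <- "enrichment"
    enr <- NULL
    for (set_name in c("down", "up")) {
      ids <- call[[set_name]]
      if (length(ids) == 0L) next
      e <- origin_enrichment(ids, ref, null_props)
      e <- cbind(set = set_name, e)
      enr <- rbind(enr, e)
    }
    if (is.null(enr)) {
      enr <- data.frame(set = character(0), origin_class = character(0),
                        k = integer(0), n = integer(0), p0 = numeric(0),
                        expected = numeric(0), chi2 = numeric(0),
                        p = numeric(0), direction = character(0),
                        untestable = logical(0))
    }
    written <- c(written, write_tsv_report(
      enr, file.path(config$out_dir, "enrichment.tsv"),
      "one-vs-rest chi-square goodness of fit vs genome-wide proportions"))

    stage <- "composition"
    comp <- composition_bias(call$up, call$down, ref$id, ref)
    written <- c(written, write_tsv_report(
      comp, file.path(config$out_dir, "composition.tsv"),
      "cytosine fraction by position: called up / called down / all piRNAs"))

    stage <- "clustering"
    sf <- attr(de, "size_factors")
    logm <- log_transform(counts, sf)
    top_ids <- top_de(de, config$top_n_de)
    clus <- NULL
    if (length(top_ids) >= 2L) {
      clus <- hcluster(logm, top_ids, sheet, group_col = config$contrast)
      cl_df <- data.frame(sample_id = names(clus$clusters),
                          cluster = unname(clus$clusters),
                          group = as.character(clus$groups))
      written <- c(written, write_tsv_report(
        cl_df, file.path(config$out_dir, "clusters.tsv"),
        c(paste0("top_n=", length(top_ids), " distance=1-pearson",
                 " linkage=average"),
          paste0("adjusted_rand_index=", format(clus$ari, digits = 10)))))
    }

    stage <- "memory"
    memory <- NULL
    if (!is.null(config$baseline_calls)) {
      baseline <- read_calls_tsv(config$baseline_calls)
      memory <- memory_fraction(call, baseline,
                                config$direction_matched_memory)
      written <- c(written, write_tsv_report(
        data.frame(stage = memory$stage, n_memory = memory$n_memory,
                   n_total_deregulated = memory$n_total_deregulated,
                   fraction = memory$fraction),
        file.path(config$out_dir, "memory.tsv"),
        paste0("direction_matched=", config$direction_matched_memory)))
    }

    stage <- "overlap"
    overlap <- NULL
    if (!is.null(config$compare_calls)) {
      other <- read_calls_tsv(config$compare_calls)
      overlap <- direction_overlap(call, other)
      written <- c(written, write_tsv_report(
        data.frame(n_up_shared = overlap$n_up_shared,
                   n_down_shared = overlap$n_down_shared,
                   n_shared = overlap$n_shared,
                   a_up = overlap$sizes["a_up"],
                   a_down = overlap$sizes["a_down"],
                   b_up = overlap$sizes["b_up"],
                   b_down = overlap$sizes["b_down"]),
        file.path(config$out_dir, "overlap.tsv"),
        "direction-stratified overlap with comparison cohort"))
    }

    stage <- "report"
    # inputs are recorded as name + content checksum so a manifest pins the
    # run without depending on where the files happen to live
    input_id <- function(p) {
      paste0(basename(p), ":md5=", unname(tools::md5sum(p)))
    }
    manifest <- data.frame(
      key = c("package_version", "seed", "contrast", "covariates",
              "lfc_min", "padj_max", "top_n_de", "mode",
              "counts", "sample_sheet", "reference", "annotation"),
      value = c(as.character(utils::packageVersion("pirsig")),
                config$seed, config$contrast, config$covariates,
                config$lfc_min, config$padj_max, config$top_n_de,
                config$mode, input_id(config$counts),
                input_id(config$sample_sheet), input_id(config$reference),
                input_id(config$annotation))
    )
    written <- c(written, write_tsv_report(
      manifest, file.path(config$out_dir, "manifest.tsv")))

    summary_lines <- c(
      sprintf("features tested: %d / %d", sum(de$status == "tested"),
              nrow(de)),
      sprintf("called up: %d, down: %d (|log2FC| >= %s, padj < %s)",
              length(call$up), length(call$down), config$lfc_min,
              config$padj_max),
      if (!is.null(clus)) sprintf(
        "TOP%d clustering adjusted Rand index vs %s: %.3f",
        length(top_ids), config$contrast, clus$ari),
      if (!is.null(memory)) sprintf(
        "memory fraction: %d/%d = %.3f", memory$n_memory,
        memory$n_total_deregulated, memory$fraction),
      if (!is.null(overlap)) sprintf(
        "shared deregulated with comparison cohort: %d", overlap$n_shared)
    )
    sfile <- file.path(config$out_dir, "summary.txt")
    writeLines(summary_lines, sfile)
    written <- c(written, sfile)

    list(de = de, call = call, enrichment = enr, composition = comp,
         cluster = clus, memory = memory, overlap = overlap,
         files = written)
  }, error = function(e) {
    unlink(written)
    stop("signature run failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Simulate a scenario and write its inputs to disk
#'
#' Convenience wrapper used by the command-line entry point: generates the
#' reference, count matrix, sample sheet and truth table for a named
#' scenario and writes them as FASTA/TSV under `out_dir`.
#'
#' @param scenario_name One of the [scenario()] presets.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisible named list of the written file paths.
#' @export
simulate_to_dir <- function(scenario_name, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- scenario(scenario_name, seed = seed)
  simref <- simulate_reference(params)
  sim <- simulate_counts(simref$reference, params, simref$truth)
  paths <- list(
    reference = file.path(out_dir, "reference.fasta"),
    annotation = file.path(out_dir, "annotation.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_reference_fasta(simref$reference, paths$reference)
  write_annotation(simref$reference, paths$annotation)
  write_counts(sim$counts, paths$counts)
  write_sample_sheet(sim$sample_sheet, paths$sample_sheet)
  write_truth(sim$truth, paths$truth)
  invisible(paths)
}
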