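## End-to-end orchestration: simulate/load -> pileup -> call -> annotate ->
## summarize -> compare, with a machine-readable JSON run report.

FILTER_DEFAULTS <- list(min_base_quality = 25L, min_depth = 10L,
                        min_alt_support = 3L, min_freq = 0.1, alpha = 0.05,
                        error_rate = 0.01, end_trim = 6L,
                        exclude_multimapped = TRUE, max_multimap_mapq = 0L)

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a list. Schema:
#' \preformatted{
#' seed: 1
#' outdir: path
#' baseline: naive
#' filter: {min_base_quality: 25, min_depth: 10, ...}   # optional
#' conditions:
#'   naive:
#'     sim: {mean_depth: 50, ...}        # sim_config() overrides, OR
#'   acute:
#'     paths: {sam: ..., reference: ..., annotation: ..., snp_vcf: ...}
#' }
#' Exactly one of `sim` / `paths` per condition. Missing filter fields are
#' filled with the stringent defaults (base quality 25, depth 10, support 3,
#' frequency 0.1, alpha 0.05). All violations are collected and reported
#' together, each naming the offending field.
#'
#' @param config YAML path or nested list.
#' @return normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    check_that(file.exists(config), paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  check_that(is.list(config), "config must be a list or a YAML path")
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$outdir)) note("outdir: missing")
  if (is.null(config$conditions) || !length(config$conditions)) {
    note("conditions: at least one condition required")
  }
  if (is.null(config$baseline)) {
    note("baseline: missing")
  } else if (!is.null(config$conditions) &&
             !config$baseline %in% names(config$conditions)) {
    note(sprintf("baseline: '%s' not among conditions", config$baseline))
  }

  filt <- utils::modifyList(FILTER_DEFAULTS,
                            if (is.null(config$filter)) list()
                            else config$filter)
  fc <- tryCatch(do.call(filter_config, filt), error = function(e) {
    note(paste0("filter: ", conditionMessage(e)))
    NULL
  })
  config$filter <- fc

  for (nm in names(config$conditions)) {
    cond <- config$conditions[[nm]]
    has_sim <- !is.null(cond$sim)
    has_paths <- !is.null(cond$paths)
    if (has_sim == has_paths) {
      note(sprintf("conditions.%s: exactly one of sim/paths required", nm))
      next
    }
    if (has_sim) {
      sc <- tryCatch(do.call(sim_config, cond$sim), error = function(e) {
        note(sprintf("conditions.%s.sim: %s", nm, conditionMessage(e)))
        NULL
      })
      config$conditions[[nm]]$sim <- sc
    } else {
      for (p in c("sam", "reference", "annotation")) {
        if (is.null(cond$paths[[p]])) {
          note(sprintf("conditions.%s.paths.%s: missing", nm, p))
        } else if (!file.exists(cond$paths[[p]])) {
          note(sprintf("conditions.%s.paths.%s: file not found (%s)",
                       nm, p, cond$paths[[p]]))
        }
      }
    }
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  class(config) <- "pipeline_config"
  config
}

#' Run the editome pipeline end to end
#'
#' For each condition, either simulates a dataset (reference FASTA, BED and
#' GFF3 annotation, coordinate-sorted SAM, VCF SNP mask, ground-truth TSV)
#' or loads the configured files; builds the quality-filtered pileup; calls
#' RDD sites; annotates passing calls; and summarizes the editome. Every
#' non-baseline condition is then compared against the baseline. Outputs are
#' written under `outdir/<condition>/`, and a consolidated JSON run report
#' under `outdir/report.json`. Reruns with an identical configuration
#' reproduce identical outputs.
#'
#' Simulated conditions derive their generator seed deterministically as
#' `seed + 1000 * condition_index + sim_seed`, so distinct conditions get
#' distinct genomes while a rerun reproduces them exactly.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return the run report, invisibly (also written as JSON): per-condition
#'   stage record counts with telescoping filter attrition, editome
#'   summaries, baseline comparisons, filter settings and a config hash.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  run_condition <- function(nm, idx) {
    cdir <- file.path(outdir, nm)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    cond <- config$conditions[[nm]]
    if (!is.null(cond$sim)) {
      sc <- cond$sim
      sc$seed <- as.integer(config$seed + 1000L * idx + sc$seed)
      genome <- simulate_reference(sc)
      planted <- plant_sites(sc, genome$reference, genome$features)
      reads <- simulate_alignments(sc, genome$reference, planted$truth,
                                   planted$snps)
      ref_path <- file.path(cdir, "reference.fasta")
      Biostrings::writeXStringSet(genome$reference, ref_path)
      write_features(genome$features, file.path(cdir, "features.bed"))
      write_features(genome$features, file.path(cdir, "features.gff3"))
      sam_path <- file.path(cdir, "reads.sam")
      write_sam(reads, sam_path)
      vcf_path <- file.path(cdir, "snp_mask.vcf")
      write_vcf(planted$snps, vcf_path, genome_length = sc$genome_length)
      write_truth_table(planted$truth, file.path(cdir, "truth.tsv"))
      list(reference = genome$reference, features = genome$features,
           sam = sam_path, snp_mask = planted$snps,
           n_reads = nrow(reads), truth = planted$truth)
    } else {
      p <- cond$paths
      mask <- if (!is.null(p$snp_vcf)) read_snp_mask(p$snp_vcf) else NULL
      ref <- as_reference(p$reference)
      list(reference = ref, features = read_features(p$annotation),
           sam = p$sam, snp_mask = mask, n_reads = NA_integer_,
           truth = NULL)
    }
  }

  summaries <- list()
  stages <- list()
  cond_names <- names(config$conditions)
  for (i in seq_along(cond_names)) {
    nm <- cond_names[i]
    inputs <- tryCatch(run_condition(nm, i), error = function(e) {
      stop(sprintf("pipeline stage 'inputs' failed for condition '%s': %s",
                   nm, conditionMessage(e)), call. = FALSE)
    })
    cdir <- file.path(outdir, nm)
    pu <- tryCatch(
      build_pileup(inputs$sam, inputs$reference, config$filter),
      error = function(e) {
        stop(sprintf("pipeline stage 'pileup' failed for condition '%s': %s",
                     nm, conditionMessage(e)), call. = FALSE)
      })
    calls <- call_rdd_sites(pu, inputs$snp_mask, config$filter)
    write_rdd_calls(calls, tsv_path = file.path(cdir, "calls.tsv"),
                    vcf_path = file.path(cdir, "calls.vcf"))
    edits <- annotate_edits(calls[calls$passed, , drop = FALSE],
                            inputs$features)
    utils::write.table(edits, file.path(cdir, "annotated_edits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries[[nm]] <- suppressWarnings(summarize_editome(edits, nm))
    att <- call_attrition(calls)
    stages[[nm]] <- list(
      n_reads = inputs$n_reads,
      n_pileup_sites = nrow(pu),
      n_candidates = att$n_candidates,
      removed = as.list(att$removed),
      n_passed = att$n_passed,
      n_annotated = nrow(edits))
  }

  comparisons <- list()
  for (nm in setdiff(cond_names, config$baseline)) {
    comparisons[[nm]] <- compare_editomes(summaries[[config$baseline]],
                                          summaries[[nm]])
  }

  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  report <- list(
    package_version = as.character(utils::packageVersion("editomeR")),
    config_hash = unname(tools::md5sum(cfg_file)),
    baseline = config$baseline,
    filter = unclass(config$filter),
    stages = stages,
    summaries = lapply(summaries, unclass),
    comparisons = lapply(comparisons, unclass))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

## strip S3 classes recursively so jsonlite serializes plain lists
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}
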