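#' Load a run manifest from YAML
#'
#' The manifest names the per-replicate SAM/BAM inputs, the reference
#' FASTA, the GTF annotation, the control-ID prefix, optional QC/filter
#' overrides, an output directory and a seed.
#'
#' @param path YAML manifest path.
#' @return The manifest list.
#' @export
load_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$replicates) || length(m$replicates) < 1)
    stop("manifest must list at least one replicate")
  if (is.null(names(m$replicates)) || anyDuplicated(names(m$replicates)))
    stop("replicate names must be present and unique")
  for (f in unlist(m$replicates)) {
    if (is.character(f) && !file.exists(f)) stop("input does not exist: ", f)
  }
  m
}

#' Run the full post-alignment pipeline
#'
#' Per replicate: read QC, UMI grouping/deduplication with discordance
#' statistics on control-mapped reads, spike-in conversion-rate
#' estimation, methylation calling and the multi-level filter cascade;
#' then replicate concordance across replicates and annotation of the
#' high-confidence set. Deterministic given identical inputs.
#'
#' @param manifest A list (or YAML path for [load_manifest()]) with
#'   elements `replicates` (named list of SAM/BAM paths or read tables),
#'   `reference` (FASTA path or `bs_reference`), `annotation` (GTF path
#'   or table), `control_prefix` (default `"CTRL"`), optional `qc` and
#'   `filters` override lists, optional `out_dir`, optional `seed`.
#' @return A `pipeline_run` list: `replicates` (per-replicate stage
#'   results), `high_confidence` (annotated site table), `summary`
#'   (machine-readable list, also written as JSON when `out_dir` is
#'   set).
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (!is.null(manifest$seed)) set.seed(as.integer(manifest$seed))
  reference <- manifest$reference
  if (is.character(reference)) {
    seqs <- Biostrings::readDNAStringSet(reference)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    prefix <- manifest$control_prefix %||% "CTRL"
    reference <- structure(list(sequences = seqs, annotation = NULL,
                                control_ids = names(seqs)[startsWith(names(seqs),
                                                                     prefix)]),
                           class = "bs_reference")
  }
  annotation <- manifest$annotation
  if (is.character(annotation)) annotation <- read_gtf(annotation)
  if (is.null(annotation) && inherits(reference, "bs_reference"))
    annotation <- reference$annotation
  control_ids <- reference$control_ids
  qc_cfg <- do.call(qc_config, manifest$qc %||% list())
  fl_args <- manifest$filters %||% list()
  filter_cfg <- do.call(filter_config, fl_args)

  rep_names <- names(manifest$replicates)
  reps <- list()
  for (rn in rep_names) {
    input <- manifest$replicates[[rn]]
    reads <- if (is.character(input)) read_sam(input) else validate_reads(input)
    n_in <- nrow(reads)
    qc <- qc_pipeline(reads, qc_cfg)
    groups <- umi_group(qc$reads)
    dd <- umi_dedup(groups)
    disc <- umi_discordance(groups, refs = if (length(control_ids)) control_ids
                            else NULL)
    conv <- conversion_rate(dd$reads, reference, control_ids)
    err <- if (is.na(conv$rate)) 1 - 0.999 else
      min(max(1 - conv$rate, 1e-6), 0.5)
    cascade <- filter_cascade(dd$reads, reference, annotation, filter_cfg,
                              min_base_q = qc_cfg$min_site_base_q,
                              error_rate = err)
    reps[[rn]] <- list(n_reads_in = n_in, qc = qc, dedup = dd,
                       discordance = disc, conversion = conv,
                       error_rate = err, cascade = cascade,
                       passed = cascade$passed,
                       post_cutoff = cascade$post_cutoff)
  }

  if (length(reps) >= 2) {
    hc <- replicate_concordance(reps, filter_cfg)
  } else {
    warning("single replicate: high-confidence set is empty by definition")
    hc <- data.table::data.table(ref = character(), pos = integer())
  }
  if (nrow(hc) > 0 && !is.null(annotation)) hc <- annotate_sites(hc, annotation)

  summary <- list(
    replicates = lapply(reps, function(r) list(
      n_reads_in = r$n_reads_in,
      n_reads_qc = nrow(r$qc$reads),
      duplication_rate = r$dedup$duplication_rate,
      discordance_ratio = r$discordance$discordance_ratio,
      conversion_rate = r$conversion$rate,
      error_rate = r$error_rate,
      chosen_c_cutoff = r$cascade$cutoff$chosen_k,
      stage_counts = as.list(setNames(r$cascade$attrition$n_sites,
                                      r$cascade$attrition$stage)))),
    n_high_confidence = nrow(hc),
    thresholds = list(qc = unclass(qc_cfg),
                      filters = unclass(filter_cfg[
                        setdiff(names(filter_cfg), "resistant_regions")])))

  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rn in rep_names) {
      data.table::fwrite(reps[[rn]]$passed,
                         file.path(manifest$out_dir,
                                   paste0(rn, ".passed_sites.tsv")), sep = "\t")
      data.table::fwrite(reps[[rn]]$cascade$attrition,
                         file.path(manifest$out_dir,
                                   paste0(rn, ".attrition.tsv")), sep = "\t")
    }
    data.table::fwrite(hc, file.path(manifest$out_dir,
                                     "high_confidence_sites.tsv"), sep = "\t")
    jsonlite::write_json(summary,
                         file.path(manifest$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(replicates = reps, high_confidence = hc, summary = summary),
            class = "pipeline_run")
}

#' Simulate replicates and run the pipeline end to end
#'
#' Convenience wrapper for validation runs: simulates `n_replicates`
#' datasets sharing one reference and planted truth (replicate seeds are
#' offset from `config$seed`), runs [run_pipeline()] on them, and
#' attaches recovery statistics against the truth: sensitivity over
#' planted sites, false sites on control transcripts, false sites at
#' non-planted positions, and per-site level error.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of simulated replicates.
#' @param filters,qc Optional override lists for [filter_config()] /
#'   [qc_config()].
#' @return The `pipeline_run` with an extra `recovery` element.
#' @export
run_simulated_pipeline <- function(config = sim_config(), n_replicates = 2,
                                   filters = list(), qc = list()) {
  reference <- generate_reference(config)
  truth <- plant_methylation(reference, config)
  replicates <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + 1000L * r
    sim <- simulate_reads(reference, truth, cfg_r)
    replicates[[paste0("rep", r)]] <- sim$reads
  }
  run <- run_pipeline(list(replicates = replicates, reference = reference,
                           annotation = reference$annotation,
                           qc = qc, filters = filters,
                           seed = config$seed))
  hc <- run$high_confidence
  planted <- truth$sites
  hc_key <- if (nrow(hc) > 0) paste(hc$ref, hc$pos) else character(0)
  planted_key <- paste(planted$ref, planted$pos)
  recovered <- planted_key %in% hc_key
  on_controls <- if (nrow(hc) > 0) sum(hc$ref %in% reference$control_ids) else 0L
  false_pos <- sum(!(hc_key %in% planted_key))
  level_err <- NA_real_
  if (any(recovered) && nrow(hc) > 0) {
    m <- merge(data.table::as.data.table(hc)[, .(ref, pos, level)],
               planted[, .(ref, pos, true_level = level)],
               by = c("ref", "pos"))
    level_err <- m[, abs(level - true_level)]
  }
  run$recovery <- list(sensitivity = mean(recovered),
                       n_planted = nrow(planted),
                       n_recovered = sum(recovered),
                       false_on_controls = on_controls,
                       false_non_planted = false_pos,
                       level_abs_error = level_err)
  run$truth <- truth
  run$reference <- reference
  run
}
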