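#' Generate a synthetic transcriptome with spike-in controls
#'
#' Draws random transcript sequences (iid bases at the configured GC
#' content) plus unmethylated control transcripts whose IDs carry
#' `control_prefix`, mimicking ERCC-style external spike-ins. Each
#' non-control transcript gets a minimal gene model with 5'UTR, CDS and
#' 3'UTR sub-features; controls are annotated as single-exon noncoding.
#'
#' @param config A [sim_config()] object.
#' @return A `bs_reference` list with elements `sequences`
#'   (a [Biostrings::DNAStringSet]), `annotation` (a GTF-shaped
#'   `data.table` with 1-based closed intervals) and `control_ids`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  n_ctrl <- config$n_control_transcripts
  ids <- c(sprintf("TX%04d", seq_len(n - n_ctrl)),
           if (n_ctrl > 0) sprintf("%s%04d", config$control_prefix, seq_len(n_ctrl)))
  lens <- sample_int_range(config$length_range[1], config$length_range[2], n)
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ids
  control_ids <- ids[startsWith(ids, config$control_prefix) &
                       seq_along(ids) > (n - n_ctrl)]

  ann <- data.table::rbindlist(lapply(seq_len(n), function(k) {
    id <- ids[k]; L <- lens[k]
    is_ctrl <- id %in% control_ids
    gid <- sub("^TX", "GENE", id)
    rows <- list(data.table::data.table(
      seqname = id, source = "rnabs_sim", feature = "exon",
      start = 1L, end = L, strand = "+", gene_id = gid, transcript_id = id))
    if (!is_ctrl && L >= 120) {
      u5 <- max(30L, as.integer(round(0.15 * L)))
      u3 <- max(30L, as.integer(round(0.25 * L)))
      cds_start <- u5 + 1L
      cds_end <- L - u3
      rows <- c(rows, list(
        data.table::data.table(seqname = id, source = "rnabs_sim",
                               feature = "five_prime_utr", start = 1L, end = u5,
                               strand = "+", gene_id = gid, transcript_id = id),
        data.table::data.table(seqname = id, source = "rnabs_sim",
                               feature = "CDS", start = cds_start, end = cds_end,
                               strand = "+", gene_id = gid, transcript_id = id),
        data.table::data.table(seqname = id, source = "rnabs_sim",
                               feature = "three_prime_utr", start = cds_end + 1L,
                               end = L, strand = "+", gene_id = gid,
                               transcript_id = id)))
    }
    data.table::rbindlist(rows)
  }))

  structure(list(sequences = sequences, annotation = ann,
                 control_ids = control_ids),
            class = "bs_reference")
}

#' Plant methylated cytosines on a synthetic reference
#'
#' Chooses `n_true_sites` distinct reference-C positions on non-control
#' transcripts and assigns each a true methylation level drawn from
#' `config$level_distribution`. Control (spike-in) transcripts never carry
#' planted sites, so any candidate signal on them is artifact by
#' construction. For clean parameter recovery, sites are preferentially
#' placed in the transcript interior (at least one maximal fragment length
#' from either end, where the fragment process reaches its nominal
#' coverage) and at least one maximal fragment length apart (so a fragment
#' supports at most one site); when the reference is too small for those
#' constraints they are relaxed stepwise (half spacing/margin, then none)
#' before giving up.
#'
#' @param reference A `bs_reference` from [generate_reference()].
#' @param config A [sim_config()] object.
#' @return A `bs_truth` list with `sites`
#'   (`data.table(ref, pos, level)`, 0-based positions) and `read_truth`
#'   (`NULL` until [simulate_reads()] fills it).
#' @export
plant_methylation <- function(reference, config) {
  stopifnot(inherits(reference, "bs_reference"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cpos <- reference_c_positions(reference$sequences)
  cpos <- cpos[!ref %in% reference$control_ids]
  if (config$n_true_sites > nrow(cpos))
    stop("insufficient C positions on non-control transcripts (",
         nrow(cpos), ") for n_true_sites = ", config$n_true_sites)
  if (config$n_true_sites == 0) {
    sites <- data.table::data.table(ref = character(), pos = integer(),
                                    level = numeric())
    return(structure(list(sites = sites, read_truth = NULL),
                     class = "bs_truth"))
  }
  lens <- setNames(Biostrings::width(reference$sequences),
                   names(reference$sequences))
  frag_max <- config$fragment_length[2]
  picked <- NULL
  for (scale in c(1, 0.5, 0)) {
    margin <- as.integer(frag_max * scale)
    spacing <- as.integer(frag_max * scale)
    pool <- cpos[pos >= margin & pos < lens[ref] - margin]
    if (nrow(pool) < config$n_true_sites) next
    ord <- sample.int(nrow(pool))
    sel <- integer(0)
    for (idx in ord) {
      cand <- pool[idx]
      same <- pool[sel][ref == cand$ref]
      if (nrow(same) == 0 || all(abs(same$pos - cand$pos) >= spacing))
        sel <- c(sel, idx)
      if (length(sel) == config$n_true_sites) break
    }
    if (length(sel) == config$n_true_sites) {
      picked <- pool[sort(sel)]
      break
    }
  }
  if (is.null(picked))
    stop("could not place ", config$n_true_sites,
         " sites even without spacing constraints; ",
         "reference has too few usable C positions")
  sites <- picked
  sites[, level := config$level_distribution(.N)]
  if (any(sites$level < 0 | sites$level > 1))
    stop("level_distribution produced values outside [0,1]")
  data.table::setkey(sites, ref, pos)
  structure(list(sites = sites, read_truth = NULL), class = "bs_truth")
}
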