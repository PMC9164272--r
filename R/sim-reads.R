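#' Simulate UMI-tagged bisulfite reads from a planted truth
#'
#' Draws template molecules (fragments) from each transcript at roughly
#' `mean_coverage` unique-molecule depth, applies per-cytosine bisulfite
#' conversion (methylated Cs retained with probability equal to the true
#' level; unmethylated Cs converted with probability `conversion_rate`;
#' resistant molecules skip conversion entirely), amplifies templates over
#' discrete PCR rounds whose per-molecule efficiency is penalised by the
#' molecule's unconverted-C fraction (so unmethylated templates amplify
#' preferentially), injects PCR and sequencing substitution errors, and
#' samples Phred scores with a cytosine penalty. Each template gets a
#' random UMI carried by all of its PCR copies, appended to the read name
#' (`_UMI` convention) and exposed as the `umi` column / `RX` tag.
#'
#' @param reference A `bs_reference` from [generate_reference()].
#' @param truth A `bs_truth` from [plant_methylation()].
#' @param config A [sim_config()] object.
#' @return A list with `reads` (the aligned-read `data.table`: `qname`,
#'   `umi`, `ref`, 0-based `start`, `cigar`, `seq`, `qual`, `orientation`,
#'   `mate`, `reverse`) and `read_truth` (`data.table` of per-molecule
#'   provenance: `read_id`, `template_id`, `is_pcr_duplicate`,
#'   `is_resistant`, `unconv_frac`).
#' @export
simulate_reads <- function(reference, truth, config) {
  stopifnot(inherits(reference, "bs_reference"), inherits(truth, "bs_truth"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  seqs <- as.character(reference$sequences)
  ids <- names(seqs)
  sites <- truth$sites

  mean_frag <- mean(config$fragment_length)
  mol_list <- vector("list", length(ids))
  tid_offset <- 0L
  for (k in seq_along(ids)) {
    id <- ids[k]
    L <- nchar(seqs[k])
    s_chars <- strsplit(seqs[k], "", fixed = TRUE)[[1]]
    n_templates <- max(1L, as.integer(round(config$mean_coverage * L / mean_frag)))
    fl <- pmin(L, sample_int_range(config$fragment_length[1],
                                   config$fragment_length[2], n_templates))
    fs <- vapply(fl, function(f) sample.int(L - f + 1L, 1L) - 1L, integer(1))
    r_frac <- if (is.null(config$resistant_transcripts)) {
      config$resistant_read_fraction
    } else if (id %in% config$resistant_transcripts) {
      config$resistant_read_fraction
    } else 0
    resistant <- runif(n_templates) < r_frac
    tx_sites <- sites[ref == id]
    frag_seq <- character(n_templates)
    unconv <- numeric(n_templates)
    for (m in seq_len(n_templates)) {
      idx <- (fs[m] + 1L):(fs[m] + fl[m])
      chars <- s_chars[idx]
      cpos <- which(chars == "C")
      meth_off <- integer(0)
      if (nrow(tx_sites) > 0) {
        inside <- tx_sites[pos >= fs[m] & pos < fs[m] + fl[m]]
        if (nrow(inside) > 0) {
          meth <- runif(nrow(inside)) < inside$level
          meth_off <- inside$pos[meth] - fs[m] + 1L
        }
      }
      if (!resistant[m]) {
        conv_targets <- setdiff(cpos, meth_off)
        if (length(conv_targets) > 0) {
          conv <- conv_targets[runif(length(conv_targets)) < config$conversion_rate]
          chars[conv] <- "T"
        }
      }
      frag_seq[m] <- paste(chars, collapse = "")
      unconv[m] <- if (length(cpos) > 0) sum(chars[cpos] == "C") / length(cpos) else 0
    }
    mol_list[[k]] <- data.table::data.table(
      template_id = tid_offset + seq_len(n_templates),
      ref = id, fs = fs, fl = fl, seq = frag_seq,
      unconv_frac = unconv, is_resistant = resistant)
    tid_offset <- tid_offset + n_templates
  }
  molecules <- data.table::rbindlist(mol_list)
  molecules[, umi := random_umis(.N, config$umi_length)]
  molecules[, is_pcr_duplicate := FALSE]

  # PCR: discrete rounds; each molecule duplicates with probability
  # efficiency * max(0, 1 - beta * unconverted-C fraction); copies acquire
  # substitution errors and can themselves duplicate in later rounds.
  if (config$pcr_cycles > 0 && config$pcr_efficiency > 0) {
    for (cyc in seq_len(config$pcr_cycles)) {
      p_dup <- config$pcr_efficiency *
        pmax(0, 1 - config$pcr_bias_beta * molecules$unconv_frac)
      dup <- runif(nrow(molecules)) < p_dup
      if (any(dup)) {
        copies <- molecules[dup]
        copies[, is_pcr_duplicate := TRUE]
        copies[, seq := mutate_seqs(seq, config$pcr_error_rate)]
        molecules <- rbind(molecules, copies)
      }
    }
  }
  molecules[, copy := seq_len(.N), by = template_id]
  molecules[, qname := sprintf("T%06d.%d_%s", template_id, copy, umi)]

  # Sequencing: read 1 from the fragment 5' end; in paired mode read 2 from
  # the 3' end, stored reverse-complemented (reference orientation) as an
  # aligner would emit it.
  rl <- config$read_length
  r1_len <- pmin(rl, molecules$fl)
  r1 <- data.table::data.table(
    qname = molecules$qname, umi = molecules$umi, ref = molecules$ref,
    start = molecules$fs, seq = substr(molecules$seq, 1L, r1_len),
    orientation = "C2T", mate = if (config$paired) "R1" else "SE",
    reverse = FALSE)
  reads <- r1
  if (config$paired) {
    r2_len <- pmin(rl, molecules$fl)
    r2 <- data.table::data.table(
      qname = molecules$qname, umi = molecules$umi, ref = molecules$ref,
      start = molecules$fs + molecules$fl - r2_len,
      seq = substr(molecules$seq, molecules$fl - r2_len + 1L, molecules$fl),
      orientation = "G2A", mate = "R2", reverse = TRUE)
    reads <- rbind(r1, r2)
  }
  reads[, seq := mutate_seqs(seq, config$seq_error_rate)]
  reads[, qual := sample_quals(seq, reverse, config)]
  reads[, cigar := paste0(nchar(seq), "M")]
  data.table::setcolorder(reads, c(READ_COLS, "reverse"))
  data.table::setorder(reads, ref, start, qname, mate)

  read_truth <- molecules[, .(read_id = qname, template_id, is_pcr_duplicate,
                              is_resistant, unconv_frac, ref)]
  list(reads = reads[], read_truth = read_truth[])
}

random_umis <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Substitution errors at `rate` per base; only strings that draw at least
# one error are rebuilt.
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (h in hit) {
    chars <- strsplit(seqs[h], "", fixed = TRUE)[[1]]
    at <- sample.int(length(chars), n_err[h])
    for (a in at) {
      chars[a] <- sample(setdiff(bases, chars[a]), 1L)
    }
    seqs[h] <- paste(chars, collapse = "")
  }
  seqs
}

# Truncated-normal Phred scores; cytosine calls (guanine on reverse-stored
# reads) are penalised by qual_c_penalty, reproducing the quality asymmetry
# of bisulfite libraries.
sample_quals <- function(seqs, reverse, config) {
  if (length(seqs) == 0) return(character(0))
  widths <- nchar(seqs)
  f <- rep(seq_along(seqs), widths)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  penalised <- (chars == "C" & !reverse[f]) | (chars == "G" & reverse[f])
  mu <- config$qual_mean_non_c - config$qual_c_penalty * penalised
  q <- round(rnorm(length(chars), mu, config$qual_sd))
  q <- pmin(pmax(q, 2), 41)
  vapply(split(as.integer(q), f), phred_encode_one, character(1),
         USE.NAMES = FALSE)
}
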