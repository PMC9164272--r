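#' Read-level QC configuration
#'
#' Thresholds for the pre-processing filters: minimum retained length,
#' polyX trimming, mean-quality and low-quality-fraction read filters,
#' fixed end trimming against m-bias, the paired-mate overlap requirement,
#' and the per-base Q30 gate applied later at candidate sites.
#'
#' @param min_length Minimum read length after trimming (nt).
#' @param polyx_min_run Minimum homopolymer run at the read 3' end to trim.
#' @param min_mean_q Minimum mean Phred score per read.
#' @param max_lowq_fraction Maximum tolerated fraction of bases below
#'   `lowq_threshold`.
#' @param lowq_threshold Phred score below which a base counts as low
#'   quality.
#' @param end_trim_5,end_trim_3 Fixed trim (nt) from the read 5' and 3'
#'   ends.
#' @param require_mate_overlap In paired mode, discard fragments whose
#'   mates do not share at least one reference base.
#' @param min_site_base_q Per-base Phred gate used at candidate sites
#'   during methylation calling.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_length = 50L, polyx_min_run = 10L, min_mean_q = 25,
                      max_lowq_fraction = 0.40, lowq_threshold = 25,
                      end_trim_5 = 6L, end_trim_3 = 6L,
                      require_mate_overlap = TRUE, min_site_base_q = 30) {
  cfg <- list(min_length = as.integer(min_length),
              polyx_min_run = as.integer(polyx_min_run),
              min_mean_q = min_mean_q,
              max_lowq_fraction = max_lowq_fraction,
              lowq_threshold = lowq_threshold,
              end_trim_5 = as.integer(end_trim_5),
              end_trim_3 = as.integer(end_trim_3),
              require_mate_overlap = isTRUE(require_mate_overlap),
              min_site_base_q = min_site_base_q)
  if (any(unlist(cfg[c("min_length", "polyx_min_run", "min_mean_q",
                       "max_lowq_fraction", "end_trim_5", "end_trim_3")]) < 0))
    stop("qc thresholds must be non-negative")
  if (cfg$polyx_min_run < 2) stop("polyx_min_run must be >= 2")
  structure(cfg, class = "qc_config")
}

# Head/tail homopolymer run lengths of a character vector of sequences.
run_length_tail <- function(seq) {
  out <- integer(length(seq))
  nz <- nzchar(seq)
  out[nz] <- nchar(seq[nz]) - nchar(sub("(.)\\1*$", "", seq[nz]))
  out
}
run_length_head <- function(seq) {
  out <- integer(length(seq))
  nz <- nzchar(seq)
  out[nz] <- nchar(seq[nz]) - nchar(sub("^(.)\\1*", "", seq[nz]))
  out
}

#' Trim 3'-end homopolymer runs (polyX)
#'
#' Removes a trailing single-nucleotide run of at least `min_run` bases
#' from the read 3' end (the left end of reverse-stored reads, whose
#' alignment start advances accordingly). Qualities are trimmed in
#' lockstep; a read that is entirely one homopolymer becomes empty and is
#' later discarded by the length filter.
#'
#' @param reads Aligned-read `data.table`.
#' @param min_run Minimum run length to trigger trimming.
#' @return The reads table with trimmed `seq`/`qual`/`cigar`/`start`.
#' @export
trim_polyx <- function(reads, min_run = 10L) {
  stopifnot(min_run >= 2)
  reads <- data.table::copy(validate_reads(reads))
  fwd <- !reads$reverse
  run <- integer(nrow(reads))
  run[fwd] <- run_length_tail(reads$seq[fwd])
  run[!fwd] <- run_length_head(reads$seq[!fwd])
  trim <- ifelse(run >= min_run, run, 0L)
  n <- nchar(reads$seq)
  new_len <- n - trim
  hit <- trim > 0L
  if (any(hit & fwd)) {
    i <- which(hit & fwd)
    reads[i, `:=`(seq = substr(seq, 1L, new_len[i]),
                  qual = substr(qual, 1L, new_len[i]))]
  }
  if (any(hit & !fwd)) {
    i <- which(hit & !fwd)
    reads[i, `:=`(seq = substr(seq, trim[i] + 1L, n[i]),
                  qual = substr(qual, trim[i] + 1L, n[i]),
                  start = start + trim[i])]
  }
  reads[hit, cigar := ifelse(nchar(seq) > 0, paste0(nchar(seq), "M"), "*")]
  reads[]
}

#' Trim a fixed number of bases from both read ends
#'
#' Removes `n5` bases from the read 5' end and `n3` from the 3' end
#' (m-bias mitigation for residual random-primer bases), adjusting the
#' alignment start in reference space. Reads shorter than `n5 + n3 + 1`
#' become empty and are discarded by the following length check.
#'
#' @param reads Aligned-read `data.table`.
#' @param n5,n3 Bases to trim from the 5' and 3' ends.
#' @return The trimmed reads table.
#' @export
trim_fixed_ends <- function(reads, n5 = 6L, n3 = 6L) {
  reads <- data.table::copy(validate_reads(reads))
  if (n5 == 0 && n3 == 0) return(reads)
  n <- nchar(reads$seq)
  too_short <- n <= n5 + n3
  fwd <- !reads$reverse
  # stored-string left trim: n5 for forward reads, n3 for reverse-stored
  left <- ifelse(fwd, n5, n3)
  right <- ifelse(fwd, n3, n5)
  ok <- !too_short
  reads[ok, `:=`(seq = substr(seq, left[ok] + 1L, n[ok] - right[ok]),
                 qual = substr(qual, left[ok] + 1L, n[ok] - right[ok]),
                 start = start + left[ok])]
  reads[too_short, `:=`(seq = "", qual = "", cigar = "*")]
  reads[ok, cigar := paste0(nchar(seq), "M")]
  reads[]
}

# Mark paired reads whose mates do not share a reference base (or whose
# mate is missing/already flagged); `reason` entries stay untouched where
# already set.
flag_mate_overlap <- function(reads, reason = rep(NA_character_, nrow(reads))) {
  paired <- reads$mate %in% c("R1", "R2")
  if (!any(paired)) return(reason)
  iv <- data.table::data.table(qname = reads$qname, mate = reads$mate,
                               s = reads$start,
                               e = reads$start + nchar(reads$seq),
                               bad = !is.na(reason))[paired]
  m1 <- iv[mate == "R1"]; m2 <- iv[mate == "R2"]
  mm <- merge(m1, m2, by = "qname", suffixes = c("_1", "_2"))
  overlap_ok <- mm$qname[mm$s_1 < mm$e_2 & mm$s_2 < mm$e_1 &
                           !mm$bad_1 & !mm$bad_2]
  fail <- paired & is.na(reason) & !(reads$qname %in% overlap_ok)
  reason[fail] <- "mate_overlap"
  reason
}

# Per-read mean Phred and low-quality fraction.
read_quality_stats <- function(reads, lowq_threshold) {
  qs <- phred_decode(reads$qual)
  data.table::data.table(
    read_len = nchar(reads$seq),
    mean_q = vapply(qs, function(q) if (length(q)) mean(q) else 0, numeric(1)),
    lowq_frac = vapply(qs, function(q)
      if (length(q)) mean(q < lowq_threshold) else 1, numeric(1)))
}

#' Apply the read-level keep/discard filters
#'
#' Discards reads shorter than `min_length`, with mean Phred below
#' `min_mean_q`, with more than `max_lowq_fraction` of bases below
#' `lowq_threshold`, or (paired mode with `require_mate_overlap`) whose
#' mates do not share at least one reference base; when one mate of a
#' fragment fails, both are discarded. The `reason` column records the
#' first failed rule.
#'
#' @param reads Aligned-read `data.table` (already trimmed).
#' @param cfg A [qc_config()].
#' @return `list(reads, discarded, log)`: kept reads, discarded reads with
#'   reasons, and a per-reason count table.
#' @export
qc_filter <- function(reads, cfg = qc_config()) {
  reads <- validate_reads(reads)
  st <- read_quality_stats(reads, cfg$lowq_threshold)
  reason <- rep(NA_character_, nrow(reads))
  reason[is.na(reason) & st$read_len < cfg$min_length] <- "length"
  reason[is.na(reason) & st$mean_q < cfg$min_mean_q] <- "mean_q"
  reason[is.na(reason) & st$lowq_frac > cfg$max_lowq_fraction] <- "lowq_fraction"
  if (cfg$require_mate_overlap)
    reason <- flag_mate_overlap(reads, reason)
  keep <- is.na(reason)
  log <- data.table::data.table(reason = reason[!keep])[, .N, by = reason]
  list(reads = reads[keep], discarded = cbind(reads[!keep],
                                              reason = reason[!keep]),
       log = log)
}

#' Run the full read pre-processing pipeline
#'
#' Fixed order: polyX trim, length check, per-read quality filters, fixed
#' end trim, length re-check, then (paired mode) the mate-overlap rule on
#' the final trimmed coordinates — evaluating overlap after trimming keeps
#' the pipeline idempotent, since a rerun sees the same coordinates. The
#' pipeline only removes bases or reads, never alters a retained base or
#' quality; end trimming marks reads with an `end_trimmed` column and is
#' not re-applied on a second pass.
#'
#' @param reads Aligned-read `data.table`.
#' @param cfg A [qc_config()].
#' @return `list(reads, log)`: retained reads and a stage log
#'   (`stage`, `n_in`, `n_out`, reason counts as attribute).
#' @export
qc_pipeline <- function(reads, cfg = qc_config()) {
  reads <- validate_reads(reads)
  n0 <- nrow(reads)
  reads <- trim_polyx(reads, cfg$polyx_min_run)
  cfg_pre <- cfg
  cfg_pre$require_mate_overlap <- FALSE
  f1 <- qc_filter(reads, cfg_pre)
  reads <- f1$reads
  # the fixed end trim is a once-per-dataset correction: reads already
  # carrying the marker are left alone, making the pipeline idempotent
  if (is.null(reads$end_trimmed)) reads[, end_trimmed := FALSE]
  todo <- !reads$end_trimmed
  if (any(todo)) {
    trimmed <- trim_fixed_ends(reads[todo], cfg$end_trim_5, cfg$end_trim_3)
    trimmed[, end_trimmed := TRUE]
    reads <- rbind(trimmed, reads[!todo])
    data.table::setorder(reads, ref, start, qname, mate)
  }
  # length re-check after end trimming
  relen <- nchar(reads$seq) >= cfg$min_length
  log2 <- data.table::data.table(
    reason = rep("length_after_end_trim", sum(!relen)))[, .N, by = reason]
  reads <- reads[relen]
  # mate overlap on the final, trimmed coordinates
  log3 <- NULL
  if (cfg$require_mate_overlap) {
    reason <- flag_mate_overlap(reads)
    log3 <- data.table::data.table(
      reason = reason[!is.na(reason)])[, .N, by = reason]
    reads <- reads[is.na(reason)]
  }
  log <- rbind(f1$log, log2, log3)
  stage_log <- data.table::data.table(stage = c("input", "qc"),
                                      n_reads = c(n0, nrow(reads)))
  list(reads = reads[], log = log, stages = stage_log)
}

#' Per-position, per-nucleotide sequencing quality profile
#'
#' Mean Phred score and base count for each read-space position and
#' nucleotide, plus a candidate-base summary: the mean quality of
#' candidate (p-m5C) base calls — C on forward reads, G on reverse-stored
#' reads — against the mean of all other calls.
#'
#' @param reads Aligned-read `data.table`.
#' @return `list(per_position, candidate)`; `per_position` has columns
#'   `position`, `nt`, `mean_q`, `count`; `candidate` has
#'   `mean_candidate`, `mean_other` and `n_candidate`.
#' @export
quality_profile <- function(reads) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) {
    return(list(per_position = data.table::data.table(
      position = integer(), nt = character(), mean_q = numeric(),
      count = integer()),
      candidate = list(mean_candidate = NA_real_, mean_other = NA_real_,
                       n_candidate = 0L)))
  }
  widths <- nchar(reads$seq)
  f <- rep(seq_len(nrow(reads)), widths)
  chars <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
  q <- unlist(phred_decode(reads$qual), use.names = FALSE)
  # read-space position: reverse-stored reads are flipped
  off <- sequence(widths)
  rev_row <- reads$reverse[f]
  position <- ifelse(rev_row, widths[f] - off + 1L, off)
  dt <- data.table::data.table(position = position, nt = chars, q = q)
  per_pos <- dt[, .(mean_q = mean(q), count = .N), by = .(position, nt)]
  data.table::setorder(per_pos, position, nt)
  is_cand <- (chars == "C" & !rev_row) | (chars == "G" & rev_row)
  candidate <- list(mean_candidate = if (any(is_cand)) mean(q[is_cand]) else NA_real_,
                    mean_other = if (any(!is_cand)) mean(q[!is_cand]) else NA_real_,
                    n_candidate = sum(is_cand))
  list(per_position = per_pos, candidate = candidate)
}
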