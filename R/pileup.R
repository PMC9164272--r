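# Base-level expansion of aligned reads.
#
# Maps every aligned query base to its reference position using the CIGAR
# (M/=/X segments; insertions, clips and skips contribute no reference
# bases). Returns one row per aligned base with 0-based `pos`.
expand_bases <- function(reads, min_base_q = 0, extra_cols = NULL) {
  reads <- validate_reads(reads)
  keep_cols <- c("qname", "ref", "mate", "reverse", extra_cols)
  reads <- reads[nzchar(seq) & cigar != "*"]
  if (nrow(reads) == 0) {
    out <- data.table::data.table(qname = character(), ref = character(),
                                  mate = character(), reverse = logical(),
                                  pos = integer(), base = character(),
                                  q = integer())
    for (cc in extra_cols) out[[cc]] <- integer(0)
    return(out)
  }
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(reads$cigar,
                                                      ops = c("M", "=", "X"))
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(reads$cigar,
                                                          ops = c("M", "=", "X"))
  nseg <- S4Vectors::elementNROWS(qr)
  seg_read <- rep(seq_len(nrow(reads)), nseg)
  qs <- unlist(BiocGenerics::start(qr), use.names = FALSE)
  rs <- unlist(BiocGenerics::start(rr), use.names = FALSE)
  seg_w <- unlist(BiocGenerics::width(qr), use.names = FALSE)
  b_read <- rep(seg_read, seg_w)
  within <- sequence(seg_w)
  qpos <- rep(qs, seg_w) + within - 1L
  rpos0 <- reads$start[b_read] + rep(rs, seg_w) + within - 2L
  widths <- nchar(reads$seq)
  prefix <- c(0L, cumsum(widths))
  flat <- prefix[b_read] + qpos
  chars <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
  quals <- unlist(phred_decode(reads$qual), use.names = FALSE)
  out <- data.table::data.table(qname = reads$qname[b_read],
                                ref = reads$ref[b_read],
                                mate = reads$mate[b_read],
                                reverse = reads$reverse[b_read],
                                pos = rpos0,
                                base = chars[flat],
                                q = quals[flat])
  for (cc in extra_cols) out[[cc]] <- reads[[cc]][b_read]
  if (min_base_q > 0) out <- out[q >= min_base_q]
  out
}

# Collapse overlapping mate bases of a fragment to one observation per
# (fragment, reference position): higher quality wins, ties go to read 1.
collapse_mate_overlap <- function(bl) {
  data.table::setorder(bl, qname, ref, pos, -q, mate)
  unique(bl, by = c("qname", "ref", "pos"))
}

#' One-sided binomial tail probability for a candidate site
#'
#' `P(X >= i | n = j, p = error_rate)` — the probability of observing at
#' least `i` unconverted cytosines out of `j` (C+T) reads if the site were
#' unmethylated and conversion failed at `error_rate` (one minus the
#' spike-in-calibrated conversion rate).
#'
#' @param i Candidate (unconverted C) count(s).
#' @param j (C+T) coverage(s).
#' @param error_rate Per-base false-methylation probability in (0, 1).
#' @return Numeric p-value(s).
#' @export
binomial_pvalue <- function(i, j, error_rate) {
  if (any(error_rate <= 0 | error_rate >= 1))
    stop("error_rate must lie strictly within (0, 1)")
  if (any(i < 0 | i > j)) stop("require 0 <= i <= j")
  pbinom(i - 1, j, error_rate, lower.tail = FALSE)
}

#' Call candidate methylation sites from aligned bisulfite reads
#'
#' For every reference cytosine (transcript strand; reverse-stored mates
#' are already in reference orientation), counts read bases C (the
#' candidate count `i`) and T among bases with Phred at least
#' `min_base_q`; `j = i + T` is the (C+T) coverage, and other bases are
#' tracked separately. Overlapping mate bases are counted once (higher
#' quality wins, ties to read 1). Sites with `j >= min_cov` are emitted
#' with the methylation level `i/j` and a one-sided binomial p-value
#' against `error_rate`.
#'
#' @param reads Aligned-read `data.table` (QC'd and deduplicated).
#' @param reference `bs_reference` or named [Biostrings::DNAStringSet].
#' @param min_base_q Per-base Phred gate at candidate sites (Q30).
#' @param min_cov Minimum (C+T) coverage to emit a site.
#' @param error_rate Assumed conversion-failure rate; default one minus
#'   the 99.9 percent conversion typical of a well-converted library —
#'   pass `1 - conversion_rate(...)$rate` to calibrate from spike-ins.
#' @param min_level Suppress sites with a positive level below this
#'   (minimum reported methylation rate); 0 keeps everything.
#' @return A site `data.table`: `ref`, `pos` (0-based), `pos1`, `strand`,
#'   `i`, `j`, `level`, `p_value`, `n_other`.
#' @export
call_sites <- function(reads, reference, min_base_q = 30, min_cov = 10,
                       error_rate = 0.001, min_level = 0) {
  seqs <- if (inherits(reference, "bs_reference")) reference$sequences else reference
  reads <- validate_reads(reads)
  bad <- setdiff(unique(reads$ref), names(seqs))
  if (length(bad) > 0)
    stop("reads reference contig(s) absent from reference: ",
         paste(bad, collapse = ", "))
  cdt <- reference_c_positions(seqs)
  bl <- expand_bases(reads)
  bl <- bl[cdt, on = c("ref", "pos"), nomatch = NULL]
  bl <- collapse_mate_overlap(bl)
  bl <- bl[q >= min_base_q]
  sites <- bl[, .(i = sum(base == "C"), n_t = sum(base == "T"),
                  n_other = sum(base != "C" & base != "T")),
              by = .(ref, pos)]
  sites[, j := i + n_t]
  sites <- sites[j >= min_cov]
  sites[, `:=`(pos1 = pos + 1L, strand = "+", level = ifelse(j > 0, i / j, 0))]
  sites[, p_value := binomial_pvalue(i, j, error_rate)]
  if (min_level > 0) sites <- sites[level == 0 | level >= min_level]
  data.table::setcolorder(sites, c("ref", "pos", "pos1", "strand", "i", "j",
                                   "level", "p_value", "n_other"))
  data.table::setorder(sites, ref, pos)
  sites[, n_t := NULL]
  sites[]
}

#' Estimate bisulfite conversion rate from unmethylated spike-in controls
#'
#' Over reads mapped to control sequences, the conversion rate is
#' `T / (C + T)` at reference-C positions — any retained C on an
#' unmethylated control is an artifact. Also reports, per fragment, the
#' number of candidate (unconverted C) bases: the fraction of reads free
#' of candidates and a binned histogram (0, 1, 2-5, 6-20, >20).
#'
#' @param reads Aligned-read `data.table`.
#' @param reference `bs_reference` or named [Biostrings::DNAStringSet].
#' @param control_ids Control sequence IDs (defaults to the
#'   `bs_reference`'s own controls).
#' @param min_base_q Optional Phred gate on counted bases (0 = all).
#' @return A `conversion_stats` list: `rate`, `per_control`
#'   (`data.table(ref, converted, total, rate)`),
#'   `zero_candidate_fraction`, `candidate_histogram`, `n_reads`.
#' @export
conversion_rate <- function(reads, reference, control_ids = NULL,
                            min_base_q = 0) {
  seqs <- if (inherits(reference, "bs_reference")) reference$sequences else reference
  if (is.null(control_ids) && inherits(reference, "bs_reference"))
    control_ids <- reference$control_ids
  if (length(control_ids) == 0) stop("no control sequence IDs supplied")
  reads <- validate_reads(reads)
  ctrl_reads <- reads[ref %in% control_ids]
  if (nrow(ctrl_reads) == 0) {
    warning("no reads mapped to control sequences; conversion rate undefined")
    return(structure(list(rate = NA_real_,
                          per_control = data.table::data.table(
                            ref = character(), converted = integer(),
                            total = integer(), rate = numeric()),
                          zero_candidate_fraction = NA_real_,
                          candidate_histogram = NULL, n_reads = 0L),
                     class = "conversion_stats"))
  }
  cdt <- reference_c_positions(seqs[control_ids])
  bl <- expand_bases(ctrl_reads)
  bl <- bl[cdt, on = c("ref", "pos"), nomatch = NULL]
  bl <- collapse_mate_overlap(bl)
  if (min_base_q > 0) bl <- bl[q >= min_base_q]
  per_control <- bl[, .(converted = sum(base == "T"),
                        total = sum(base == "T") + sum(base == "C")),
                    by = ref]
  per_control[, rate := ifelse(total > 0, converted / total, NA_real_)]
  pooled <- per_control[, sum(converted) / sum(total)]
  per_frag <- bl[, .(n_cand = sum(base == "C")), by = qname]
  # fragments covering no reference C still count as candidate-free
  all_frags <- unique(ctrl_reads$qname)
  n_cand <- setNames(rep(0L, length(all_frags)), all_frags)
  n_cand[per_frag$qname] <- per_frag$n_cand
  bins <- cut(n_cand, breaks = c(-Inf, 0, 1, 5, 20, Inf),
              labels = c("0", "1", "2-5", "6-20", ">20"))
  structure(list(rate = pooled, per_control = per_control[],
                 zero_candidate_fraction = mean(n_cand == 0),
                 candidate_histogram = table(bins),
                 n_reads = length(all_frags)),
            class = "conversion_stats")
}

#' Per-read unconverted-cytosine content
#'
#' Number of positions at which the reference has C (in the read's
#' conversion space) and the read still reports C — the quantity the read
#' C-cutoff thresholds. Counted per fragment (mate overlaps collapsed),
#' with no quality gate, and including genuinely methylated positions.
#'
#' @param reads Aligned-read `data.table`.
#' @param reference `bs_reference` or named [Biostrings::DNAStringSet].
#' @return `data.table(qname, c_content)` covering every input fragment.
#' @export
read_c_content <- function(reads, reference) {
  seqs <- if (inherits(reference, "bs_reference")) reference$sequences else reference
  reads <- validate_reads(reads)
  cdt <- reference_c_positions(seqs)
  bl <- expand_bases(reads)
  bl <- bl[cdt, on = c("ref", "pos"), nomatch = NULL]
  bl <- collapse_mate_overlap(bl)
  per_frag <- bl[, .(c_content = sum(base == "C")), by = qname]
  out <- data.table::data.table(qname = unique(reads$qname))
  out[per_frag, c_content := i.c_content, on = "qname"]
  out[is.na(c_content), c_content := 0L]
  out[]
}
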