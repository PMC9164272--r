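# Shared fixtures: hand-built read tables and a small cached simulation.

# Build an aligned-read table by hand. `seq` is a character vector; other
# arguments recycle.
mk_reads <- function(seq, start = 0L, ref = "TXA", qual = NULL,
                     umi = "ACGTACGT", qname = NULL, mate = "SE",
                     reverse = FALSE, orientation = "C2T") {
  n <- length(seq)
  if (is.null(qual)) qual <- vapply(nchar(seq), function(w)
    paste(rep("I", w), collapse = ""), character(1))  # "I" = Q40
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  data.table::data.table(
    qname = rep_len(qname, n), umi = rep_len(umi, n), ref = rep_len(ref, n),
    start = as.integer(rep_len(start, n)),
    cigar = paste0(nchar(seq), "M"), seq = seq,
    qual = rep_len(qual, n), orientation = rep_len(orientation, n),
    mate = rep_len(mate, n), reverse = rep_len(reverse, n))
}

# Phred string helper: qual_str(c(30, 20)) -> characters at Q30, Q20.
qual_str <- function(q) rawToChar(as.raw(as.integer(q) + 33L))

mk_refset <- function(...) {
  seqs <- Biostrings::DNAStringSet(c(...))
  seqs
}

# Small simulation config for module tests (fast: ~1-2 s); overrides win.
tiny_config <- function(...) {
  defaults <- list(n_transcripts = 4, n_control_transcripts = 1,
                   length_range = c(500L, 800L), n_true_sites = 6,
                   mean_coverage = 25, read_length = 80L,
                   fragment_length = c(100L, 160L))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# One shared tiny dataset, built lazily and reused across test files.
.fixture_env <- new.env(parent = emptyenv())
tiny_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- simulate_dataset(tiny_config(seed = 42))
  .fixture_env$ds
}
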