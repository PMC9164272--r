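# Internal helpers shared across modules.

# Decode a vector of Phred+33 quality strings into a list of integer vectors.
phred_decode <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

# Encode integer Phred scores (clamped to [0, 41]) into a Phred+33 string.
phred_encode <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 0L), 41L)
  vapply(split(q, rep(1L, length(q))), function(v) rawToChar(as.raw(v + 33L)),
         character(1), USE.NAMES = FALSE)
}

phred_encode_one <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 0L), 41L)
  rawToChar(as.raw(q + 33L))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a reads table (the package's AlignedRead container): one row per
# aligned read, 0-based `start`, Phred+33 `qual`, orientation C2T or G2A.
READ_COLS <- c("qname", "umi", "ref", "start", "cigar", "seq", "qual",
               "orientation", "mate")

validate_reads <- function(reads) {
  if (!is.data.frame(reads)) stop("reads must be a data.frame/data.table")
  reads <- data.table::as.data.table(reads)
  missing_cols <- setdiff(READ_COLS, names(reads))
  if (length(missing_cols) > 0)
    stop("reads table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(reads) > 0) {
    if (any(nchar(reads$seq) != nchar(reads$qual)))
      stop("seq and qual lengths differ for some reads")
    if (any(reads$start < 0L)) stop("negative alignment start")
    if (!all(reads$orientation %in% c("C2T", "G2A")))
      stop("orientation must be 'C2T' or 'G2A'")
  }
  reads
}

# Reference C positions (0-based) per sequence, as a data.table(ref, pos).
reference_c_positions <- function(reference) {
  stopifnot(is(reference, "DNAStringSet"))
  hits <- Biostrings::vmatchPattern("C", reference)
  dt <- data.table::rbindlist(lapply(seq_along(hits), function(k) {
    s <- BiocGenerics::start(hits[[k]])
    if (length(s) == 0) return(NULL)
    data.table::data.table(ref = names(reference)[k], pos = s - 1L)
  }))
  if (nrow(dt) == 0) dt <- data.table::data.table(ref = character(), pos = integer())
  data.table::setkey(dt, ref, pos)
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform integer draws from [a, b]; safe when a == b (base::sample would
# otherwise treat the single value as a range length).
sample_int_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n)
  else sample(seq(as.integer(a), as.integer(b)), n, replace = TRUE)
}
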