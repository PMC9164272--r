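#' Write aligned reads as a coordinate-sorted SAM file
#'
#' Emits a SAM 1.6 text file with `@SQ` lines for every reference sequence,
#' proper paired-end flags, the UMI both as the `_UMI` read-name suffix and
#' as an `RX` tag, and 1-based mapping positions (internal coordinates are
#' 0-based half-open).
#'
#' @param reads Aligned-read `data.table` (see [simulate_reads()]).
#' @param reference A `bs_reference` or named [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  reads <- validate_reads(reads)
  seqs <- if (inherits(reference, "bs_reference")) reference$sequences else reference
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), Biostrings::width(seqs)),
              "@PG\tID:rnabs\tPN:rnabs")
  reads <- data.table::copy(reads)
  reads[, ref := factor(ref, levels = names(seqs))]
  data.table::setorder(reads, ref, start, qname, mate)
  flag <- integer(nrow(reads))
  rnext <- rep("*", nrow(reads))
  pnext <- rep(0L, nrow(reads))
  tlen <- rep(0L, nrow(reads))
  paired <- reads$mate %in% c("R1", "R2")
  if (any(paired)) {
    pr <- reads[paired, .(qname, mate, start, end = start + nchar(seq), reverse)]
    m1 <- pr[mate == "R1"]; m2 <- pr[mate == "R2"]
    mm <- merge(m1, m2, by = "qname", suffixes = c("_1", "_2"))
    idx <- match(reads$qname, mm$qname)
    is_r1 <- reads$mate == "R1"
    mate_rev <- ifelse(is_r1, mm$reverse_2[idx], mm$reverse_1[idx])
    flag[paired] <- 1L + 2L +
      ifelse(reads$reverse[paired], 16L, 0L) +
      ifelse(mate_rev[paired], 32L, 0L) +
      ifelse(is_r1[paired], 64L, 128L)
    pnext[paired] <- ifelse(is_r1[paired], mm$start_2[idx[paired]],
                            mm$start_1[idx[paired]]) + 1L
    span <- pmax(mm$end_1[idx], mm$end_2[idx]) -
      pmin(mm$start_1[idx], mm$start_2[idx])
    tlen[paired] <- ifelse(is_r1[paired], span[paired], -span[paired])
    rnext[paired] <- "="
  }
  flag[!paired & reads$reverse] <- 16L
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tRX:Z:%s",
                  reads$qname, flag, as.character(reads$ref), reads$start + 1L,
                  255L, reads$cigar, rnext, pnext, tlen, reads$seq, reads$qual,
                  reads$umi)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an aligned SAM/BAM file into the package's read table
#'
#' Uses Rsamtools for parsing (SAM input is converted to BAM internally).
#' The UMI is taken from the `RX` tag when present, otherwise from the
#' trailing `_UMI` read-name component. Unmapped reads are dropped.
#'
#' @param path SAM or BAM file.
#' @param umi_source `"auto"` (tag, then read name), `"tag"` or `"name"`.
#' @return Aligned-read `data.table` with 0-based `start`.
#' @export
read_sam <- function(path, umi_source = c("auto", "tag", "name")) {
  umi_source <- match.arg(umi_source)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
      tag = "RX"))[[1]]
  keep <- !is.na(res$pos)
  fl <- res$flag[keep]
  reverse <- bitwAnd(fl, 16L) > 0L
  paired <- bitwAnd(fl, 1L) > 0L
  second <- bitwAnd(fl, 128L) > 0L
  mate <- ifelse(!paired, "SE", ifelse(second, "R2", "R1"))
  qname <- res$qname[keep]
  tag_umi <- res$tag$RX[keep]
  name_umi <- ifelse(grepl("_", qname),
                     sub(".*_", "", qname), NA_character_)
  umi <- switch(umi_source,
                tag = tag_umi,
                name = name_umi,
                auto = ifelse(!is.na(tag_umi) & nzchar(tag_umi), tag_umi, name_umi))
  reads <- data.table::data.table(
    qname = qname,
    umi = umi,
    ref = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,
    cigar = res$cigar[keep],
    seq = as.character(res$seq[keep]),
    qual = as.character(res$qual[keep]),
    orientation = ifelse(mate == "R2", "G2A", "C2T"),
    mate = mate,
    reverse = reverse)
  validate_reads(reads)
}

#' Write reads as FASTQ (read orientation)
#'
#' Reverse-stored reads are reverse-complemented back to sequencing
#' orientation; qualities are reversed in lockstep.
#'
#' @param reads Aligned-read `data.table`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- validate_reads(reads)
  seqs <- reads$seq
  quals <- reads$qual
  if (any(reads$reverse)) {
    idx <- which(reads$reverse)
    seqs[idx] <- reverse_complement(seqs[idx])
    quals[idx] <- vapply(quals[idx], function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""),
      character(1), USE.NAMES = FALSE)
  }
  suffix <- ifelse(reads$mate == "R1", "/1", ifelse(reads$mate == "R2", "/2", ""))
  out <- as.vector(rbind(paste0("@", reads$qname, suffix), seqs, "+", quals))
  writeLines(out, path)
  invisible(path)
}

#' Write a GTF annotation table
#'
#' Ensembl attribute dialect: `gene_id "X"; transcript_id "Y";`.
#'
#' @param annotation Annotation `data.table` (from [generate_reference()] or
#'   [read_gtf()]).
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   annotation$gene_id, annotation$transcript_id)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   annotation$seqname, annotation$source, annotation$feature,
                   annotation$start, annotation$end, annotation$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation into the package's gene-model table
#'
#' Minimal Ensembl-dialect parser retaining exon/CDS/UTR features; columns
#' match the annotation table emitted by [generate_reference()].
#'
#' @param path GTF file path.
#' @return Annotation `data.table` (1-based closed intervals).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop("empty GTF: ", path)
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) < 9) stop("malformed GTF: ", path)
  ann <- data.table::data.table(
    seqname = parts[[1]], source = parts[[2]], feature = parts[[3]],
    start = as.integer(parts[[4]]), end = as.integer(parts[[5]]),
    strand = parts[[7]],
    gene_id = extract_gtf_attr(parts[[9]], "gene_id"),
    transcript_id = extract_gtf_attr(parts[[9]], "transcript_id"))
  keep <- ann$feature %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr",
                             "UTR", "gene", "transcript")
  ann <- ann[keep]
  if (!any(ann$feature == "exon")) stop("GTF has no exon records: ", path)
  ann
}

extract_gtf_attr <- function(attrs, key) {
  pat <- paste0(key, ' "([^"]*)"')
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Write a simulated dataset to disk
#'
#' Runs [generate_reference()], [plant_methylation()] and
#' [simulate_reads()] under `config$seed` and writes `ref.fa`,
#' `genes.gtf`, `reads.sam`, optional `reads.fastq`, and truth TSVs to a
#' directory. The same seed reproduces byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if missing); `NULL` skips writing.
#' @param fastq Also write FASTQ?
#' @return A list with `reference`, `truth`, `reads`, `read_truth` and
#'   `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL, fastq = FALSE) {
  reference <- generate_reference(config)
  truth <- plant_methylation(reference, config)
  sim <- simulate_reads(reference, truth, config)
  truth$read_truth <- sim$read_truth
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "ref.fa"),
      gtf = file.path(dir, "genes.gtf"),
      sam = file.path(dir, "reads.sam"),
      truth_sites = file.path(dir, "truth_sites.tsv"),
      truth_reads = file.path(dir, "truth_reads.tsv"))
    Biostrings::writeXStringSet(reference$sequences, paths$fasta)
    write_gtf(reference$annotation, paths$gtf)
    write_sam(sim$reads, reference, paths$sam)
    data.table::fwrite(truth$sites, paths$truth_sites, sep = "\t")
    data.table::fwrite(sim$read_truth, paths$truth_reads, sep = "\t")
    if (fastq) {
      paths$fastq <- file.path(dir, "reads.fastq")
      write_fastq(sim$reads, paths$fastq)
    }
  }
  list(reference = reference, truth = truth, reads = sim$reads,
       read_truth = sim$read_truth, paths = paths)
}
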