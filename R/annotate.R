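#' Annotate sites with genes and feature classes
#'
#' Labels each site with the gene(s) whose exons overlap it and a feature
#' class (5'UTR, CDS, 3'UTR, exon-noncoding, or intergenic). When several
#' transcripts overlap, the label comes from the transcript with the
#' longest CDS; every overlapping gene is recorded in `gene_ids_all`.
#'
#' @param sites Site `data.table` (0-based `pos`).
#' @param annotation Annotation table (1-based closed intervals; see
#'   [read_gtf()]).
#' @return A copy of `sites` with `gene_id`, `transcript_id`,
#'   `feature_class` and `gene_ids_all` columns appended.
#' @export
annotate_sites <- function(sites, annotation) {
  sites <- data.table::copy(data.table::as.data.table(sites))
  ann <- data.table::as.data.table(annotation)
  if (!any(ann$feature == "exon")) stop("annotation has no exon records")
  if (nrow(sites) == 0) {
    sites[, `:=`(gene_id = character(0), transcript_id = character(0),
                 feature_class = character(0), gene_ids_all = character(0))]
    return(sites[])
  }
  cds_len <- ann[feature == "CDS",
                 .(cds_len = sum(end - start + 1L)), by = transcript_id]
  sites[, site_key := paste(ref, pos)]
  pos1 <- sites$pos + 1L
  hits <- list()
  for (feat in c("exon", "CDS", "five_prime_utr", "three_prime_utr")) {
    fa <- ann[feature == feat]
    if (nrow(fa) == 0) next
    for (r in seq_len(nrow(fa))) {
      idx <- which(sites$ref == fa$seqname[r] & pos1 >= fa$start[r] &
                     pos1 <= fa$end[r])
      if (length(idx) > 0)
        hits[[length(hits) + 1L]] <- data.table::data.table(
          site_key = sites$site_key[idx], gene_id = fa$gene_id[r],
          transcript_id = fa$transcript_id[r], feature = feat)
    }
  }
  sites[, `:=`(gene_id = NA_character_, transcript_id = NA_character_,
               feature_class = "intergenic", gene_ids_all = NA_character_)]
  if (length(hits) > 0) {
    h <- unique(data.table::rbindlist(hits))
    h <- merge(h, cds_len, by = "transcript_id", all.x = TRUE)
    h[is.na(cds_len), cds_len := 0L]
    rank_feat <- c(five_prime_utr = 1L, CDS = 2L, three_prime_utr = 3L,
                   exon = 4L)
    h[, feat_rank := rank_feat[feature]]
    all_genes <- h[, .(gene_ids_all = paste(sort(unique(gene_id)),
                                            collapse = ",")), by = site_key]
    data.table::setorder(h, site_key, -cds_len, transcript_id, feat_rank)
    best <- h[, .(gene_id = gene_id[1], transcript_id = transcript_id[1],
                  feature = feature[feat_rank == min(feat_rank[
                    transcript_id == transcript_id[1]]) &
                      transcript_id == transcript_id[1]][1]),
              by = site_key]
    class_of <- c(five_prime_utr = "5'UTR", CDS = "CDS",
                  three_prime_utr = "3'UTR", exon = "exon-noncoding")
    sites[best, `:=`(gene_id = i.gene_id, transcript_id = i.transcript_id,
                     feature_class = class_of[i.feature]), on = "site_key"]
    sites[all_genes, gene_ids_all := i.gene_ids_all, on = "site_key"]
  }
  sites[, site_key := NULL]
  sites[]
}

#' Metagene distribution of sites over binned transcripts
#'
#' Scales each annotated mRNA region to a fixed bin span — 5'UTR to bins
#' 1-5, CDS to bins 6-17, 3'UTR to bins 18-20 — and accumulates site
#' density, normalised to sum to 1. Sites on transcripts lacking any of
#' the three regions are skipped and counted.
#'
#' @param sites Site `data.table`.
#' @param annotation Annotation table with 5'UTR/CDS/3'UTR features.
#' @param n_bins Total bin count (20; region spans 5/12/3 scale
#'   proportionally for other values).
#' @return `list(density` (`data.table(bin, count, density)`),
#'   `n_assigned`, `n_skipped)`.
#' @export
metagene <- function(sites, annotation, n_bins = 20L) {
  sites <- data.table::as.data.table(sites)
  ann <- data.table::as.data.table(annotation)
  b5 <- max(1L, as.integer(round(n_bins * 5 / 20)))
  b3 <- max(1L, as.integer(round(n_bins * 3 / 20)))
  bc <- n_bins - b5 - b3
  regions <- ann[feature %in% c("five_prime_utr", "CDS", "three_prime_utr")]
  have_all <- regions[, .(n = data.table::uniqueN(feature)),
                      by = .(seqname, transcript_id)][n == 3]
  bins <- integer(0)
  n_skip <- 0L
  for (s in seq_len(nrow(sites))) {
    tx <- have_all[seqname == sites$ref[s]]
    if (nrow(tx) == 0) { n_skip <- n_skip + 1L; next }
    reg <- regions[transcript_id == tx$transcript_id[1]]
    p1 <- sites$pos[s] + 1L
    row <- reg[p1 >= start & p1 <= end]
    if (nrow(row) == 0) { n_skip <- n_skip + 1L; next }
    frac <- (p1 - row$start[1]) / (row$end[1] - row$start[1] + 1L)
    bin <- switch(row$feature[1],
                  five_prime_utr = 1L + as.integer(floor(frac * b5)),
                  CDS = b5 + 1L + as.integer(floor(frac * bc)),
                  three_prime_utr = b5 + bc + 1L + as.integer(floor(frac * b3)))
    bins <- c(bins, min(max(bin, 1L), n_bins))
  }
  counts <- tabulate(bins, nbins = n_bins)
  dens <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, n_bins)
  list(density = data.table::data.table(bin = seq_len(n_bins),
                                        count = counts, density = dens),
       n_assigned = length(bins), n_skipped = n_skip)
}

#' Positional nucleotide frequencies around sites
#'
#' Extracts `flank` bases either side of each site from the reference
#' (sites whose window would run off the sequence are skipped), returns
#' the `(2*flank+1) x 4` positional frequency matrix (center fixed to C),
#' and scores downstream GGG enrichment: the mean G frequency at offsets
#' +1 to +3 over the mean G frequency at all other non-center offsets.
#'
#' @param sites Site `data.table`.
#' @param reference `bs_reference` or named [Biostrings::DNAStringSet].
#' @param flank Bases either side of the site.
#' @return `list(matrix` (rows = offsets -flank..+flank, cols A/C/G/T),
#'   `ggg_score`, `n_used`, `n_skipped)`.
#' @export
motif_matrix <- function(sites, reference, flank = 10L) {
  seqs <- if (inherits(reference, "bs_reference")) reference$sequences else reference
  sites <- data.table::as.data.table(sites)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  p1 <- sites$pos + 1L
  ok <- p1 - flank >= 1L & p1 + flank <= lens[sites$ref]
  used <- sites[ok]
  offs <- seq(-flank, flank)
  if (nrow(used) == 0) {
    m <- matrix(NA_real_, nrow = length(offs), ncol = 4,
                dimnames = list(offs, c("A", "C", "G", "T")))
    return(list(matrix = m, ggg_score = NA_real_, n_used = 0L,
                n_skipped = sum(!ok)))
  }
  windows <- Biostrings::DNAStringSet(
    substr(as.character(seqs[used$ref]), used$pos + 1L - flank,
           used$pos + 1L + flank))
  cm <- Biostrings::consensusMatrix(windows, as.prob = TRUE,
                                    baseOnly = TRUE)[c("A", "C", "G", "T"), ,
                                                     drop = FALSE]
  m <- t(cm)
  rownames(m) <- offs
  g <- m[, "G"]
  down <- offs %in% 1:3
  bg_mask <- offs != 0 & !down
  ggg <- mean(g[down]) / mean(g[bg_mask])
  list(matrix = m, ggg_score = ggg, n_used = nrow(used),
       n_skipped = sum(!ok))
}

#' Per-gene read counts and CPM
#'
#' Counts fragments whose aligned span overlaps the union exons of
#' exactly one gene (fragments touching two genes stay unassigned) and
#' normalises to counts per million assigned fragments.
#'
#' @param reads Aligned-read `data.table`.
#' @param annotation Annotation table (exon rows).
#' @return `data.table(gene_id, count, cpm)` over genes with exons;
#'   `cpm` sums to 1e6 when any fragment is assigned.
#' @export
gene_cpm <- function(reads, annotation) {
  reads <- validate_reads(reads)
  ann <- data.table::as.data.table(annotation)[feature == "exon"]
  frags <- reads[, .(ref = ref[1], s = min(start),
                     e = max(start + nchar(seq))), by = qname]
  gene_hits <- data.table::rbindlist(lapply(seq_len(nrow(ann)), function(r) {
    idx <- which(frags$ref == ann$seqname[r] & frags$s < ann$end[r] &
                   frags$e > ann$start[r] - 1L)
    if (length(idx) == 0) return(NULL)
    data.table::data.table(qname = frags$qname[idx], gene_id = ann$gene_id[r])
  }))
  genes <- unique(ann$gene_id)
  if (nrow(gene_hits) == 0) {
    return(data.table::data.table(gene_id = genes, count = 0L, cpm = NA_real_))
  }
  gene_hits <- unique(gene_hits)
  uniq <- gene_hits[, .(n_genes = .N), by = qname][n_genes == 1, qname]
  assigned <- gene_hits[qname %in% uniq]
  counts <- assigned[, .(count = .N), by = gene_id]
  out <- data.table::data.table(gene_id = genes)
  out[counts, count := i.count, on = "gene_id"]
  out[is.na(count), count := 0L]
  total <- sum(out$count)
  out[, cpm := if (total > 0) count * 1e6 / total else NA_real_]
  out[]
}

#' Compare CPM with and without UMI deduplication
#'
#' @param reads_raw,reads_dedup Read tables before and after
#'   deduplication.
#' @param annotation Annotation table.
#' @return Per-gene table with `cpm_raw`, `cpm_dedup` and `log2fc`
#'   (dedup over raw).
#' @export
compare_cpm <- function(reads_raw, reads_dedup, annotation) {
  a <- gene_cpm(reads_raw, annotation)
  b <- gene_cpm(reads_dedup, annotation)
  out <- merge(a[, .(gene_id, count_raw = count, cpm_raw = cpm)],
               b[, .(gene_id, count_dedup = count, cpm_dedup = cpm)],
               by = "gene_id")
  out[, log2fc := log2(cpm_dedup / cpm_raw)]
  out[]
}

#' Compare two site tables: shared sites, correlation and tests
#'
#' Merges on coordinates; reports the Spearman correlation of shared
#' levels, a two-sided Wilcoxon rank-sum p-value comparing the level
#' vectors, and per-shared-site two-sided Fisher exact tests on the
#' `(i, j - i)` contingency (differential methylation), BH-adjusted.
#'
#' @param siteset_a,siteset_b Site tables in the same coordinate space.
#' @param alpha BH threshold for calling a differentially methylated
#'   site.
#' @return `list(shared, spearman, wilcoxon_p, n_shared, n_dms)`.
#' @export
compare_libraries <- function(siteset_a, siteset_b, alpha = 0.05) {
  a <- data.table::as.data.table(siteset_a)
  b <- data.table::as.data.table(siteset_b)
  shared <- merge(a[, .(ref, pos, i_a = i, j_a = j, level_a = level)],
                  b[, .(ref, pos, i_b = i, j_b = j, level_b = level)],
                  by = c("ref", "pos"))
  if (nrow(shared) == 0) {
    warning("no shared sites between the two libraries")
    return(list(shared = shared, spearman = NA_real_, wilcoxon_p = NA_real_,
                n_shared = 0L, n_dms = 0L))
  }
  shared[, p_fisher := vapply(seq_len(.N), function(k)
    fisher.test(matrix(c(i_a[k], j_a[k] - i_a[k],
                         i_b[k], j_b[k] - i_b[k]), nrow = 2))$p.value,
    numeric(1))]
  shared[, q_fisher := p.adjust(p_fisher, method = "BH")]
  sp <- suppressWarnings(cor(shared$level_a, shared$level_b,
                             method = "spearman"))
  wp <- if (nrow(shared) >= 1)
    suppressWarnings(wilcox.test(shared$level_a, shared$level_b)$p.value)
  else NA_real_
  list(shared = shared[], spearman = sp, wilcoxon_p = wp,
       n_shared = nrow(shared), n_dms = sum(shared$q_fisher <= alpha))
}
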