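#' Group reads by mapping coordinate and UMI
#'
#' Reads (fragments, in paired mode: mates are treated as one template,
#' keyed by the read-1 start) that share reference, leftmost read-1 start,
#' conversion orientation and an identical UMI are considered PCR
#' amplicons of one molecule. Matching is exact: no edit-distance
#' clustering is applied, so UMI collisions merge and near-miss UMIs stay
#' separate.
#'
#' @param reads Aligned-read `data.table`; every read must carry a UMI
#'   (reads with a missing UMI are dropped with a warning).
#' @return A `umi_groups` list: `reads` (with `frag_id` and `group_id`),
#'   `fragments` (one row per template copy), `groups` (one row per UMI
#'   group with `depth`), and `n_missing_umi`.
#' @export
umi_group <- function(reads) {
  reads <- data.table::copy(validate_reads(reads))
  missing <- is.na(reads$umi) | !nzchar(reads$umi)
  n_missing <- sum(missing)
  if (n_missing > 0) {
    warning(n_missing, " reads without a UMI were dropped")
    reads <- reads[!missing]
  }
  # fragment = all mates sharing a read name
  anchor <- reads[, .(ref = ref[1],
                      start = if (any(mate != "R2")) min(start[mate != "R2"])
                              else min(start),
                      orientation = orientation[which(mate != "R2")[1]] %||% "C2T",
                      umi = umi[1]), by = qname]
  anchor[is.na(orientation), orientation := "C2T"]
  anchor[, frag_id := .I]
  anchor[, group_id := .GRP, by = .(ref, start, orientation, umi)]
  reads[anchor, `:=`(frag_id = i.frag_id, group_id = i.group_id),
        on = "qname"]
  groups <- anchor[, .(ref = ref[1], start = start[1], umi = umi[1],
                       orientation = orientation[1], depth = .N),
                   by = group_id]
  structure(list(reads = reads[], fragments = anchor[], groups = groups[],
                 n_missing_umi = n_missing),
            class = "umi_groups")
}

#' Deduplicate UMI groups, retaining the most prevalent sequence
#'
#' Within each UMI group the most prevalent member sequence (read 1 plus
#' read 2 concatenated for paired fragments) is retained for methylation
#' calling. Ties are broken by the higher summed base quality, then by the
#' lexicographically smaller sequence.
#'
#' @param groups A `umi_groups` object from [umi_group()].
#' @return `list(reads, duplication_rate, n_fragments, n_groups)`; `reads`
#'   holds every mate of the retained fragment per group;
#'   `duplication_rate = 1 - n_groups / n_fragments`.
#' @export
umi_dedup <- function(groups) {
  stopifnot(inherits(groups, "umi_groups"))
  reads <- groups$reads
  frag <- reads[, .(fseq = paste(seq[order(mate)], collapse = "|"),
                    qual_sum = sum(unlist(phred_decode(qual))),
                    group_id = group_id[1]), by = frag_id]
  frag[, prevalence := .N, by = .(group_id, fseq)]
  data.table::setorder(frag, group_id, -prevalence, -qual_sum, fseq, frag_id)
  winners <- frag[, .(frag_id = frag_id[1]), by = group_id]
  kept <- reads[frag_id %in% winners$frag_id]
  n_frag <- nrow(groups$fragments)
  n_grp <- nrow(groups$groups)
  list(reads = kept[], duplication_rate = 1 - n_grp / n_frag,
       n_fragments = n_frag, n_groups = n_grp)
}

#' Within-UMI-group discordance statistics
#'
#' Compares member reads of each UMI group base by base over the reference
#' span covered by every member (depth-1 groups count as concordant). A
#' position is discordant when members report more than one nucleotide
#' there; a group is attributed to nucleotide class N when N appears among
#' the observed bases of at least one of its discordant positions (so a
#' C/T mismatch increments both the C and the T class). For discordant
#' positions at which at least one member reports the candidate base
#' (`"C"` in C-to-T space), the full nucleotide frequency vector across
#' member reads is accumulated.
#'
#' @param groups A `umi_groups` object.
#' @param candidate_base Candidate base in the library's conversion space.
#' @param refs Optional reference IDs to restrict the analysis to (e.g.
#'   spike-in controls, as when estimating PCR error from ERCC reads).
#' @return A `discordance_report` list: `n_groups`, `n_discordant`,
#'   `discordance_ratio`, `per_nucleotide` (class ratios),
#'   `depth_histogram`, and `candidate_base_freq` (A/C/G/T counts at
#'   discordant candidate positions).
#' @export
umi_discordance <- function(groups, candidate_base = "C", refs = NULL) {
  stopifnot(inherits(groups, "umi_groups"))
  reads <- groups$reads
  grp <- groups$groups
  if (!is.null(refs)) {
    reads <- reads[ref %in% refs]
    grp <- grp[ref %in% refs]
  }
  n_groups <- nrow(grp)
  depth_hist <- grp[, .N, by = depth][order(depth)]
  empty_freq <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
  if (n_groups == 0) {
    return(structure(list(n_groups = 0L, n_discordant = 0L,
                          discordance_ratio = NA_real_,
                          per_nucleotide = setNames(rep(NA_real_, 4),
                                                    c("A", "C", "G", "T")),
                          depth_histogram = depth_hist,
                          candidate_base_freq = empty_freq),
                     class = "discordance_report"))
  }
  multi <- grp[depth >= 2, group_id]
  per_nt_groups <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
  cand_freq <- empty_freq
  n_disc <- 0L
  if (length(multi) > 0) {
    sub <- reads[group_id %in% multi]
    data.table::setorder(sub, group_id, frag_id, mate)
    bl <- expand_bases(sub, min_base_q = 0,
                       extra_cols = c("group_id", "frag_id"))
    # one base per fragment and position: higher quality wins (tie: read 1)
    bl <- bl[, .(base = base[which.max(q)]), by = .(group_id, frag_id, pos)]
    depth_by_group <- groups$fragments[group_id %in% multi,
                                       .(gdepth = .N), by = group_id]
    pos_stat <- bl[, .(n_cov = .N, n_base = data.table::uniqueN(base)),
                   by = .(group_id, pos)]
    pos_stat <- pos_stat[depth_by_group, on = "group_id"]
    disc_pos <- pos_stat[n_cov == gdepth & n_base > 1, .(group_id, pos)]
    if (nrow(disc_pos) > 0) {
      disc_bases <- bl[disc_pos, on = c("group_id", "pos")]
      n_disc <- data.table::uniqueN(disc_pos$group_id)
      cls <- unique(disc_bases[, .(group_id, base)])
      tab <- cls[, .(n = .N), by = base]
      per_nt_groups[tab$base] <- tab$n
      cand_pos <- disc_bases[, .(has_cand = any(base == candidate_base)),
                             by = .(group_id, pos)][has_cand == TRUE]
      if (nrow(cand_pos) > 0) {
        cb <- disc_bases[cand_pos[, .(group_id, pos)], on = c("group_id", "pos")]
        tb <- table(factor(cb$base, levels = c("A", "C", "G", "T")))
        cand_freq <- setNames(as.integer(tb), names(tb))
      }
    }
  }
  structure(list(n_groups = n_groups, n_discordant = n_disc,
                 discordance_ratio = n_disc / n_groups,
                 per_nucleotide = per_nt_groups / n_groups,
                 depth_histogram = depth_hist,
                 candidate_base_freq = cand_freq),
            class = "discordance_report")
}
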