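#' Filter cascade configuration
#'
#' Thresholds of the multi-level high-confidence filter: the standard
#' filter (candidate count, coverage, level), the Gini threshold and scan
#' range for the read C-cutoff, the signal/noise minimum, the FDR level,
#' optional conversion-resistant regions, and the replicate-concordance
#' rule.
#'
#' @param min_i Minimum candidate (unconverted C) count per site.
#' @param min_j Minimum (C+T) coverage per site.
#' @param min_level Minimum methylation level `i/j`.
#' @param gini_threshold Gini coefficient at or below which a C-cutoff is
#'   accepted.
#' @param c_cutoff_range Ascending integer candidates for the read
#'   C-cutoff scan.
#' @param sn_min Minimum signal/noise ratio (post- over pre-cutoff
#'   candidate count).
#' @param fdr_alpha BH-adjusted p-value threshold.
#' @param resistant_regions Optional `data.table(ref, start, end)` of
#'   half-open conversion-resistant intervals to exclude.
#' @param replicate_min_count Minimum candidate count required in another
#'   replicate.
#' @param replicate_min_cov Minimum coverage required in another
#'   replicate.
#' @param min_start_cov Coverage of the 10x starting set the attrition
#'   report is anchored to.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_i = 3L, min_j = 20L, min_level = 0.1,
                          gini_threshold = 0.15, c_cutoff_range = 1:30,
                          sn_min = 0.9, fdr_alpha = 0.05,
                          resistant_regions = NULL,
                          replicate_min_count = 1L, replicate_min_cov = 10L,
                          min_start_cov = 10L) {
  if (length(c_cutoff_range) == 0 || is.unsorted(c_cutoff_range))
    stop("c_cutoff_range must be non-empty and ascending")
  if (min_i <= 0 || min_j <= 0 || min_level <= 0)
    stop("standard-filter thresholds must be positive")
  structure(list(min_i = as.integer(min_i), min_j = as.integer(min_j),
                 min_level = min_level, gini_threshold = gini_threshold,
                 c_cutoff_range = as.integer(c_cutoff_range),
                 sn_min = sn_min, fdr_alpha = fdr_alpha,
                 resistant_regions = resistant_regions,
                 replicate_min_count = as.integer(replicate_min_count),
                 replicate_min_cov = as.integer(replicate_min_cov),
                 min_start_cov = as.integer(min_start_cov)),
            class = "filter_config")
}

#' Standard site filter
#'
#' Passes a site iff `i >= min_i`, `j >= min_j` and `i/j >= min_level`
#' (all boundaries inclusive; defaults 3, 20 and 0.1).
#'
#' @param sites Site `data.table` from [call_sites()].
#' @param cfg A [filter_config()].
#' @return The sites that pass, with a logical `pass_standard` column
#'   added to a copy of the input when `flag_only = TRUE`.
#' @param flag_only Return all sites flagged rather than the passing
#'   subset.
#' @export
standard_filter <- function(sites, cfg = filter_config(), flag_only = FALSE) {
  sites <- data.table::as.data.table(sites)
  pass <- sites$i >= cfg$min_i & sites$j >= cfg$min_j &
    sites$level >= cfg$min_level
  if (flag_only) {
    out <- data.table::copy(sites)
    out[, passes := pass]
    return(out[])
  }
  sites[pass]
}

#' Gini coefficient of positive counts
#'
#' Population pairwise form
#' `G = sum_ab |x_a - x_b| / (2 n^2 mean(x))`, computed via the sorted
#' identity; 0 for perfect equality, approaching 1 as counts concentrate
#' on a single gene.
#'
#' @param values Positive counts (e.g. candidate sites per gene).
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(values) {
  if (length(values) == 0) stop("gini() needs at least one value")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("gini() requires positive finite values")
  n <- length(values)
  x <- sort(values)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Scan read C-cutoffs and choose one by the Gini criterion
#'
#' For each candidate cutoff `k`, drops fragments whose unconverted-C
#' content exceeds `k`, re-calls sites on the retained reads, and computes
#' the Gini coefficient of candidate-sites-per-gene (sites with `i >= 1`
#' on annotated genes). The chosen cutoff is the largest `k` whose Gini
#' is at or below `gini_threshold` — the least stringent cutoff keeping
#' candidate sites acceptably even across genes, so as few reads as
#' possible are discarded (stricter cutoffs remove the C-laden reads that
#' concentrate artifact sites, lowering the Gini); if no cutoff qualifies
#' the maximum of the range is used with a warning. Retained read sets
#' are nested in `k`.
#'
#' @param reads Deduplicated aligned-read `data.table`.
#' @param reference `bs_reference` or named [Biostrings::DNAStringSet].
#' @param annotation Annotation table mapping `seqname` to `gene_id`
#'   (exon rows are used).
#' @param cfg A [filter_config()].
#' @param min_base_q,min_cov Calling parameters used during the scan.
#' @param error_rate Conversion-failure rate for the re-call.
#' @return A `cutoff_scan` list: `scan`
#'   (`data.table(cutoff, gini_sites, n_genes, n_sites, n_reads)`),
#'   `chosen_k`, and `c_content` (per-fragment counts).
#' @export
select_c_cutoff <- function(reads, reference, annotation,
                            cfg = filter_config(), min_base_q = 30,
                            min_cov = 10, error_rate = 0.001) {
  reads <- validate_reads(reads)
  cc <- read_c_content(reads, reference)
  gene_of <- unique(annotation[annotation$feature == "exon",
                               c("seqname", "gene_id")])
  # expand once; per cutoff the retained fragment set is nested, so sites
  # can be aggregated from one base table with call_sites() semantics
  seqs <- if (inherits(reference, "bs_reference")) reference$sequences
          else reference
  cdt <- reference_c_positions(seqs)
  bl <- expand_bases(reads)
  bl <- bl[cdt, on = c("ref", "pos"), nomatch = NULL]
  bl <- collapse_mate_overlap(bl)
  bl <- bl[q >= min_base_q]
  bl[cc, c_content := i.c_content, on = "qname"]
  rows <- lapply(cfg$c_cutoff_range, function(k) {
    sub <- bl[c_content <= k]
    sites <- sub[, .(i = sum(base == "C"),
                     j = sum(base == "C") + sum(base == "T")),
                 by = .(ref, pos)][j >= min_cov]
    cand <- sites[i >= 1]
    cand <- merge(cand, gene_of, by.x = "ref", by.y = "seqname")
    per_gene <- cand[, .N, by = gene_id]
    g <- if (nrow(per_gene) > 0) gini(per_gene$N) else NA_real_
    data.table::data.table(cutoff = k, gini_sites = g,
                           n_genes = nrow(per_gene), n_sites = nrow(cand),
                           n_reads = sum(cc$c_content <= k))
  })
  scan <- data.table::rbindlist(rows)
  if (all(is.na(scan$gini_sites)))
    stop("no genes with candidate sites at any C-cutoff")
  ok <- which(!is.na(scan$gini_sites) &
                scan$gini_sites <= cfg$gini_threshold)
  if (length(ok) > 0) {
    chosen <- scan$cutoff[ok[length(ok)]]
  } else {
    chosen <- max(cfg$c_cutoff_range)
    warning("no C-cutoff reached Gini <= ", cfg$gini_threshold,
            "; using maximum of range (", chosen, ")")
  }
  structure(list(scan = scan[], chosen_k = chosen, c_content = cc),
            class = "cutoff_scan")
}

#' Signal/noise ratio of sites before and after the C-cutoff
#'
#' For each site, the candidate count after the C-cutoff divided by the
#' count before (`after.i / before.i`; defined as 0 when `before.i` is 0).
#' Sites supported mainly by poorly converted reads collapse towards 0
#' and are removed below `sn_min`.
#'
#' @param before,after Site tables for the same library called before and
#'   after applying the read C-cutoff.
#' @param sn_min Retention threshold (retain iff ratio `>= sn_min`).
#' @return The `after` table joined with `i_before` and `sn_ratio`, plus
#'   a logical `retained` column.
#' @export
signal_noise <- function(before, after, sn_min = 0.9) {
  b <- data.table::as.data.table(before)[, .(ref, pos, i_before = i)]
  a <- data.table::copy(data.table::as.data.table(after))
  out <- merge(a, b, by = c("ref", "pos"), all.x = TRUE)
  if (any(is.na(out$i_before)))
    stop("sites present after the C-cutoff but absent before it")
  if (any(out$i > out$i_before))
    stop("candidate count increased after the C-cutoff")
  out[, sn_ratio := ifelse(i_before > 0, i / i_before, 0)]
  out[, retained := sn_ratio >= sn_min]
  out[]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values with enforced monotonicity (via
#' [stats::p.adjust()]); a site passes at `q <= alpha`.
#'
#' @param p_values P-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return `list(q_values, pass)`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, pass = q <= alpha)
}

#' Remove sites inside conversion-resistant regions
#'
#' Regions are half-open `[start, end)` intervals per reference (as
#' predicted upstream from RNA secondary structure, e.g. by RNAfold, and
#' supplied as BED-style input); a site is removed iff
#' `start <= pos < end` on the same reference.
#'
#' @param sites Site `data.table`.
#' @param regions `data.table(ref, start, end)`; `NULL` or empty is the
#'   identity.
#' @return Sites outside every region.
#' @export
region_filter <- function(sites, regions) {
  sites <- data.table::as.data.table(sites)
  if (is.null(regions) || nrow(regions) == 0) return(sites)
  regions <- data.table::as.data.table(regions)
  if (any(regions$end <= regions$start))
    stop("malformed region interval (end <= start)")
  hit <- rep(FALSE, nrow(sites))
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (sites$ref == regions$ref[r] &
                    sites$pos >= regions$start[r] &
                    sites$pos < regions$end[r])
  }
  sites[!hit]
}

#' Replicate concordance for high-confidence sites
#'
#' A site enters the high-confidence set iff it passes every filter in at
#' least one replicate and, in at least one other replicate, shows
#' `i >= replicate_min_count` and `j >= replicate_min_cov` after that
#' replicate's own C-cutoff.
#'
#' @param replicate_results Named list (length >= 2), one element per
#'   replicate, each a list with `passed` (sites passing all filters) and
#'   `post_cutoff` (that replicate's full post-C-cutoff site table).
#' @param cfg A [filter_config()].
#' @return The high-confidence site `data.table` with a
#'   `supporting_replicate` column.
#' @export
replicate_concordance <- function(replicate_results, cfg = filter_config()) {
  if (length(replicate_results) < 2)
    stop("replicate concordance requires at least two replicates")
  nms <- names(replicate_results) %||% paste0("rep", seq_along(replicate_results))
  out <- list()
  for (a in seq_along(replicate_results)) {
    passed <- data.table::as.data.table(replicate_results[[a]]$passed)
    if (nrow(passed) == 0) next
    support <- rep(FALSE, nrow(passed))
    supporter <- rep(NA_character_, nrow(passed))
    for (b in seq_along(replicate_results)) {
      if (b == a) next
      pc <- data.table::as.data.table(replicate_results[[b]]$post_cutoff)
      okb <- pc[i >= cfg$replicate_min_count & j >= cfg$replicate_min_cov,
                .(ref, pos)]
      hit <- paste(passed$ref, passed$pos) %in% paste(okb$ref, okb$pos)
      supporter[hit & !support] <- nms[b]
      support <- support | hit
    }
    keep <- passed[support]
    if (nrow(keep) > 0) {
      keep[, `:=`(replicate = nms[a],
                  supporting_replicate = supporter[support])]
      out[[length(out) + 1L]] <- keep
    }
  }
  if (length(out) == 0) {
    return(data.table::data.table(ref = character(), pos = integer()))
  }
  hc <- data.table::rbindlist(out, fill = TRUE)
  # one row per site: first replicate in which it passed everything
  unique(hc, by = c("ref", "pos"))
}

#' Stage-wise site attrition report
#'
#' Percentage of sites remaining after each filter stage, anchored to
#' 100 percent at the first (10x-coverage) stage; monotone non-increasing
#' by construction of the cascade.
#'
#' @param stage_sets Named ordered list of site tables (or counts).
#' @return `data.table(stage, n_sites, pct_remaining)`.
#' @export
attrition_report <- function(stage_sets) {
  ns <- vapply(stage_sets, function(s)
    if (is.numeric(s) && length(s) == 1) as.integer(s) else nrow(s),
    integer(1))
  base <- if (length(ns) > 0 && ns[1] > 0) ns[1] else NA_integer_
  data.table::data.table(stage = names(stage_sets) %||% seq_along(ns),
                         n_sites = ns,
                         pct_remaining = if (is.na(base)) rep(NA_real_, length(ns))
                                         else 100 * ns / base)
}

#' Run the per-library multi-level filter cascade
#'
#' Order: 10x starting set, standard filter, read C-cutoff (Gini-selected)
#' with signal/noise, structure-region exclusion, binomial test with
#' BH-FDR. Returns every intermediate set for the attrition report plus
#' the post-cutoff site table used by the replicate rule.
#'
#' @param reads Deduplicated aligned-read `data.table`.
#' @param reference `bs_reference` or named [Biostrings::DNAStringSet].
#' @param annotation Annotation table (exon rows map transcripts to
#'   genes).
#' @param cfg A [filter_config()].
#' @param min_base_q Q30 gate used at calling.
#' @param error_rate Conversion-failure rate (1 - spike-in conversion
#'   rate).
#' @return A `filter_cascade` list: `stages` (named site tables),
#'   `passed` (sites surviving all per-library filters), `post_cutoff`
#'   (full site table after the C-cutoff), `cutoff` (the scan object) and
#'   `attrition`.
#' @export
filter_cascade <- function(reads, reference, annotation,
                           cfg = filter_config(), min_base_q = 30,
                           error_rate = 0.001) {
  reads <- validate_reads(reads)
  start_set <- call_sites(reads, reference, min_base_q = min_base_q,
                          min_cov = cfg$min_start_cov,
                          error_rate = error_rate)
  std <- standard_filter(start_set, cfg)
  scan <- select_c_cutoff(reads, reference, annotation, cfg,
                          min_base_q = min_base_q,
                          min_cov = cfg$min_start_cov,
                          error_rate = error_rate)
  keep_frag <- scan$c_content$qname[scan$c_content$c_content <= scan$chosen_k]
  post_reads <- reads[qname %in% keep_frag]
  post_cutoff <- call_sites(post_reads, reference, min_base_q = min_base_q,
                            min_cov = 1L, error_rate = error_rate)
  sn <- signal_noise(before = start_set,
                     after = post_cutoff[paste(ref, pos) %in%
                                           paste(std$ref, std$pos)],
                     sn_min = cfg$sn_min)
  after_cut <- sn[retained == TRUE]
  # standard thresholds re-checked on post-cutoff counts
  after_cut <- standard_filter(after_cut, cfg)
  after_region <- region_filter(after_cut, cfg$resistant_regions)
  if (nrow(after_region) > 0) {
    fdr <- bh_fdr(after_region$p_value, cfg$fdr_alpha)
    after_region[, q_value := fdr$q_values]
    passed <- after_region[fdr$pass]
  } else {
    after_region[, q_value := numeric(0)]
    passed <- after_region
  }
  stages <- list(coverage10x = start_set, standard = std,
                 c_cutoff_sn = after_cut, structure_regions = after_region,
                 fdr = passed)
  structure(list(stages = stages, passed = passed,
                 post_cutoff = post_cutoff, cutoff = scan,
                 attrition = attrition_report(stages)),
            class = "filter_cascade")
}
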