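mk_sites <- function(i, j, ref = "TXA", pos = seq_along(i) * 10L,
                     p_value = 0.01) {
  data.table::data.table(ref = ref, pos = pos, pos1 = pos + 1L, strand = "+",
                         i = as.integer(i), j = as.integer(j),
                         level = i / j, p_value = p_value, n_other = 0L)
}

test_that("standard filter boundaries are inclusive", {
  s <- mk_sites(i = c(3L, 2L, 3L), j = c(20L, 20L, 40L))
  out <- standard_filter(s)
  # (3, 20, 0.15) passes; (2, 20) fails on count; (3, 40, 0.075) on level
  expect_equal(out$pos, 10L)
  flagged <- standard_filter(s, flag_only = TRUE)
  expect_equal(flagged$passes, c(TRUE, FALSE, FALSE))
})

test_that("gini matches hand-computed values and is scale invariant", {
  expect_equal(gini(c(5, 5, 5, 5)), 0)
  expect_equal(gini(c(1, 3)), 0.25)  # 4 / (2 * 4 * 2) by pairwise sums
  x <- c(2, 7, 1, 9, 4)
  expect_equal(gini(10 * x), gini(x), tolerance = 1e-12)
  expect_error(gini(numeric(0)), "at least one")
  expect_error(gini(c(1, 0)), "positive")
})

test_that("BH adjustment matches the hand step-up procedure", {
  expect_equal(bh_fdr(0.03)$q_values, 0.03)
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q_values, rep(0.04, 4))
  all1 <- bh_fdr(rep(1, 5))
  expect_equal(all1$q_values, rep(1, 5))
  expect_false(any(all1$pass))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("region filtering uses half-open intervals", {
  s <- mk_sites(i = c(5L, 5L), j = c(20L, 20L), pos = c(100L, 110L))
  regions <- data.table::data.table(ref = "TXA", start = 90L, end = 110L)
  out <- region_filter(s, regions)
  expect_equal(out$pos, 110L)  # end-exclusive boundary kept
  expect_equal(nrow(region_filter(s, NULL)), 2L)
  bad <- data.table::data.table(ref = "TXA", start = 100L, end = 100L)
  expect_error(region_filter(s, bad), "malformed")
})

test_that("signal/noise ratios behave at the boundaries", {
  before <- mk_sites(i = c(10L, 10L, 0L), j = c(20L, 20L, 20L))
  after <- mk_sites(i = c(10L, 5L, 0L), j = c(18L, 15L, 20L))
  out <- signal_noise(before, after, sn_min = 0.9)
  expect_equal(out$sn_ratio, c(1.0, 0.5, 0))
  expect_equal(out$retained, c(TRUE, FALSE, FALSE))
  expect_true(all(out$sn_ratio <= 1))
  worse <- mk_sites(i = 12L, j = 20L, pos = 10L)
  expect_error(signal_noise(before[1], worse), "increased")
})

test_that("read C content counts retained candidate bases", {
  ref5 <- Biostrings::DNAStringSet(c(TXA = "CTCTCTCTCT"))  # Cs at 0,2,4,6,8
  conv <- mk_reads("TTTTTTTTTT", qname = "conv")
  part <- mk_reads("CTCTTTTTTT", qname = "part")
  cc <- read_c_content(rbind(conv, part), ref5)
  expect_equal(cc[qname == "conv", c_content], 0L)
  expect_equal(cc[qname == "part", c_content], 2L)
})

test_that("resistant reads carry their full cytosine load", {
  # oracle: simulator truth flags; error-free so no stray conversions
  cfg <- tiny_config(seed = 41, resistant_read_fraction = 0.3,
                     seq_error_rate = 0, pcr_error_rate = 0, n_true_sites = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_reads(ref, plant_methylation(ref, cfg), cfg)
  cc <- read_c_content(sim$reads, ref)
  rt <- merge(cc, sim$read_truth[, .(qname = read_id, is_resistant)],
              by = "qname")
  expect_gt(min(rt[is_resistant == TRUE, c_content]), 10L)
  expect_lte(max(rt[is_resistant == FALSE, c_content]), 3L)
})

test_that("the C-cutoff scan is flat when no read exceeds one candidate", {
  cfg <- tiny_config(seed = 42, resistant_read_fraction = 0,
                     conversion_rate = 1.0, seq_error_rate = 0,
                     pcr_error_rate = 0, n_true_sites = 3,
                     level_distribution = function(n) rep(1, n))
  ref <- generate_reference(cfg)
  tr <- plant_methylation(ref, cfg)
  sim <- simulate_reads(ref, tr, cfg)
  sc <- select_c_cutoff(sim$reads, ref, ref$annotation,
                        filter_config(c_cutoff_range = 1:6))
  expect_equal(data.table::uniqueN(sc$scan$gini_sites), 1L)
  expect_equal(data.table::uniqueN(sc$scan$n_sites), 1L)
})

test_that("concentrated resistance inflates the uncut Gini", {
  # resistant molecules restricted to two transcripts; oracle = direct
  # recomputation of the per-gene Gini with and without those reads
  cfg <- tiny_config(seed = 43, n_transcripts = 6, n_control_transcripts = 0,
                     resistant_read_fraction = 0.5,
                     gc_content = 0.3, fragment_length = c(60L, 90L),
                     read_length = 60L, n_true_sites = 0)
  ref <- generate_reference(cfg)
  cfg$resistant_transcripts <- names(ref$sequences)[1:2]
  sim <- simulate_reads(ref, plant_methylation(ref, cfg), cfg)
  gene_of <- unique(ref$annotation[feature == "exon", .(seqname, gene_id)])
  gini_at <- function(reads) {
    s <- call_sites(reads, ref, min_base_q = 30, min_cov = 10)[i >= 1]
    per_gene <- merge(s, gene_of, by.x = "ref",
                      by.y = "seqname")[, .N, by = gene_id]
    gini(per_gene$N)
  }
  cc <- read_c_content(sim$reads, ref)
  g_uncut <- gini_at(sim$reads)  # k = infinity: resistant reads included
  g_k3 <- gini_at(sim$reads[qname %in% cc[c_content <= 3, qname]])
  expect_gt(g_uncut, g_k3)
})

test_that("retained read sets are nested across cutoffs", {
  ds <- tiny_dataset()
  cc <- read_c_content(ds$reads, ds$reference)
  sets <- lapply(c(1L, 3L, 10L), function(k) cc[c_content <= k, qname])
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("replicate concordance applies the cross-replicate rule", {
  passed1 <- mk_sites(i = 10L, j = 30L, pos = 100L)
  mk_rep <- function(passed, post) list(passed = passed, post_cutoff = post)
  # supported: other replicate has i >= 1 and j >= 10 after its cutoff
  reps <- list(rep1 = mk_rep(passed1, mk_sites(i = 10L, j = 30L, pos = 100L)),
               rep2 = mk_rep(passed1[0], mk_sites(i = 1L, j = 10L, pos = 100L)))
  hc <- replicate_concordance(reps)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$supporting_replicate, "rep2")

  # unsupported: i = 0 in the other replicate despite deep coverage
  reps$rep2$post_cutoff <- mk_sites(i = 0L, j = 50L, pos = 100L)
  expect_equal(nrow(replicate_concordance(reps)), 0L)

  # passing in both replicates is also enough
  reps$rep2 <- mk_rep(passed1, mk_sites(i = 10L, j = 30L, pos = 100L))
  expect_equal(nrow(replicate_concordance(reps)), 1L)

  expect_error(replicate_concordance(reps[1]), "two replicates")
})

test_that("attrition percentages are anchored and monotone", {
  sets <- list(start = mk_sites(rep(5L, 200), rep(20L, 200),
                                pos = seq_len(200) * 3L))
  sets$standard <- sets$start[1:100]
  sets$cutoff <- sets$start[1:10]
  sets$fdr <- sets$start[1:10]
  rep_ <- attrition_report(sets)
  expect_equal(rep_$pct_remaining, c(100, 50, 5, 5))
  same <- attrition_report(list(a = sets$start, b = sets$start))
  expect_equal(same$pct_remaining, c(100, 100))
})

test_that("the cascade is a pure set reduction in the stated order", {
  ds <- tiny_dataset()
  reads <- umi_dedup(umi_group(qc_pipeline(ds$reads)$reads))$reads
  cas <- suppressWarnings(
    filter_cascade(reads, ds$reference, ds$reference$annotation,
                   filter_config(c_cutoff_range = 1:12)))
  keys <- lapply(cas$stages, function(s) paste(s$ref, s$pos))
  for (k in seq_along(keys)[-1])
    expect_true(all(keys[[k]] %in% keys[[k - 1]]),
                label = names(keys)[k])
  expect_true(all(diff(cas$attrition$pct_remaining) <= 1e-9))
})

test_that("artifact sites on unmethylated controls never survive the cascade", {
  # controls carry no planted sites; standard + C-cutoff must clear them
  ds <- tiny_dataset()
  reads <- umi_dedup(umi_group(qc_pipeline(ds$reads)$reads))$reads
  cas <- suppressWarnings(
    filter_cascade(reads, ds$reference, ds$reference$annotation))
  ctrl <- ds$reference$control_ids
  expect_equal(nrow(cas$stages$c_cutoff_sn[ref %in% ctrl]), 0L)
  expect_equal(nrow(cas$passed[ref %in% ctrl]), 0L)
})
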