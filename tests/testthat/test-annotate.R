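# A two-transcript annotation on one reference sequence, hand-built:
# TXA: 5'UTR 1-100, CDS 101-700, 3'UTR 701-800 (gene GA)
# TXB: 5'UTR 1-100, CDS 101-400, 3'UTR 401-500 (gene GB) - shorter CDS
mk_ann <- function() {
  data.table::rbindlist(list(
    data.table::data.table(seqname = "CHR", source = "t", feature = "exon",
                           start = 1L, end = 800L, strand = "+",
                           gene_id = "GA", transcript_id = "TXA"),
    data.table::data.table(seqname = "CHR", source = "t",
                           feature = "five_prime_utr", start = 1L, end = 100L,
                           strand = "+", gene_id = "GA", transcript_id = "TXA"),
    data.table::data.table(seqname = "CHR", source = "t", feature = "CDS",
                           start = 101L, end = 700L, strand = "+",
                           gene_id = "GA", transcript_id = "TXA"),
    data.table::data.table(seqname = "CHR", source = "t",
                           feature = "three_prime_utr", start = 701L,
                           end = 800L, strand = "+", gene_id = "GA",
                           transcript_id = "TXA"),
    data.table::data.table(seqname = "CHR", source = "t", feature = "exon",
                           start = 1L, end = 500L, strand = "+",
                           gene_id = "GB", transcript_id = "TXB"),
    data.table::data.table(seqname = "CHR", source = "t", feature = "CDS",
                           start = 101L, end = 400L, strand = "+",
                           gene_id = "GB", transcript_id = "TXB")))
}

site_at <- function(pos0, ref = "CHR") {
  data.table::data.table(ref = ref, pos = as.integer(pos0),
                         pos1 = as.integer(pos0) + 1L, strand = "+",
                         i = 5L, j = 20L, level = 0.25, p_value = 0.01,
                         n_other = 0L)
}

test_that("sites are labeled by feature with longest-CDS tie-break", {
  ann <- mk_ann()
  cds_site <- annotate_sites(site_at(200), ann)   # in both CDS intervals
  expect_equal(cds_site$gene_id, "GA")            # TXA has the longer CDS
  expect_equal(cds_site$feature_class, "CDS")
  expect_equal(cds_site$gene_ids_all, "GA,GB")

  utr5 <- annotate_sites(site_at(50), ann)
  expect_equal(utr5$feature_class, "5'UTR")
  utr3 <- annotate_sites(site_at(750), ann)
  expect_equal(utr3$feature_class, "3'UTR")

  nowhere <- annotate_sites(site_at(100, ref = "OTHER"), ann)
  expect_equal(nowhere$feature_class, "intergenic")
  expect_true(is.na(nowhere$gene_id))

  no_exon <- ann[feature != "exon"]
  expect_error(annotate_sites(site_at(200), no_exon), "exon")
})

test_that("annotation appends columns without mutating site rows", {
  s <- site_at(c(50, 200, 750))
  before <- data.table::copy(s)
  out <- annotate_sites(s, mk_ann())
  expect_identical(s, before)
  expect_identical(out[, names(before), with = FALSE], before)
})

test_that("metagene bins map region extremes and midpoints correctly", {
  ann <- mk_ann()[transcript_id == "TXA"]
  mg1 <- metagene(site_at(0), ann)      # first base of the 5'UTR
  expect_equal(mg1$density[bin == 1, count], 1L)
  mg20 <- metagene(site_at(799), ann)   # last base of the 3'UTR
  expect_equal(mg20$density[bin == 20, count], 1L)

  # CDS midpoint: p1 = 400, frac = (400-101)/600 = 0.498..., bin 6 + 5 = 11
  mid <- metagene(site_at(399), ann)
  expect_equal(mid$density[bin == 11, count], 1L)

  many <- metagene(site_at(c(0, 399, 799)), ann)
  expect_equal(sum(many$density$density), 1, tolerance = 1e-12)
  expect_true(all(many$density$bin %in% 1:20))

  # transcript lacking a UTR: site skipped and counted
  mg_skip <- metagene(site_at(200), mk_ann()[transcript_id == "TXB"])
  expect_equal(mg_skip$n_skipped, 1L)
})

test_that("motif matrices are one-hot for a single site", {
  refm <- Biostrings::DNAStringSet(c(M = "AAAATTTTGGCAGGGTTTTCCCC"))
  # site at 0-based pos 10 (the first C), flank 3: window "TTGGCAG" -> "GGCAGGG"
  s <- site_at(10, ref = "M")
  mm <- motif_matrix(s, refm, flank = 3)
  expect_equal(unname(mm$matrix["0", "C"]), 1)
  expect_equal(unname(mm$matrix["-1", "G"]), 1)
  expect_equal(unname(mm$matrix["1", "A"]), 1)
  expect_equal(unname(mm$matrix["2", "G"]), 1)
  expect_equal(mm$n_used, 1L)

  # flank outside the sequence: pad-skip
  edge <- motif_matrix(site_at(1, ref = "M"), refm, flank = 3)
  expect_equal(edge$n_skipped, 1L)
})

test_that("a planted downstream GGG context saturates the motif score", {
  # sites planted only in NNCGGG context
  unit <- "ATCGGGTTTA"
  refg <- Biostrings::DNAStringSet(c(G = strrep(unit, 30)))
  pos <- seq(2, by = 10, length.out = 28)  # every C, 0-based
  s <- site_at(pos, ref = "G")
  mm <- motif_matrix(s, refg, flank = 5)
  expect_equal(unname(mm$matrix["1", "G"]), 1)
  expect_equal(unname(mm$matrix["2", "G"]), 1)
  expect_equal(unname(mm$matrix["3", "G"]), 1)
  expect_equal(unname(mm$matrix["0", "C"]), 1)
  expect_gt(mm$ggg_score, 3)
})

test_that("CPM normalisation and unique-gene assignment", {
  ann <- mk_ann()
  # 10 fragments on gene GB's private span (501-800 is GA-only; 1-500 shared)
  shared <- mk_reads(rep(strrep("A", 50), 4), ref = "CHR", start = 100L,
                     qname = sprintf("s%d", 1:4))
  ga_only <- mk_reads(rep(strrep("A", 50), 10), ref = "CHR", start = 600L,
                      qname = sprintf("g%d", 1:10))
  out <- gene_cpm(rbind(shared, ga_only), ann)
  # shared fragments overlap both genes and are unassigned
  expect_equal(out[gene_id == "GA", count], 10L)
  expect_equal(out[gene_id == "GB", count], 0L)
  expect_equal(sum(out$cpm), 1e6)

  one <- gene_cpm(ga_only[1], ann)
  expect_equal(one[gene_id == "GA", cpm], 1e6)
})

test_that("uniform duplication cancels in CPM but halves counts", {
  ann <- mk_ann()
  base <- mk_reads(rep(strrep("A", 50), 6), ref = "CHR",
                   start = c(600L, 620L, 640L, 660L, 680L, 700L),
                   qname = sprintf("b%d", 1:6))
  dup <- data.table::copy(base)[, qname := paste0(qname, "_dup")]
  cmp <- compare_cpm(rbind(base, dup), base, ann)
  ga <- cmp[gene_id == "GA"]
  expect_equal(ga$count_raw, 12L)
  expect_equal(ga$count_dedup, 6L)
  expect_equal(ga$log2fc, 0)  # uniform duplication cancels in CPM
})

test_that("library comparison reports identity and disjointness correctly", {
  a <- site_at(c(10, 20, 30))
  a$i <- c(4L, 10L, 16L)
  a$level <- a$i / a$j
  ident <- compare_libraries(a, a)
  expect_equal(ident$spearman, 1)
  expect_equal(ident$shared$p_fisher, rep(1, 3), tolerance = 1e-9)
  expect_equal(ident$n_dms, 0L)

  b <- site_at(c(100, 200))
  expect_warning(disj <- compare_libraries(a, b), "no shared sites")
  expect_equal(disj$n_shared, 0L)
})

test_that("Fisher DMS p-values match exact hypergeometric summation", {
  # oracle: sum of hypergeometric point masses no larger than the observed
  fisher_brute <- function(i_a, j_a, i_b, j_b) {
    m <- i_a + i_b; n <- (j_a - i_a) + (j_b - i_b); k <- j_a
    supp <- max(0, k - n):min(m, k)
    probs <- dhyper(supp, m, n, k)
    sum(probs[probs <= dhyper(i_a, m, n, k) * (1 + 1e-7)])
  }
  a <- site_at(10); b <- site_at(10)
  a$i <- 10L; a$j <- 20L; b$i <- 0L; b$j <- 20L
  out <- compare_libraries(a, b)
  expect_equal(out$shared$p_fisher, fisher_brute(10, 20, 0, 20),
               tolerance = 1e-12)
  set.seed(7)
  for (k in 1:20) {
    ja <- sample(5:40, 1); jb <- sample(5:40, 1)
    ia <- sample(0:ja, 1); ib <- sample(0:jb, 1)
    aa <- site_at(10); bb <- site_at(10)
    aa$i <- ia; aa$j <- ja; bb$i <- ib; bb$j <- jb
    got <- compare_libraries(aa, bb)$shared$p_fisher
    expect_equal(got, fisher_brute(ia, ja, ib, jb), tolerance = 1e-12)
  }
})
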