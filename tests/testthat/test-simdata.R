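test_that("reference generation is deterministic and respects counts", {
  cfg <- sim_config(n_transcripts = 1, n_control_transcripts = 0,
                    length_range = c(300, 300), seed = 7)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_equal(length(r1$sequences), 1L)
  expect_equal(Biostrings::width(r1$sequences), 300L)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))

  cfg2 <- sim_config(n_transcripts = 5, n_control_transcripts = 2, seed = 1)
  r <- generate_reference(cfg2)
  expect_length(r$control_ids, 2L)
  expect_true(all(startsWith(r$control_ids, "CTRL")))
  expect_equal(sum(startsWith(names(r$sequences), "CTRL")), 2L)
})

test_that("generated GC content matches the configured value", {
  # oracle: direct base counting over >= 100 kb of sequence
  cfg <- sim_config(n_transcripts = 60, length_range = c(1800, 2000),
                    gc_content = 0.4, n_control_transcripts = 0, seed = 5)
  r <- generate_reference(cfg)
  expect_gte(sum(Biostrings::width(r$sequences)), 100000L)
  counts <- colSums(Biostrings::letterFrequency(r$sequences, c("G", "C")))
  gc <- sum(counts) / sum(Biostrings::width(r$sequences))
  expect_lt(abs(gc - 0.4), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(length_range = c(500, 300)), "ascending")
  expect_error(sim_config(conversion_rate = 1.5), "probabilities")
  expect_error(sim_config(n_transcripts = 0), "n_transcripts")
})

test_that("planted sites are distinct reference Cs off the controls", {
  cfg <- tiny_config(seed = 2)
  ref <- generate_reference(cfg)
  t0 <- plant_methylation(ref, sim_config(n_true_sites = 0, seed = 2))
  expect_equal(nrow(t0$sites), 0L)

  tr <- plant_methylation(ref, cfg)
  expect_equal(nrow(tr$sites), 6L)
  expect_equal(anyDuplicated(tr$sites[, paste(ref, pos)]), 0L)
  expect_false(any(tr$sites$ref %in% ref$control_ids))
  planted_base <- substr(as.character(ref$sequences[tr$sites$ref]),
                         tr$sites$pos + 1L, tr$sites$pos + 1L)
  expect_true(all(planted_base == "C"))
  expect_true(all(tr$sites$level >= 0 & tr$sites$level <= 1))
})

test_that("planting rejects impossible site counts", {
  cfg <- tiny_config(seed = 3)
  ref <- generate_reference(cfg)
  cfg_big <- tiny_config(seed = 3, n_true_sites = 10000)
  expect_error(plant_methylation(ref, cfg_big), "insufficient C positions")
})

test_that("perfect conversion leaves control reads C-free at reference Cs", {
  cfg <- tiny_config(seed = 4, conversion_rate = 1.0,
                     resistant_read_fraction = 0, n_true_sites = 0,
                     pcr_error_rate = 0, seq_error_rate = 0)
  ref <- generate_reference(cfg)
  tr <- plant_methylation(ref, cfg)
  sim <- simulate_reads(ref, tr, cfg)
  ctrl_ids <- ref$control_ids
  cc <- read_c_content(sim$reads[ref %in% ctrl_ids], ref)
  expect_true(all(cc$c_content == 0L))
})

test_that("a fully methylated site stays C on every error-free molecule", {
  cfg <- tiny_config(seed = 5, conversion_rate = 1.0,
                     resistant_read_fraction = 0, pcr_error_rate = 0,
                     seq_error_rate = 0, n_true_sites = 1,
                     level_distribution = function(n) rep(1, n))
  ref <- generate_reference(cfg)
  tr <- plant_methylation(ref, cfg)
  sim <- simulate_reads(ref, tr, cfg)
  sites <- call_sites(sim$reads, ref, min_base_q = 0, min_cov = 1)
  at <- sites[ref == tr$sites$ref & pos == tr$sites$pos]
  expect_equal(at$level, 1)
  expect_gt(at$j, 0)
})

test_that("no PCR means no duplicate templates", {
  cfg <- tiny_config(seed = 6, pcr_cycles = 0)
  ref <- generate_reference(cfg)
  tr <- plant_methylation(ref, cfg)
  sim <- simulate_reads(ref, tr, cfg)
  expect_false(any(sim$read_truth$is_pcr_duplicate))
  expect_equal(data.table::uniqueN(sim$reads$qname), nrow(sim$read_truth))
})

test_that("simulated conversion rate is recovered within binomial error", {
  # oracle: binomial CI around the configured rate on >= 50k C observations
  cfg <- sim_config(n_transcripts = 4, n_control_transcripts = 4,
                    length_range = c(1500, 1500), mean_coverage = 60,
                    n_true_sites = 0, conversion_rate = 0.99,
                    resistant_read_fraction = 0, seq_error_rate = 0,
                    pcr_error_rate = 0, seed = 8)
  ref <- generate_reference(cfg)
  tr <- plant_methylation(ref, cfg)
  sim <- simulate_reads(ref, tr, cfg)
  cs <- conversion_rate(sim$reads, ref)
  n_obs <- cs$per_control[, sum(total)]
  expect_gte(n_obs, 50000)
  sd3 <- 3 * sqrt(0.99 * 0.01 / n_obs)
  expect_lt(abs(cs$rate - 0.99), sd3)
})

test_that("fixed seed reproduces byte-identical SAM and FASTQ", {
  cfg <- tiny_config(seed = 9)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_dataset(cfg, dir = d1, fastq = TRUE)
  simulate_dataset(cfg, dir = d2, fastq = TRUE)
  for (f in c("reads.sam", "reads.fastq", "ref.fa", "genes.gtf")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("PCR amplification favours templates with fewer unconverted Cs", {
  for (s in 1:2) {
    cfg <- tiny_config(seed = 10 + s, pcr_cycles = 4, pcr_efficiency = 0.5,
                       pcr_bias_beta = 0.9, resistant_read_fraction = 0.1)
    ref <- generate_reference(cfg)
    tr <- plant_methylation(ref, cfg)
    sim <- simulate_reads(ref, tr, cfg)
    rt <- sim$read_truth
    expect_lte(rt[is_pcr_duplicate == TRUE, mean(unconv_frac)],
               rt[is_pcr_duplicate == FALSE, mean(unconv_frac)])
  }
})

test_that("SAM round trip preserves reads, coordinates and UMIs", {
  ds <- tiny_dataset()
  sam <- tempfile(fileext = ".sam")
  write_sam(ds$reads, ds$reference, sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(ds$reads))
  a <- data.table::setorder(data.table::copy(ds$reads), qname, mate)
  b <- data.table::setorder(back, qname, mate)
  for (col in c("qname", "umi", "ref", "start", "seq", "qual", "mate",
                "reverse", "orientation"))
    expect_identical(a[[col]], b[[col]], label = col)
  unlink(sam)
})
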