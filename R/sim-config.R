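#' Simulation configuration for bisulfite read generation
#'
#' Builds the configuration object consumed by [generate_reference()],
#' [plant_methylation()] and [simulate_reads()]. Defaults describe a small
#' directional RNA BS-seq experiment: paired 150 nt reads from short
#' fragments, near-complete bisulfite conversion (99.9 percent), a small
#' fraction of molecules that escape conversion entirely (secondary-structure
#' proxy), mild PCR duplication whose efficiency is penalised for
#' unconverted-C-rich (i.e. methylated or resistant) templates, and Phred
#' scores in which called cytosines run three points below other bases.
#'
#' @param n_transcripts Number of non-control reference transcripts.
#' @param length_range Length range (nt) for generated transcripts,
#'   `c(min, max)`.
#' @param gc_content Target GC fraction of generated sequence.
#' @param n_control_transcripts Number of unmethylated spike-in control
#'   transcripts (ERCC-like); never receive planted sites.
#' @param control_prefix ID prefix marking control transcripts.
#' @param n_true_sites Number of methylated cytosines to plant.
#' @param level_distribution Function `n -> numeric(n)` drawing true
#'   methylation levels in `[0, 1]`.
#' @param mean_coverage Target per-base coverage in unique template
#'   molecules (pre-PCR).
#' @param read_length Read length (nt).
#' @param fragment_length Fragment length range `c(min, max)` (nt).
#' @param paired Simulate paired-end reads (read 2 reverse-complemented,
#'   G-to-A conversion space)? Single-end when `FALSE`.
#' @param conversion_rate Probability that an unmethylated C is read as T.
#' @param resistant_read_fraction Probability that a whole molecule escapes
#'   bisulfite conversion.
#' @param resistant_transcripts Optional character vector of transcript IDs
#'   on which resistance is concentrated; `NULL` applies
#'   `resistant_read_fraction` uniformly.
#' @param pcr_cycles Number of discrete PCR doubling rounds.
#' @param pcr_efficiency Per-round per-molecule duplication probability for
#'   a fully converted template.
#' @param pcr_bias_beta Amplification penalty per unit unconverted-C
#'   fraction: efficiency is multiplied by
#'   `max(0, 1 - pcr_bias_beta * unconverted_fraction)`, so PCR favours
#'   unmethylated (T-bearing) templates.
#' @param pcr_error_rate Per-base substitution probability per PCR copy.
#' @param seq_error_rate Per-base sequencing substitution probability.
#' @param qual_mean_non_c Mean Phred score of non-cytosine base calls.
#' @param qual_sd Phred score standard deviation.
#' @param qual_c_penalty Phred points subtracted from the mean for cytosine
#'   calls (guanines on reverse-stored reads).
#' @param umi_length UMI length (nt); collisions are allowed.
#' @param seed Integer seed fixing all randomness end to end.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 10,
                       length_range = c(1200L, 2000L),
                       gc_content = 0.5,
                       n_control_transcripts = 2,
                       control_prefix = "CTRL",
                       n_true_sites = 20,
                       level_distribution = function(n) runif(n, 0.2, 1),
                       mean_coverage = 100,
                       read_length = 150L,
                       fragment_length = c(200L, 300L),
                       paired = TRUE,
                       conversion_rate = 0.999,
                       resistant_read_fraction = 0.02,
                       resistant_transcripts = NULL,
                       pcr_cycles = 3L,
                       pcr_efficiency = 0.07,
                       pcr_bias_beta = 0.5,
                       pcr_error_rate = 1e-4,
                       seq_error_rate = 1e-3,
                       qual_mean_non_c = 36,
                       qual_sd = 3,
                       qual_c_penalty = 3,
                       umi_length = 8L,
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    length_range = as.integer(length_range),
    gc_content = gc_content,
    n_control_transcripts = as.integer(n_control_transcripts),
    control_prefix = control_prefix,
    n_true_sites = as.integer(n_true_sites),
    level_distribution = level_distribution,
    mean_coverage = mean_coverage,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    paired = isTRUE(paired),
    conversion_rate = conversion_rate,
    resistant_read_fraction = resistant_read_fraction,
    resistant_transcripts = resistant_transcripts,
    pcr_cycles = as.integer(pcr_cycles),
    pcr_efficiency = pcr_efficiency,
    pcr_bias_beta = pcr_bias_beta,
    pcr_error_rate = pcr_error_rate,
    seq_error_rate = seq_error_rate,
    qual_mean_non_c = qual_mean_non_c,
    qual_sd = qual_sd,
    qual_c_penalty = qual_c_penalty,
    umi_length = as.integer(umi_length),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (length(cfg$length_range) != 2 || cfg$length_range[1] > cfg$length_range[2])
    stop("length_range must be an ascending pair")
  if (length(cfg$fragment_length) != 2 ||
      cfg$fragment_length[1] > cfg$fragment_length[2])
    stop("fragment_length must be an ascending pair")
  probs <- c(gc_content = cfg$gc_content,
             conversion_rate = cfg$conversion_rate,
             resistant_read_fraction = cfg$resistant_read_fraction,
             pcr_efficiency = cfg$pcr_efficiency,
             pcr_error_rate = cfg$pcr_error_rate,
             seq_error_rate = cfg$seq_error_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities out of [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  if (cfg$n_control_transcripts < 0 || cfg$n_control_transcripts > cfg$n_transcripts)
    stop("n_control_transcripts must be in [0, n_transcripts]")
  if (cfg$n_true_sites < 0) stop("n_true_sites must be >= 0")
  if (cfg$umi_length < 1) stop("umi_length must be >= 1")
  if (cfg$pcr_bias_beta < 0) stop("pcr_bias_beta must be >= 0")
  invisible(cfg)
}
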