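#' Configuration for the synthetic editome dataset
#'
#' Builds and validates the configuration object consumed by
#' [simulate_reference()], [plant_sites()] and [simulate_alignments()]. The
#' defaults emulate, at desk scale, pooled microglia RNA-seq libraries:
#' moderate uniform coverage, a small fraction of multimapping reads, a low
#' per-base substitution error rate that is elevated near read ends (the
#' signature of random-hexamer mispriming), and planted A-to-I and C-to-U
#' editing sites at intermediate frequencies alongside heterozygous SNPs.
#'
#' @param seed integer seed controlling every stochastic step.
#' @param genome_length reference length in bases (single chromosome).
#' @param n_transcripts number of transcripts laid out along the genome;
#'   coding and non-coding models alternate so that every genomic feature
#'   class is represented. Must be at least 2.
#' @param flank_window bases defining the merged upstream/downstream flank
#'   feature around each transcript.
#' @param n_edit_sites named integer vector `c(a_to_i =, c_to_u =)`: number
#'   of editing sites planted per class.
#' @param edit_freq_range numeric length-2 interval in (0, 1]; each planted
#'   site draws its true editing frequency uniformly from this range.
#' @param n_snp_sites number of SNP positions planted (and masked in the VCF).
#' @param snp_hom_fraction fraction of SNPs simulated homozygous (alt in all
#'   reads); the remainder are heterozygous (alt in ~50% of reads) so that
#'   they pass frequency filters and can only be removed by the SNP mask.
#' @param error_rate per-base substitution error probability.
#' @param end_error_boost multiplier applied to `error_rate` within
#'   `end_error_window` bases of either read end.
#' @param end_error_window width in bases of the elevated-error zone at each
#'   read end.
#' @param read_length read length in bases.
#' @param mean_depth target mean coverage (reads are placed uniformly).
#' @param multimap_fraction fraction of reads emitted as multimappers
#'   (mapping quality 0, tag `ZM:i:1`).
#' @param low_qual_fraction fraction of base calls assigned a quality below
#'   25 (drawn in Q10-Q24) to exercise the base-quality filter; the rest are
#'   drawn in Q33-Q40 (around Q35).
#' @param chrom_name name of the simulated chromosome.
#'
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 20000, n_transcripts = 4)
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_transcripts = 6L,
                       flank_window = 1000L,
                       n_edit_sites = c(a_to_i = 20L, c_to_u = 10L),
                       edit_freq_range = c(0.2, 0.8),
                       n_snp_sites = 20L,
                       snp_hom_fraction = 0,
                       error_rate = 0.005,
                       end_error_boost = 3,
                       end_error_window = 6L,
                       read_length = 75L,
                       mean_depth = 50,
                       multimap_fraction = 0.05,
                       low_qual_fraction = 0.05,
                       chrom_name = "chrS") {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_transcripts = as.integer(n_transcripts),
    flank_window = as.integer(flank_window),
    n_edit_sites = vapply(n_edit_sites, as.integer, integer(1)),
    edit_freq_range = as.numeric(edit_freq_range),
    n_snp_sites = as.integer(n_snp_sites),
    snp_hom_fraction = as.numeric(snp_hom_fraction),
    error_rate = as.numeric(error_rate),
    end_error_boost = as.numeric(end_error_boost),
    end_error_window = as.integer(end_error_window),
    read_length = as.integer(read_length),
    mean_depth = as.numeric(mean_depth),
    multimap_fraction = as.numeric(multimap_fraction),
    low_qual_fraction = as.numeric(low_qual_fraction),
    chrom_name = as.character(chrom_name)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_that(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be a single integer")
  check_that(cfg$genome_length >= 1000, "genome_length must be at least 1000 bases")
  check_that(cfg$n_transcripts >= 2,
             "n_transcripts must be >= 2 (coding and non-coding models alternate)")
  check_that(all(c("a_to_i", "c_to_u") %in% names(cfg$n_edit_sites)),
             "n_edit_sites must be named c(a_to_i =, c_to_u =)")
  check_that(all(cfg$n_edit_sites >= 0) && cfg$n_snp_sites >= 0,
             "site counts must be non-negative")
  check_that(length(cfg$edit_freq_range) == 2 &&
               cfg$edit_freq_range[1] > 0 && cfg$edit_freq_range[2] <= 1 &&
               cfg$edit_freq_range[1] <= cfg$edit_freq_range[2],
             "edit_freq_range must be an ordered interval within (0, 1]")
  for (p in c("snp_hom_fraction", "error_rate", "multimap_fraction",
              "low_qual_fraction")) {
    check_that(cfg[[p]] >= 0 && cfg[[p]] <= 1,
               paste0(p, " must lie in [0, 1]"))
  }
  check_that(cfg$end_error_boost >= 1, "end_error_boost must be >= 1")
  check_that(cfg$read_length >= 20 &&
               cfg$read_length > 2L * cfg$end_error_window,
             "read_length must exceed twice the end_error_window")
  check_that(cfg$mean_depth >= 0, "mean_depth must be non-negative")
  check_that(cfg$flank_window >= 0, "flank_window must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("genome %d bp, %d transcripts, %d+%d edit sites, %d SNPs",
              x$genome_length, x$n_transcripts,
              x$n_edit_sites[["a_to_i"]], x$n_edit_sites[["c_to_u"]],
              x$n_snp_sites),
      sprintf("depth %.0fx, read %d bp, error %.4f (x%.0f in %d-bp read ends), seed %d",
              x$mean_depth, x$read_length, x$error_rate, x$end_error_boost,
              x$end_error_window, x$seed),
      sep = "\n  ")
  invisible(x)
}
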