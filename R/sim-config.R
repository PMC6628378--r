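# Simulation configuration for the eight-library synthetic experiment.

#' Configuration of the synthetic small RNA experiment
#'
#' Defines the study conditions the generator emulates: two genotypes (HRK,
#' resistant; HSK, susceptible) at two feeding timepoints (0 h, 48 h) with
#' two biological replicates each, at per-library depths of roughly
#' 150,000-220,000 reads (published library magnitudes scaled down 100x),
#' a ~90% clean-read rate from seven planted contamination classes, insert
#' lengths of 18-32 nt peaking at 20/21/24 nt, an rRNA content of about 2%
#' of clean reads, and differential expression planted at |log2fc| >= 1.
#'
#' All downstream randomness flows from `seed` through per-stage derived
#' seeds; identical configurations produce byte-identical artifacts.
#'
#' @param seed integer master seed.
#' @param n_known_mirnas number of catalogued mature miRNAs.
#' @param n_novel_hairpins number of planted novel (uncatalogued) hairpins.
#' @param n_other_ncrna named counts of reference sequences per non-miRNA
#'   class (`rRNA`, `tRNA`, `snoRNA`, `snRNA`).
#' @param genome_length total genome size (nt, split over 4 contigs); must be
#'   at least 10x the embedded feature length.
#' @param n_genes protein-coding genes in the gene model.
#' @param library_sizes named integer vector of reads per library
#'   (`HRK0-1` ... `HSK48-2`).
#' @param de_fraction fraction of known miRNAs planted differentially
#'   expressed.
#' @param de_log2fc_range planted |log2fc| interval; lower bound >= 1.
#' @param n_genotype_specific miRNAs expressed only in the resistant
#'   genotype.
#' @param adapter_5p,adapter_3p library adapter sequences (defaults: Illumina
#'   TruSeq small RNA adapters).
#' @param contamination_rates named per-rule violation fractions
#'   (`rule1_low_quality` ... `rule7_short`); each in \[0,1) and jointly
#'   below 1.
#' @param rrna_target_fraction rRNA fraction of clean reads.
#' @param class_fractions named clean-read fractions for the remaining
#'   annotation classes (`mirna`, `novel`, `trna`, `snorna`, `snrna`,
#'   `precursor`, `unmapped`); the genomic background takes the remainder.
#' @param mrna_targets_per_de_mirna planted target transcripts per DE miRNA.
#' @param n_decoy_genes non-target decoy transcripts.
#' @param read_length raw read length (nt).
#' @param mean_phred mean base quality of good reads.
#' @param insert_len_probs named probabilities of insert lengths 18-32 nt
#'   (default peaks at 20, 21 and 24 nt).
#' @param qpcr_noise_sd Gaussian Ct noise (cycles) of the qPCR simulation.
#' @return validated list of class `mirdef_sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_known_mirnas = 60L,
    n_novel_hairpins = 8L,
    n_other_ncrna = c(rRNA = 6L, tRNA = 4L, snoRNA = 4L, snRNA = 4L),
    genome_length = 100000L,
    n_genes = 15L,
    library_sizes = c(
      "HRK0-1" = 181876L, "HRK0-2" = 156450L, "HRK48-1" = 158115L,
      "HRK48-2" = 222138L, "HSK0-1" = 158777L, "HSK0-2" = 164181L,
      "HSK48-1" = 191547L, "HSK48-2" = 197055L
    ),
    de_fraction = 0.25,
    de_log2fc_range = c(1, 3),
    n_genotype_specific = 2L,
    adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
    adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
    contamination_rates = c(
      rule1_low_quality = 0.030, rule2_high_n = 0.004,
      rule3_adapter5 = 0.008, rule4_no_adapter3 = 0.030,
      rule5_no_insert = 0.010, rule6_polya = 0.004, rule7_short = 0.008
    ),
    rrna_target_fraction = 0.02,
    class_fractions = c(
      mirna = 0.045, novel = 0.004, trna = 0.0003, snorna = 0.0005,
      snrna = 0.0005, precursor = 0.0015, unmapped = 0.10
    ),
    mrna_targets_per_de_mirna = 2L,
    n_decoy_genes = 30L,
    read_length = 50L,
    mean_phred = 35L,
    insert_len_probs = default_insert_len_probs(),
    qpcr_noise_sd = 0.15) {
  assert_count(seed, "seed")
  assert_count(n_known_mirnas, "n_known_mirnas", min = 1)
  assert_count(n_novel_hairpins, "n_novel_hairpins")
  if (de_log2fc_range[1] < 1)
    abort("`de_log2fc_range` must be bounded below by 1.0")
  assert_fraction(contamination_rates, "contamination_rates")
  if (sum(contamination_rates) >= 1)
    abort("contamination rates must jointly stay below 1")
  assert_fraction(de_fraction, "de_fraction")
  assert_fraction(rrna_target_fraction, "rrna_target_fraction")
  if (length(library_sizes) != 8 || is.null(names(library_sizes)))
    abort("`library_sizes` must name the 8 libraries")
  if (abs(sum(insert_len_probs) - 1) > 1e-8)
    abort("`insert_len_probs` must sum to 1")
  structure(
    list(
      seed = as.integer(seed), n_known_mirnas = as.integer(n_known_mirnas),
      n_novel_hairpins = as.integer(n_novel_hairpins),
      n_other_ncrna = n_other_ncrna, genome_length = as.integer(genome_length),
      n_genes = as.integer(n_genes), library_sizes = library_sizes,
      de_fraction = de_fraction, de_log2fc_range = de_log2fc_range,
      n_genotype_specific = as.integer(n_genotype_specific),
      adapter_5p = adapter_5p, adapter_3p = adapter_3p,
      contamination_rates = contamination_rates,
      rrna_target_fraction = rrna_target_fraction,
      class_fractions = class_fractions,
      mrna_targets_per_de_mirna = as.integer(mrna_targets_per_de_mirna),
      n_decoy_genes = as.integer(n_decoy_genes),
      read_length = as.integer(read_length), mean_phred = as.integer(mean_phred),
      insert_len_probs = insert_len_probs, qpcr_noise_sd = qpcr_noise_sd
    ),
    class = "mirdef_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_insert_len_probs <- function() {
  p <- setNames(rep(0.29 / 12, 15), as.character(18:32))
  p["20"] <- 0.18
  p["21"] <- 0.26
  p["24"] <- 0.27
  p / sum(p)
}

#' @export
print.mirdef_sim_config <- function(x, ...) {
  cat(sprintf(
    "<mirdef_sim_config> seed %d: %d known miRNAs, %d novel hairpins, %d nt genome, 8 libraries (%s reads)\n",
    x$seed, x$n_known_mirnas, x$n_novel_hairpins, x$genome_length,
    paste(range(x$library_sizes), collapse = "-")))
  invisible(x)
}
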