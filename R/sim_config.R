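#' Configuration for the synthetic small RNA-seq data generator
#'
#' Builds and validates the parameter set that fully determines a simulated
#' study: a toy genome with planted gene models, repeats and piRNA clusters,
#' plus two groups of replicate FASTQ libraries carrying piRNA reads, known
#' small RNA fragments and one planted read class per QC filter.
#'
#' Defaults emulate the study conditions the package is built around: a
#' unimodal 24-33 nt piRNA length distribution peaking at 29 nt, a strong
#' 5' U bias, opposite-strand ping-pong partner loci whose 5' ends overlap by
#' exactly 10 nt, mono-directional piRNA clusters, retrotransposon-dominated
#' TE composition, two groups of three replicate libraries, and the TruSeq
#' small RNA adapters (the 5' adapter stored RNA-to-DNA converted so trimming
#' tests are byte-exact).
#'
#' @param seed Integer seed; fully determines every generator output.
#' @param n_chromosomes,chrom_length Number and length (nt) of toy chromosomes.
#' @param n_clusters Number of planted piRNA clusters.
#' @param cluster_length_range Length range (nt) clusters are drawn from.
#' @param loci_per_cluster Distinct piRNA 5' positions planted per cluster.
#' @param pirna_length_mode,pirna_length_range Modal length and allowed
#'   length range (nt) of planted piRNA loci; the range must sit within
#'   18-40 nt.
#' @param frac_1U Probability that a planted locus has 5' U.
#' @param frac_pingpong_pairs Probability that a cluster or repeat locus gets
#'   an opposite-strand partner with an exact 10-nt 5' overlap.
#' @param frac_antisense_bg Probability that a cluster or repeat locus gets
#'   an opposite-strand partner at a random 5' overlap other than 10 nt;
#'   emulates the incidental antisense overlaps real libraries always
#'   contain, giving the ping-pong Z-score a non-degenerate background.
#' @param n_genes_per_chrom Planted protein-coding gene models per
#'   chromosome.
#' @param te_composition Named fractions ("class/family") summing to 1; the
#'   family labels written to the repeat BED track.
#' @param n_repeats Number of planted repeat intervals.
#' @param contaminant_fracs Named per-library read fractions for the planted
#'   QC classes `qc_low_quality`, `qc_high_N`, `qc_5p_adapter`,
#'   `qc_no_3p_adapter`, `qc_homopolymer`, `qc_bad_length`.
#' @param srna_fracs Named per-library read fractions for known small RNA
#'   classes (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `miRNA`).
#' @param n_feature_loci Named counts of piRNA loci planted inside gene
#'   features, repeats and unannotated space (keys `CDS`, `UTR5`, `UTR3`,
#'   `intron`, `lncRNA`, `repeat`, `unannotated`).
#' @param n_samples_per_group Replicate libraries per group (groups "A", "B").
#' @param n_reads_per_library Total reads emitted per library.
#' @param n_de_tags Number of planted differentially expressed tags (split
#'   evenly between up- and down-regulated in group B).
#' @param de_log2fc Absolute planted log2 fold change.
#' @param dispersion Negative-binomial dispersion of per-sample tag counts.
#' @param adapter_3p,adapter_5p Adapter sequences (DNA alphabet).
#' @param read_length Raw read length (nt) before trimming.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_reads_per_library = 20000)
#' cfg$pirna_length_mode
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 150000L,
                       n_clusters = 5L,
                       cluster_length_range = c(3000L, 8000L),
                       loci_per_cluster = 40L,
                       pirna_length_mode = 29L,
                       pirna_length_range = c(24L, 33L),
                       frac_1U = 0.9,
                       frac_pingpong_pairs = 0.25,
                       frac_antisense_bg = 0.10,
                       n_genes_per_chrom = 4L,
                       te_composition = c(
                         "LINE/L1" = 0.30, "LINE/L2" = 0.15, "SINE/MIR" = 0.15,
                         "LTR/ERV1" = 0.10, "LTR/ERVK" = 0.10, "LTR/ERVL" = 0.05,
                         "LTR/ERVL-MaLR" = 0.05, "DNA/hAT-Charlie" = 0.10),
                       n_repeats = 36L,
                       contaminant_fracs = c(
                         qc_low_quality = 0.002, qc_high_N = 0.0001,
                         qc_5p_adapter = 0.0005, qc_no_3p_adapter = 0.015,
                         qc_homopolymer = 0.004, qc_bad_length = 0.02),
                       srna_fracs = c(
                         rRNA = 0.016, tRNA = 0.0005, snRNA = 0.0012,
                         snoRNA = 0.003, miRNA = 0.07),
                       n_feature_loci = c(
                         CDS = 24L, UTR5 = 6L, UTR3 = 6L, intron = 12L,
                         lncRNA = 6L, "repeat" = 40L, unannotated = 24L),
                       n_samples_per_group = 3L,
                       n_reads_per_library = 100000L,
                       n_de_tags = 30L,
                       de_log2fc = 2,
                       dispersion = 0.1,
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_length = 50L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_clusters = as.integer(n_clusters),
    cluster_length_range = as.integer(cluster_length_range),
    loci_per_cluster = as.integer(loci_per_cluster),
    pirna_length_mode = as.integer(pirna_length_mode),
    pirna_length_range = as.integer(pirna_length_range),
    frac_1U = frac_1U,
    frac_pingpong_pairs = frac_pingpong_pairs,
    frac_antisense_bg = frac_antisense_bg,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    te_composition = te_composition,
    n_repeats = as.integer(n_repeats),
    contaminant_fracs = contaminant_fracs,
    srna_fracs = srna_fracs,
    n_feature_loci = n_feature_loci,
    n_samples_per_group = as.integer(n_samples_per_group),
    n_reads_per_library = as.integer(n_reads_per_library),
    n_de_tags = as.integer(n_de_tags),
    de_log2fc = de_log2fc,
    dispersion = dispersion,
    adapter_3p = toupper(adapter_3p),
    adapter_5p = toupper(adapter_5p),
    read_length = as.integer(read_length)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar_fraction(cfg$frac_1U, "frac_1U")
  stopifnot_scalar_fraction(cfg$frac_pingpong_pairs, "frac_pingpong_pairs")
  stopifnot_scalar_fraction(cfg$frac_antisense_bg, "frac_antisense_bg")
  if (cfg$frac_pingpong_pairs + cfg$frac_antisense_bg > 1) {
    stop("frac_pingpong_pairs + frac_antisense_bg must not exceed 1",
         call. = FALSE)
  }
  if (abs(sum(cfg$te_composition) - 1) > 1e-9) {
    stop("te_composition fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(cfg$te_composition < 0) || any(cfg$te_composition > 1)) {
    stop("te_composition fractions must lie in [0, 1]", call. = FALSE)
  }
  for (nm in names(cfg$contaminant_fracs)) {
    stopifnot_scalar_fraction(cfg$contaminant_fracs[[nm]], nm)
  }
  for (nm in names(cfg$srna_fracs)) {
    stopifnot_scalar_fraction(cfg$srna_fracs[[nm]], nm)
  }
  if (sum(cfg$contaminant_fracs) + sum(cfg$srna_fracs) > 1) {
    stop("contaminant and known-sRNA fractions sum above 1", call. = FALSE)
  }
  rng <- cfg$pirna_length_range
  if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 18L || rng[2] > 40L) {
    stop("pirna_length_range must be an increasing pair within [18, 40]",
         call. = FALSE)
  }
  if (cfg$pirna_length_mode < rng[1] || cfg$pirna_length_mode > rng[2]) {
    stop("pirna_length_mode must lie inside pirna_length_range", call. = FALSE)
  }
  if (cfg$n_chromosomes < 1L || cfg$chrom_length < 10000L) {
    stop("need at least one chromosome of length >= 10000", call. = FALSE)
  }
  if (nchar(cfg$adapter_3p) < 8L || nchar(cfg$adapter_5p) < 8L) {
    stop("adapters must be at least 8 nt", call. = FALSE)
  }
  if (cfg$read_length < rng[2] + 8L) {
    stop("read_length too short to carry the longest insert plus adapter seed",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_chromosomes, "chromosomes x", x$chrom_length, "nt;",
      x$n_clusters, "clusters;",
      2L * x$n_samples_per_group, "libraries x",
      x$n_reads_per_library, "reads; seed", x$seed, "\n")
  invisible(x)
}
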