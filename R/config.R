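# Threshold and simulation configuration. Every numeric knob of the
# detection cascade lives in filter_config() so a run is fully described by
# one object.

#' Filter cascade configuration
#'
#' All thresholds of the RDD detection cascade in one list. Defaults are the
#' operating point of the chicken embryo screen: 15-read minimum depth in
#' both DNA and RNA, support by at least 2 biological replicates, rejection
#' of sites whose median alt-read offset falls in the first or last 10 read
#' bases, a maximum strand delta of 0.5, a third-allele cap of 5%, removal
#' of homopolymers of length >= 5, a 20-base flank per side for the
#' genomic-read pattern search (a 41-mer centred on the edited base), and
#' VEP-convention splice windows (3 exonic / 8 intronic bases).
#'
#' @param min_depth Minimum read depth required in both DNA and RNA.
#' @param min_replicates Minimum biological replicates sharing the edited
#'   allele.
#' @param end_window Read-end window (bases) for the median-offset filter.
#' @param strand_delta_max Maximum |forward - reverse| edited-allele
#'   proportion difference.
#' @param third_allele_max Maximum pooled fraction of alleles other than the
#'   DNA allele and the edited allele (strictly below passes).
#' @param homopolymer_min_run Minimal single-base run length treated as a
#'   homopolymer.
#' @param pattern_flank Reference flank per side of the edited base for the
#'   DNA-read pattern search.
#' @param pattern_max_mismatch Mismatches tolerated in the pattern search.
#' @param splice_window_exonic,splice_window_intronic Bases on the exon /
#'   intron side of a splice boundary considered splice region.
#' @param cluster_max_gap Maximum distance (bp) between consecutive sites of
#'   a cluster (used by [find_clusters()]).
#' @param het_min_fraction,het_min_count Floor on the RNA alternative-allele
#'   fraction and read count for a heterozygous RNA call.
#' @param dna_hom_fraction Minimum DNA major-allele fraction for a
#'   provisional homozygous genotype (the strict zero-count rule is applied
#'   cascade-wide by the DNA-alt-zero stage).
#' @param max_coverage Pileup coverage cap honoured on load.
#' @param flank_bp Up/downstream window for gene consequence assignment.
#' @return A list of class `rdd_filter_config`.
#' @export
filter_config <- function(min_depth = 15L,
                          min_replicates = 2L,
                          end_window = 10L,
                          strand_delta_max = 0.5,
                          third_allele_max = 0.05,
                          homopolymer_min_run = 5L,
                          pattern_flank = 20L,
                          pattern_max_mismatch = 0L,
                          splice_window_exonic = 3L,
                          splice_window_intronic = 8L,
                          cluster_max_gap = 1000L,
                          het_min_fraction = 0.05,
                          het_min_count = 2L,
                          dna_hom_fraction = 0.98,
                          max_coverage = 10000L,
                          flank_bp = 5000L) {
  cfg <- list(
    min_depth = as.integer(min_depth),
    min_replicates = as.integer(min_replicates),
    end_window = as.integer(end_window),
    strand_delta_max = strand_delta_max,
    third_allele_max = third_allele_max,
    homopolymer_min_run = as.integer(homopolymer_min_run),
    pattern_flank = as.integer(pattern_flank),
    pattern_max_mismatch = as.integer(pattern_max_mismatch),
    splice_window_exonic = as.integer(splice_window_exonic),
    splice_window_intronic = as.integer(splice_window_intronic),
    cluster_max_gap = as.integer(cluster_max_gap),
    het_min_fraction = het_min_fraction,
    het_min_count = as.integer(het_min_count),
    dna_hom_fraction = dna_hom_fraction,
    max_coverage = as.integer(max_coverage),
    flank_bp = as.integer(flank_bp)
  )
  nums <- unlist(cfg[names(cfg) != "pattern_max_mismatch"])
  if (any(nums <= 0) || cfg$pattern_max_mismatch < 0L) {
    abort("all filter thresholds must be positive")
  }
  if (cfg$third_allele_max >= 0.5) {
    abort("third_allele_max must be below 0.5")
  }
  structure(cfg, class = c("rdd_filter_config", "list"))
}

#' Simulation configuration for the synthetic data generator
#'
#' Defaults mirror the design of the chicken embryo screen scaled to a toy
#' genome: 8 biological replicates of matched DNA/RNA, 100-base reads, an
#' editing-frequency range spanning the observed candidate frequencies
#' (0.18-0.87), and sequencing error at a post-quality-filtering per-base
#' miscall rate.
#'
#' @param seed Integer seed; every emitted file is a deterministic function
#'   of the configuration.
#' @param genome_length Toy genome length in bases (single chromosome).
#' @param n_replicates Biological replicates with matched DNA and RNA.
#' @param dna_depth,rna_depth Mean per-replicate read depth at a site.
#' @param error_rate Per-base miscall rate of retained (quality-filtered)
#'   read bases.
#' @param n_true_edits Planted genuine editing sites.
#' @param n_per_artifact_class Planted sites per artifact class.
#' @param freq_range Editing-frequency range for planted true edits.
#' @param read_length Nominal read length in bases.
#' @param homopolymer_run Length of planted homopolymer runs (>= 5).
#' @param paralog_divergence Substitutions planted in the duplicated
#'   segment copy.
#' @param tissues,stages Factor levels of the editing-level design.
#' @param n_per_cell Replicates per tissue x stage cell.
#' @param tissue_effects,stage_effects Logit-scale main effects (length 3).
#' @param interaction_effects 3 x 3 matrix of logit-scale interaction terms.
#' @param baseline_logit Logit of the grand-mean editing level.
#' @param noise_sd Logit-scale residual standard deviation.
#' @return A list of class `rdd_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 50000L,
                              n_replicates = 8L,
                              dna_depth = 30,
                              rna_depth = 50,
                              error_rate = 2e-4,
                              n_true_edits = 50L,
                              n_per_artifact_class = 30L,
                              freq_range = c(0.18, 0.87),
                              read_length = 100L,
                              homopolymer_run = 6L,
                              paralog_divergence = 35L,
                              tissues = c("brain", "heart", "liver"),
                              stages = c("embryo_d4.5", "embryo_d15", "adult_11mo"),
                              n_per_cell = 4L,
                              tissue_effects = c(0, 0, 0),
                              stage_effects = c(0, 0, 0),
                              interaction_effects = matrix(0, 3, 3),
                              baseline_logit = 0,
                              noise_sd = 0.4) {
  if (is.null(seed) || is.na(seed)) {
    abort("simulation_config() requires an explicit integer seed")
  }
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_replicates = as.integer(n_replicates),
    dna_depth = dna_depth,
    rna_depth = rna_depth,
    error_rate = error_rate,
    n_true_edits = as.integer(n_true_edits),
    n_per_artifact_class = as.integer(n_per_artifact_class),
    freq_range = freq_range,
    read_length = as.integer(read_length),
    homopolymer_run = as.integer(homopolymer_run),
    paralog_divergence = as.integer(paralog_divergence),
    tissues = tissues,
    stages = stages,
    n_per_cell = as.integer(n_per_cell),
    tissue_effects = tissue_effects,
    stage_effects = stage_effects,
    interaction_effects = interaction_effects,
    baseline_logit = baseline_logit,
    noise_sd = noise_sd
  )
  if (cfg$genome_length < 10000L) {
    abort("genome_length must be at least 10 kb to host the planted features")
  }
  if (cfg$homopolymer_run < 5L) {
    abort("homopolymer_run must be >= 5")
  }
  if (any(cfg$freq_range <= 0) || any(cfg$freq_range >= 1) ||
    cfg$freq_range[1] >= cfg$freq_range[2]) {
    abort("freq_range must be an increasing pair inside (0, 1)")
  }
  if (min(
    cfg$genome_length, cfg$n_replicates, cfg$dna_depth, cfg$rna_depth,
    cfg$error_rate, cfg$read_length, cfg$n_per_cell, cfg$noise_sd
  ) <= 0) {
    abort("simulation parameters must be positive")
  }
  structure(cfg, class = c("rdd_sim_config", "list"))
}

#' @export
print.rdd_filter_config <- function(x, ...) {
  cat("<rdd_filter_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' @export
print.rdd_sim_config <- function(x, ...) {
  cat("<rdd_sim_config>\n")
  scalars <- x[vapply(x, function(v) is.atomic(v) && length(v) <= 3, logical(1))]
  for (k in names(scalars)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(scalars[[k]]), collapse = ", ")))
  }
  invisible(x)
}
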