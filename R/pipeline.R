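# End-to-end orchestration: simulate a dataset to disk, run the detection
# cascade over on-disk inputs, and characterize a candidate set, each
# leaving a JSON run manifest for reproducibility.

write_manifest <- function(out_dir, step, seed, config, files, counts = list()) {
  manifest <- list(
    tool = "rddcascade",
    version = as.character(utils::packageVersion("rddcascade")),
    step = step,
    seed = seed,
    config = config,
    input_digests = as.list(tools::md5sum(unlist(files))),
    counts = counts
  )
  path <- file.path(out_dir, paste0("manifest_", step, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes the toy genome (`genome.fa`), annotation (`genes.gff3`), pileup
#' observations (`observations.tsv`), raw DNA reads (`dna_reads.fa`),
#' truth table (`truth.tsv`) and a run manifest into `out_dir`.
#'
#' @param config An [simulation_config()]; the seed is mandatory.
#' @param out_dir Output directory (created if absent).
#' @param classes Artifact classes to plant.
#' @return Named list of written paths, invisibly; the simulated objects
#'   are attached as the `"dataset"` attribute.
#' @export
pipeline_simulate <- function(config, out_dir, classes = ARTIFACT_CLASSES) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config, classes = classes)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    annotation = file.path(out_dir, "genes.gff3"),
    observations = file.path(out_dir, "observations.tsv"),
    dna_reads = file.path(out_dir, "dna_reads.fa"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_reference(ds$reference, paths$genome)
  write_annotation(ds$genes, paths$annotation)
  write_site_observations(ds$observations, paths$observations)
  write_dna_reads(ds$dna_reads, paths$dna_reads)
  write_truth(ds$truth, paths$truth)
  write_manifest(
    out_dir, "simulate", config$seed,
    config = unclass(config)[vapply(config, is.atomic, logical(1))],
    files = paths,
    counts = list(
      n_sites = nrow(ds$truth),
      n_observations = nrow(ds$observations),
      n_reads = nrow(ds$dna_reads)
    )
  )
  out <- paths
  attr(out, "dataset") <- ds
  invisible(out)
}

#' Run the detection cascade over on-disk inputs
#'
#' Reads the observation TSV (and, when given, the reference FASTA, GFF3
#' annotation and DNA-read FASTA), runs [run_cascade()], and writes the
#' surviving candidates as a VCF-like file plus the per-stage report and
#' per-candidate fate tables. Zero surviving candidates is a normal
#' outcome, not an error.
#'
#' @param observations Path to a site-observation TSV (or a tibble).
#' @param out_dir Output directory (created if absent).
#' @param reference,annotation,dna_reads Paths (or loaded objects), or
#'   `NULL` to skip the stages that need them.
#' @param cfg A [filter_config()].
#' @param truth Optional truth TSV path (or tibble); when given,
#'   sensitivity and precision against planted true edits are written into
#'   the manifest and returned.
#' @return The [run_cascade()] result list, with `paths` and (optionally)
#'   `recovery` added.
#' @export
pipeline_detect <- function(observations, out_dir, reference = NULL,
                            annotation = NULL, dna_reads = NULL,
                            cfg = filter_config(), truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_paths <- Filter(is.character, list(
    observations = observations, reference = reference,
    annotation = annotation, dna_reads = dna_reads
  ))
  if (is.character(observations)) observations <- read_site_observations(observations, cfg$max_coverage)
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(dna_reads)) dna_reads <- read_dna_reads(dna_reads)
  if (is.character(truth)) truth <- read_truth(truth)

  res <- run_cascade(observations, reference, annotation, dna_reads, cfg)
  candidates <- res$candidates
  if (!is.null(annotation) && nrow(candidates) > 0L && !is.null(reference)) {
    candidates <- annotate_candidates(candidates, annotation, reference, cfg)
  }
  res$candidates <- candidates

  paths <- list(
    candidates = file.path(out_dir, "candidates.vcf"),
    report = file.path(out_dir, "filter_report.tsv"),
    fates = file.path(out_dir, "candidate_fates.tsv")
  )
  write_candidates(candidates, paths$candidates)
  write_filter_report(res$report, paths$report)
  readr::write_tsv(res$fates, paths$fates, progress = FALSE)

  counts <- as.list(setNames(res$report$surviving, res$report$stage))
  if (!is.null(truth)) {
    res$recovery <- compare_truth(candidates, truth)
    counts <- c(counts, as.list(res$recovery))
    inform(sprintf(
      "recovery vs truth: sensitivity %.3f, precision %.3f (tp %d, fp %d, fn %d)",
      res$recovery$sensitivity, res$recovery$precision,
      res$recovery$tp, res$recovery$fp, res$recovery$fn
    ))
  }
  write_manifest(
    out_dir, "detect",
    seed = NA, config = unclass(cfg),
    files = c(in_paths, paths), counts = counts
  )
  res$paths <- paths
  res
}

#' Characterize a candidate set
#'
#' Computes the base-change spectrum, clusters (at
#' `cfg$cluster_max_gap`), cluster statistics and the gene summary - and,
#' when a measurements table is supplied, the tissue x stage ANOVA - and
#' writes each as TSV.
#'
#' @param candidates Candidate tibble, or path to a VCF-like candidate
#'   file from [write_candidates()].
#' @param out_dir Output directory (created if absent).
#' @param measurements Optional editing-level tibble (or TSV path) with
#'   `tissue`, `stage`, `editing_level`.
#' @param cfg A [filter_config()].
#' @return List with `spectrum`, `clusters`, `cluster_stats`, `genes`,
#'   optional `anova`, and `paths`.
#' @export
pipeline_characterize <- function(candidates, out_dir, measurements = NULL,
                                  cfg = filter_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_paths <- Filter(is.character, list(candidates = candidates))
  if (is.character(candidates)) candidates <- read_candidates(candidates)
  if (is.character(measurements)) {
    measurements <- readr::read_tsv(measurements, show_col_types = FALSE)
  }
  spectrum <- change_spectrum(candidates)
  clusters <- find_clusters(candidates, cfg$cluster_max_gap)
  genes <- summarize_genes(candidates)
  out <- list(
    spectrum = spectrum,
    clusters = clusters,
    cluster_stats = if (nrow(clusters)) cluster_statistics(clusters) else NULL,
    genes = genes
  )
  paths <- list(
    spectrum = file.path(out_dir, "spectrum.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    genes = file.path(out_dir, "genes.tsv")
  )
  readr::write_tsv(as_tibble(spectrum), paths$spectrum, progress = FALSE)
  readr::write_tsv(
    clusters |>
      mutate(
        positions = format_offsets(.data$positions),
        gaps = format_offsets(.data$gaps)
      ),
    paths$clusters,
    progress = FALSE
  )
  readr::write_tsv(
    genes |> mutate(positions = map_chr(.data$positions, paste, collapse = ",")),
    paths$genes,
    progress = FALSE
  )
  if (!is.null(out$cluster_stats)) {
    paths$cluster_stats <- file.path(out_dir, "cluster_stats.tsv")
    readr::write_tsv(out$cluster_stats, paths$cluster_stats, progress = FALSE)
  }
  if (!is.null(measurements)) {
    out$anova <- anova_tissue_stage(measurements)
    paths$anova <- file.path(out_dir, "anova.tsv")
    write_anova(out$anova, paths$anova)
  }
  write_manifest(
    out_dir, "characterize",
    seed = NA, config = unclass(cfg),
    files = c(in_paths, paths),
    counts = list(
      n_candidates = nrow(candidates),
      n_clusters = nrow(clusters),
      n_genes = nrow(genes)
    )
  )
  out$paths <- paths
  out
}
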