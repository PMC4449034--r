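# Per-replicate RDD calling: the genotype contrast (DNA homozygous, RNA
# heterozygous) and the read-depth threshold, followed by aggregation of
# calls into per-position candidates.

#' Call RNA-DNA differences per replicate
#'
#' A replicate observation yields a call when (i) its DNA genotype is
#' provisionally homozygous (major allele fraction at or above
#' `dna_hom_fraction`; the strict zero-count rule is applied cascade-wide
#' by [dna_alt_zero()]), (ii) the RNA is heterozygous - it carries the DNA
#' allele and an alternative allele, both at or above the heterozygosity
#' floor (`het_min_fraction` of reads and `het_min_count` reads), and
#' (iii) both DNA and RNA depth reach `min_depth`. The edited allele is the
#' majority non-DNA allele in RNA; whether additional low-level alleles
#' disqualify the site is the job of the downstream biallelic filter.
#' Absence of a call is a value, not an error.
#'
#' @param obs Site-observation tibble (see [read_site_observations()]).
#' @param cfg A [filter_config()].
#' @return Tibble of calls: `replicate_id`, `chrom`, `pos`, `ref`,
#'   `dna_allele`, `dna_genotype` (`hom_ref`/`hom_alt`), `edited_allele`,
#'   `rna_depth`, `edited_count`, `rna_edited_fraction`, `passes_depth`,
#'   plus the strand/offset evidence columns carried through for pooling.
#' @export
call_replicates <- function(obs, cfg = filter_config()) {
  validate_site_observations(obs)
  n <- nrow(obs)
  empty <- tibble(
    replicate_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), dna_allele = character(0), dna_genotype = character(0),
    edited_allele = character(0), rna_depth = integer(0),
    edited_count = integer(0), rna_edited_fraction = numeric(0)
  )
  if (n == 0L) {
    return(empty)
  }
  dna <- as.matrix(obs[, paste0("dna", DNA_BASES)])
  rna <- as.matrix(obs[, paste0("rna", DNA_BASES)])
  dna_depth <- rowSums(dna)
  rna_depth <- rowSums(rna)
  major_idx <- max.col(dna, ties.method = "first")
  dna_allele <- DNA_BASES[major_idx]
  major_count <- dna[cbind(seq_len(n), major_idx)]
  is_hom <- dna_depth > 0 & major_count / dna_depth >= cfg$dna_hom_fraction

  # majority non-DNA allele in RNA
  rna_masked <- rna
  rna_masked[cbind(seq_len(n), major_idx)] <- -1L
  alt_idx <- max.col(rna_masked, ties.method = "first")
  edited_allele <- DNA_BASES[alt_idx]
  edited_count <- rna[cbind(seq_len(n), alt_idx)]
  dna_allele_rna_count <- rna[cbind(seq_len(n), major_idx)]

  ok_het <- rna_depth > 0 &
    edited_count >= cfg$het_min_count &
    edited_count / pmax(rna_depth, 1L) >= cfg$het_min_fraction &
    dna_allele_rna_count >= cfg$het_min_count &
    dna_allele_rna_count / pmax(rna_depth, 1L) >= cfg$het_min_fraction
  passes_depth <- dna_depth >= cfg$min_depth & rna_depth >= cfg$min_depth
  keep <- is_hom & ok_het & passes_depth

  out <- obs[keep, ]
  out$dna_allele <- dna_allele[keep]
  out$dna_genotype <- ifelse(out$dna_allele == out$ref, "hom_ref", "hom_alt")
  out$edited_allele <- edited_allele[keep]
  out$rna_depth <- as.integer(rna_depth[keep])
  out$edited_count <- as.integer(edited_count[keep])
  out$rna_edited_fraction <- out$edited_count / out$rna_depth
  out
}

#' Aggregate replicate calls into candidates
#'
#' Groups calls sharing (chromosome, position, edited allele) and pools the
#' supporting evidence: alt-read offsets, per-strand alt and coverage
#' counts, and RNA allele counts, along with per-candidate depth and
#' frequency summaries. Offset and strand evidence is pooled only from
#' replicates whose candidate alternative allele column matches the edited
#' allele (it always does for homozygous-reference sites).
#'
#' @param calls Output of [call_replicates()].
#' @return Candidate tibble, one row per (chrom, pos, edited allele).
#' @export
aggregate_candidates <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble(
      chrom = character(0), pos = integer(0), ref = character(0),
      dna_allele = character(0), edited_allele = character(0),
      n_edited_replicates = integer(0), replicate_ids = list(),
      read_length = integer(0), alt_offsets = list(),
      alt_fwd = integer(0), alt_rev = integer(0),
      cov_fwd = integer(0), cov_rev = integer(0),
      rnaA = integer(0), rnaC = integer(0), rnaG = integer(0),
      rnaT = integer(0),
      mean_depth = numeric(0), sd_depth = numeric(0),
      mean_freq = numeric(0), sd_freq = numeric(0)
    ))
  }
  calls |>
    mutate(.alt_is_edited = .data$alt_base == .data$edited_allele) |>
    group_by(.data$chrom, .data$pos, .data$edited_allele) |>
    summarise(
      ref = first(.data$ref),
      dna_allele = first(.data$dna_allele),
      n_edited_replicates = dplyr::n(),
      replicate_ids = list(.data$replicate_id),
      read_length = max(.data$read_length),
      alt_offsets = list(sort(unlist(.data$alt_offsets[.data$.alt_is_edited]))),
      alt_fwd = sum(.data$alt_fwd[.data$.alt_is_edited]),
      alt_rev = sum(.data$alt_rev[.data$.alt_is_edited]),
      cov_fwd = sum(.data$cov_fwd[.data$.alt_is_edited]),
      cov_rev = sum(.data$cov_rev[.data$.alt_is_edited]),
      rnaA = sum(.data$rnaA), rnaC = sum(.data$rnaC),
      rnaG = sum(.data$rnaG), rnaT = sum(.data$rnaT),
      mean_depth = mean(.data$rna_depth),
      sd_depth = ifelse(dplyr::n() > 1L, stats::sd(.data$rna_depth), 0),
      mean_freq = mean(.data$rna_edited_fraction),
      sd_freq = ifelse(dplyr::n() > 1L, stats::sd(.data$rna_edited_fraction), 0),
      .groups = "drop"
    ) |>
    select(
      "chrom", "pos", "ref", "dna_allele", "edited_allele",
      "n_edited_replicates", "replicate_ids", "read_length", "alt_offsets",
      "alt_fwd", "alt_rev", "cov_fwd", "cov_rev",
      "rnaA", "rnaC", "rnaG", "rnaT",
      "mean_depth", "sd_depth", "mean_freq", "sd_freq"
    ) |>
    arrange(.data$chrom, .data$pos)
}

#' Strict DNA alternative-allele zero-count rule
#'
#' For each candidate, `TRUE` when the edited allele is absent from the DNA
#' of every replicate at the position - edited or not. When DNA is
#' homozygous for a non-reference allele the rule is evaluated against the
#' non-DNA ("edited") allele, which may be the reference base.
#'
#' @param candidates Candidate tibble from [aggregate_candidates()].
#' @param obs The full site-observation tibble (all replicates).
#' @return Logical vector, one element per candidate.
#' @export
dna_alt_zero <- function(candidates, obs) {
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  dna_tot <- obs |>
    tidyr::pivot_longer(
      all_of(paste0("dna", DNA_BASES)),
      names_to = "base", names_prefix = "dna", values_to = "count"
    ) |>
    group_by(.data$chrom, .data$pos, .data$base) |>
    summarise(count = sum(.data$count), .groups = "drop")
  joined <- left_join(
    select(candidates, "chrom", "pos", base = "edited_allele"),
    dna_tot,
    by = c("chrom", "pos", "base")
  )
  cnt <- joined$count
  cnt[is.na(cnt)] <- 0L
  cnt == 0L
}
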