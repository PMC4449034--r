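# Post-cascade biology: base-change spectrum with strand collapsing,
# clustering of nearby edited sites, gene summaries and editing levels.

#' Classify a DNA-to-RNA base change
#'
#' Because sequencing is not strand-specific, a change and its complement
#' are the same event: the 12 ordered base pairs collapse to 6 labels (the
#' orientation whose DNA base is A or C is the representative). Canonical
#' changes are those consistent with known editing chemistry: A>G (A-to-I)
#' and C>T (C-to-U), together with their complements T>C and G>A.
#'
#' @param dna_base,rdd_base Character vectors of DNA and RNA bases
#'   (recycled to a common length); elements must differ pairwise.
#' @return Tibble with columns `dna_base`, `rdd_base`, `collapsed_label`,
#'   `is_canonical`.
#' @examples
#' classify_change("T", "C")
#' @export
classify_change <- function(dna_base, rdd_base) {
  n <- max(length(dna_base), length(rdd_base))
  dna_base <- rep_len(dna_base, n)
  rdd_base <- rep_len(rdd_base, n)
  if (any(!is_base(dna_base)) || any(!is_base(rdd_base))) {
    abort("bases must be one of A, C, G, T")
  }
  if (any(dna_base == rdd_base)) {
    abort("dna_base and rdd_base must differ")
  }
  flip <- !dna_base %in% c("A", "C")
  d <- ifelse(flip, comp_base(dna_base), dna_base)
  r <- ifelse(flip, comp_base(rdd_base), rdd_base)
  label <- paste0(d, ">", r)
  tibble(
    dna_base = dna_base, rdd_base = rdd_base,
    collapsed_label = label,
    is_canonical = label %in% c("A>G", "C>T")
  )
}

#' Base-change spectrum of a candidate set
#'
#' @param candidates Tibble with `dna_base` and `rdd_base` columns.
#' @return Tibble of class `rdd_change_spectrum` with one row per observed
#'   collapsed label: `collapsed_label`, `is_canonical`, `n`, `proportion`
#'   (summing to 1).
#' @export
change_spectrum <- function(candidates) {
  if (nrow(candidates) == 0L) {
    abort("cannot compute a change spectrum from an empty candidate set")
  }
  out <- classify_change(candidates$dna_base, candidates$rdd_base) |>
    count(.data$collapsed_label, .data$is_canonical, name = "n") |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$n))
  class(out) <- c("rdd_change_spectrum", class(out))
  out
}

#' Canonical fraction of a candidate set
#'
#' @inheritParams change_spectrum
#' @return Proportion of candidates whose change is canonical.
#' @export
canonical_fraction <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(NA_real_)
  }
  mean(classify_change(candidates$dna_base, candidates$rdd_base)$is_canonical)
}

#' Find clusters of edited sites
#'
#' A single linear scan per chromosome groups consecutive sites whose
#' inter-site distance is at most `max_gap`; maximal groups of two or more
#' sites are clusters, singletons are not. Edited sites clustering within
#' a few hundred bases is a known signature of ADAR acting along
#' double-stranded RNA regions.
#'
#' @param candidates Tibble with `chrom` and `pos` columns (one row per
#'   site; duplicated positions are collapsed).
#' @param max_gap Maximum distance in bases between consecutive cluster
#'   members.
#' @return Tibble with one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end`, `size`, `span` (`end - start`), and list columns
#'   `positions` and `gaps` (consecutive inter-site distances).
#' @export
find_clusters <- function(candidates, max_gap = 1000L) {
  sites <- distinct(candidates, .data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(sites) == 0L) {
    return(tibble(
      cluster_id = integer(0), chrom = character(0),
      start = integer(0), end = integer(0), size = integer(0),
      span = integer(0), positions = list(), gaps = list()
    ))
  }
  sites <- sites |>
    group_by(.data$chrom) |>
    mutate(
      gap = .data$pos - lag(.data$pos),
      new_run = is.na(.data$gap) | .data$gap > max_gap
    ) |>
    ungroup() |>
    mutate(run = cumsum(.data$new_run))
  out <- sites |>
    group_by(.data$run) |>
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$pos), end = max(.data$pos),
      size = dplyr::n(),
      positions = list(.data$pos),
      gaps = list(diff(.data$pos)),
      .groups = "drop"
    ) |>
    filter(.data$size >= 2L) |>
    mutate(span = .data$end - .data$start, cluster_id = row_number()) |>
    select(
      "cluster_id", "chrom", "start", "end", "size", "span",
      "positions", "gaps"
    )
  out
}

#' Summary statistics over a cluster set
#'
#' @param clusters Cluster tibble from [find_clusters()].
#' @return One-row tibble: `n_clusters`, `size_min`, `size_max`,
#'   `span_min`, `span_max`, `gap_min`, `gap_max` (intra-cluster
#'   consecutive-site distances).
#' @export
cluster_statistics <- function(clusters) {
  if (nrow(clusters) == 0L) {
    abort("no clusters to summarise")
  }
  gaps <- unlist(clusters$gaps)
  tibble(
    n_clusters = nrow(clusters),
    size_min = min(clusters$size), size_max = max(clusters$size),
    span_min = min(clusters$span), span_max = max(clusters$span),
    gap_min = min(gaps), gap_max = max(gaps)
  )
}

#' Summarise genes impacted by a candidate set
#'
#' A site may be associated with several genes (space-separated
#' identifiers); intergenic sites (`"-"` or missing) contribute none. Gene
#' identity is the (Ensembl-style) gene identifier, so unnamed novel genes
#' count as distinct genes.
#'
#' @param candidates Tibble with `gene_id` (space-separated ids), optional
#'   `gene_name`, and `chrom`, `pos`.
#' @return Tibble with one row per distinct gene: `gene_id`, `gene_name`,
#'   `n_sites`, and a `positions` list column. The distinct gene count is
#'   `nrow()` of the result.
#' @export
summarize_genes <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(tibble(
      gene_id = character(0), gene_name = character(0),
      n_sites = integer(0), positions = list()
    ))
  }
  gene_name <- if ("gene_name" %in% names(candidates)) {
    candidates$gene_name
  } else {
    NA_character_
  }
  long <- tibble(
    chrom = candidates$chrom, pos = candidates$pos,
    gene_id = candidates$gene_id %||% NA_character_,
    gene_name = gene_name
  ) |>
    mutate(
      gene_id = strsplit(ifelse(is.na(.data$gene_id), "", .data$gene_id), "\\s+"),
      gene_name = strsplit(ifelse(is.na(.data$gene_name), "", .data$gene_name), "\\s+")
    )
  # align names with ids positionally; pad when a shared name spans ids
  long <- long |>
    mutate(gene_name = map2(.data$gene_id, .data$gene_name, function(id, nm) {
      if (length(nm) == length(id)) nm else rep_len(paste(nm, collapse = " "), length(id))
    })) |>
    tidyr::unnest(c("gene_id", "gene_name")) |>
    filter(!.data$gene_id %in% c("", "-"))
  long |>
    group_by(.data$gene_id) |>
    summarise(
      gene_name = first(.data$gene_name),
      n_sites = dplyr::n(),
      positions = list(paste0(.data$chrom, ":", .data$pos)),
      .groups = "drop"
    )
}

#' Editing level of observations
#'
#' The fraction of RNA reads carrying the edited allele. When an assay
#' reads the opposite strand (e.g. pyrosequencing a T>C site through its
#' reverse complement, reporting A and G), supply the complementary allele
#' actually counted.
#'
#' @param obs Site-observation tibble (see [read_site_observations()]).
#' @param allele Edited allele per observation; defaults to `alt_base`.
#' @return Numeric vector of editing levels in `[0, 1]`.
#' @export
editing_level <- function(obs, allele = obs$alt_base) {
  depth <- obs$rnaA + obs$rnaC + obs$rnaG + obs$rnaT
  if (any(depth == 0L)) {
    abort("editing level is undefined at zero RNA depth")
  }
  rna_count(obs, allele) / depth
}

#' Score cascade survivors against a simulation truth table
#'
#' @param candidates Final candidate tibble from [run_cascade()].
#' @param truth Truth tibble from [plant_truth()].
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity` (on planted
#'   true edits), `precision`.
#' @export
compare_truth <- function(candidates, truth) {
  true_sites <- filter(truth, .data$planted_class == "true_edit")
  hit <- semi_join(
    true_sites,
    select(candidates, "chrom", "pos", edited_allele = "rdd_base"),
    by = c("chrom", "pos", "edited_allele")
  )
  tp <- nrow(hit)
  fp <- nrow(anti_join(
    select(candidates, "chrom", "pos"),
    select(true_sites, "chrom", "pos"),
    by = c("chrom", "pos")
  ))
  tibble(
    tp = tp, fp = fp, fn = nrow(true_sites) - tp,
    sensitivity = if (nrow(true_sites)) tp / nrow(true_sites) else NA_real_,
    precision = if (nrow(candidates)) tp / nrow(candidates) else NA_real_
  )
}
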