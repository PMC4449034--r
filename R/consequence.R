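# Minimal functional-consequence classifier over the package's gene
# models: enough to place a site in the gene architecture and translate
# the affected codon. Full transcript-aware effect prediction (VEP) is a
# different tool's job.

# Spliced CDS of one gene as (sequence, per-base genomic coordinates in
# translation order).
spliced_cds <- function(gene, reference) {
  cds <- arrange(filter(gene, .data$type == "CDS"), .data$start)
  if (nrow(cds) == 0L) {
    return(NULL)
  }
  coords <- unlist(map2(cds$start, cds$end, seq))
  seq <- paste(
    map_chr(seq_len(nrow(cds)), function(i) {
      ref_slice(reference, cds$chrom[i], cds$start[i], cds$end[i])
    }),
    collapse = ""
  )
  if (gene$strand[1] == "-") {
    seq <- revcomp(seq)
    coords <- rev(coords)
  }
  list(seq = seq, coords = coords)
}

classify_coding_change <- function(gene, reference, pos, allele) {
  cds <- spliced_cds(gene, reference)
  k <- match(pos, cds$coords)
  base <- if (gene$strand[1] == "-") comp_base(allele) else allele
  codon_i <- (k - 1L) %/% 3L
  codon <- substr(cds$seq, 3L * codon_i + 1L, 3L * codon_i + 3L)
  alt_codon <- seq_substitute(codon, k - 3L * codon_i, base)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa == alt_aa) "synonymous" else "missense"
}

#' Classify the functional consequence of an edited site
#'
#' Places a position in the gene architecture of every overlapping or
#' flanking gene model and reports one or more of: `intergenic`,
#' `upstream_gene`, `downstream_gene`, `intron`, `5_prime_UTR`,
#' `3_prime_UTR`, `non_coding_exon`, `splice_region`, `synonymous`,
#' `missense`. Coding calls translate the affected codon on the gene
#' strand; splice-region terms use the same exonic/intronic windows as the
#' splice filter, here at coding and non-coding boundaries alike.
#'
#' @param chrom,pos Site coordinates (scalars).
#' @param edited_allele Edited base (scalar).
#' @param genes Annotation tibble (see [read_annotation()]).
#' @param reference Named list of reference sequences.
#' @param cfg A [filter_config()] (flank and splice window widths).
#' @return Character vector of consequence terms.
#' @export
classify_consequence <- function(chrom, pos, edited_allele, genes, reference,
                                 cfg = filter_config()) {
  if (!chrom %in% genes$chrom && is.null(reference[[chrom]])) {
    abort(sprintf("chromosome '%s' unknown to both annotation and reference", chrom))
  }
  terms <- character(0)
  for (gid in unique(genes$gene_id[genes$chrom == chrom])) {
    gene <- filter(genes, .data$gene_id == gid)
    gs <- min(gene$start)
    ge <- max(gene$end)
    if (pos < gs - cfg$flank_bp || pos > ge + cfg$flank_bp) next
    plus <- gene$strand[1] == "+"
    if (pos < gs) {
      terms <- c(terms, if (plus) "upstream_gene" else "downstream_gene")
      next
    }
    if (pos > ge) {
      terms <- c(terms, if (plus) "downstream_gene" else "upstream_gene")
      next
    }
    ex <- filter(gene, .data$type == "exon")
    cds <- filter(gene, .data$type == "CDS")
    in_iv <- function(tbl) {
      nrow(tbl) > 0L && any(tbl$start <= pos & tbl$end >= pos)
    }
    if (in_iv(cds)) {
      terms <- c(terms, classify_coding_change(gene, reference, pos, edited_allele))
    } else if (in_iv(ex)) {
      if (nrow(cds) == 0L) {
        terms <- c(terms, "non_coding_exon")
      } else {
        cds_lo <- min(cds$start)
        cds_hi <- max(cds$end)
        five <- if (plus) pos < cds_lo else pos > cds_hi
        terms <- c(terms, if (five) "5_prime_UTR" else "3_prime_UTR")
      }
    } else {
      terms <- c(terms, "intron")
    }
    win <- noncoding_splice_windows(gene, cfg, coding_too = TRUE)
    if (nrow(win) > 0L && any(win$start <= pos & win$end >= pos)) {
      terms <- c(terms, "splice_region")
    }
  }
  if (length(terms) == 0L) "intergenic" else unique(terms)
}

#' Annotate candidates with genes and consequences
#'
#' Adds `gene_id`, `gene_name` (space-separated over overlapping genes,
#' `"-"` when intergenic) and `consequence` (comma-separated terms)
#' columns to a candidate tibble.
#'
#' @param candidates Candidate tibble with `chrom`, `pos` and `rdd_base`
#'   (or `edited_allele`) columns.
#' @param genes Annotation tibble.
#' @param reference Named list of reference sequences.
#' @param cfg A [filter_config()].
#' @return The candidate tibble with annotation columns added.
#' @export
annotate_candidates <- function(candidates, genes, reference,
                                cfg = filter_config()) {
  allele <- candidates$rdd_base %||% candidates$edited_allele
  ann <- map(seq_len(nrow(candidates)), function(i) {
    terms <- classify_consequence(
      candidates$chrom[i], candidates$pos[i], allele[i],
      genes, reference, cfg
    )
    gh <- filter(
      genes,
      .data$chrom == candidates$chrom[i],
      .data$gene_id %in% unique(genes$gene_id)
    ) |>
      group_by(.data$gene_id) |>
      summarise(
        gene_name = first(.data$gene_name),
        gs = min(.data$start), ge = max(.data$end),
        .groups = "drop"
      ) |>
      filter(
        .data$gs - cfg$flank_bp <= candidates$pos[i],
        .data$ge + cfg$flank_bp >= candidates$pos[i]
      )
    tibble(
      gene_id = if (nrow(gh)) paste(gh$gene_id, collapse = " ") else "-",
      gene_name = if (nrow(gh)) paste(gh$gene_name, collapse = " ") else "-",
      consequence = paste(terms, collapse = ",")
    )
  })
  bind_cols(candidates, list_rbind(ann))
}
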