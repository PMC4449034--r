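# Packaged fixture: the 36 final RDD candidates of the chicken embryo
# screen, transcribed from the published candidate table.

FIXTURE_MD5 <- "91c684453b110e0a68cfe4a1b6075d78"

#' Load the packaged chicken RDD candidate table
#'
#' Returns the 36 final RNA-DNA difference candidates of the chicken embryo
#' screen (matched DNA/RNA sequencing of 8 embryos, Galgal4 coordinates),
#' with their edited alleles, gene annotations, predicted consequences,
#' replicate support, and mean sequencing depth and editing frequency.
#' Multi-gene sites carry space-separated gene identifiers; intergenic sites
#' carry `"-"`. The `tested` column flags candidates taken forward to
#' orthogonal validation.
#'
#' @return Tibble with 36 rows and columns `chrom`, `pos`, `dna_base`,
#'   `rdd_base`, `gene_id`, `gene_name`, `consequence`,
#'   `n_edited_replicates`, `mean_depth`, `sd_depth`, `mean_freq`,
#'   `sd_freq`, `tested`.
#' @examples
#' cand <- load_final_candidates()
#' nrow(cand)
#' @export
load_final_candidates <- function() {
  path <- system.file(
    "extdata", "rdd_candidates_gallus.tsv",
    package = "rddcascade", mustWork = TRUE
  )
  if (unname(tools::md5sum(path)) != FIXTURE_MD5) {
    abort("packaged candidate table is corrupted (checksum mismatch)")
  }
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      n_edited_replicates = readr::col_integer(),
      tested = readr::col_logical(),
      mean_depth = readr::col_double(),
      sd_depth = readr::col_double(),
      mean_freq = readr::col_double(),
      sd_freq = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  stopifnot(
    nrow(out) == 36L,
    nrow(distinct(out, .data$chrom, .data$pos)) == 36L,
    all(out$dna_base != out$rdd_base),
    all(out$n_edited_replicates >= 2L & out$n_edited_replicates <= 8L),
    all(out$mean_freq > 0 & out$mean_freq < 1)
  )
  out
}
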