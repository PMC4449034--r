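# VCF-like serialization of candidate tables. The file carries a VCFv4.2
# header and one data line per candidate; pipeline-specific fields travel in
# INFO so the table round-trips losslessly through read_candidates().

vcf_info_keys <- c(
  NREP = "Number of biological replicates supporting the edited allele",
  MEANFREQ = "Mean edited-allele frequency across supporting replicates",
  FREQSD = "Standard deviation of the edited-allele frequency",
  DEPTH = "Mean RNA depth across supporting replicates",
  DEPTHSD = "Standard deviation of the RNA depth",
  GENEID = "Overlapping or flanking gene identifier(s)",
  GENENAME = "Gene short name(s)",
  CSQ = "Predicted consequence term(s)",
  FILTERFATE = "Per-stage filter fate (stage:pass/fail, cascade order)"
)

vcf_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(" ", "%20", x, fixed = TRUE)
}

vcf_decode <- function(x) {
  x <- gsub("%20", " ", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Write a candidate table as a VCF-like file
#'
#' @param candidates Candidate tibble with at least `chrom`, `pos`,
#'   `dna_base`, `rdd_base`, `n_edited_replicates`, `mean_freq`; optional
#'   `sd_freq`, `mean_depth`, `sd_depth`, `gene_id`, `gene_name`,
#'   `consequence`, `fate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rddcascade",
    sprintf(
      "##INFO=<ID=%s,Number=.,Type=String,Description=\"%s\">",
      names(vcf_info_keys), vcf_info_keys
    ),
    paste(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      sep = "\t"
    )
  )
  opt <- function(col) {
    if (col %in% names(candidates)) as.character(candidates[[col]]) else NULL
  }
  lines <- hdr
  if (nrow(candidates) > 0L) {
    info_fields <- list(
      NREP = as.character(candidates$n_edited_replicates),
      MEANFREQ = as.character(candidates$mean_freq),
      FREQSD = opt("sd_freq"),
      DEPTH = opt("mean_depth"),
      DEPTHSD = opt("sd_depth"),
      GENEID = opt("gene_id"),
      GENENAME = opt("gene_name"),
      CSQ = opt("consequence"),
      FILTERFATE = opt("fate")
    )
    info_fields <- info_fields[!vapply(info_fields, is.null, logical(1))]
    info <- vapply(seq_len(nrow(candidates)), function(i) {
      vals <- vapply(info_fields, `[[`, character(1), i)
      keep <- !is.na(vals)
      paste(names(info_fields)[keep], vcf_encode(vals[keep]),
        sep = "=", collapse = ";"
      )
    }, character(1))
    lines <- c(lines, paste(
      candidates$chrom, candidates$pos, ".",
      candidates$dna_base, candidates$rdd_base, ".", "PASS", info,
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path Path to the VCF-like candidate file.
#' @return Candidate tibble; zero rows for a header-only file.
#' @export
read_candidates <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    abort(sprintf("'%s' is not a VCF-like candidate file", path))
  }
  body <- lines[!startsWith(lines, "#")]
  empty <- tibble(
    chrom = character(0), pos = integer(0),
    dna_base = character(0), rdd_base = character(0),
    n_edited_replicates = integer(0), mean_freq = numeric(0)
  )
  if (length(body) == 0L) {
    return(empty)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  info <- map(fields, function(f) {
    kv <- strsplit(strsplit(f[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(
      vcf_decode(vapply(kv, function(p) p[2] %||% NA_character_, character(1))),
      vapply(kv, `[[`, character(1), 1)
    )
  })
  get_info <- function(key) map_chr(info, ~ .x[key] %||% NA_character_)
  out <- tibble(
    chrom = map_chr(fields, 1),
    pos = as.integer(map_chr(fields, 2)),
    dna_base = map_chr(fields, 4),
    rdd_base = map_chr(fields, 5),
    n_edited_replicates = as.integer(get_info("NREP")),
    mean_freq = as.numeric(get_info("MEANFREQ")),
    sd_freq = as.numeric(get_info("FREQSD")),
    mean_depth = as.numeric(get_info("DEPTH")),
    sd_depth = as.numeric(get_info("DEPTHSD")),
    gene_id = get_info("GENEID"),
    gene_name = get_info("GENENAME"),
    consequence = get_info("CSQ"),
    fate = get_info("FILTERFATE")
  )
  out[, colSums(is.na(out)) < nrow(out) | names(out) %in% names(empty)]
}
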