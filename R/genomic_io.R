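# Readers and writers for the pipeline's on-disk formats: FASTA references
# and raw DNA reads, GFF3 gene annotation, and the per-site per-replicate
# pileup TSV that is the canonical input of the detection cascade.

#' Read a reference genome from FASTA
#'
#' Sequences are returned upper-cased, as a named list of character strings
#' keyed by chromosome name (the first whitespace-delimited token of each
#' header).
#'
#' @param path Path to a FASTA file.
#' @param max_ambiguous_frac Maximum tolerated fraction of non-ACGT symbols
#'   per sequence before the file is rejected as malformed.
#' @return Named list of upper-case sequence strings.
#' @export
read_reference <- function(path, max_ambiguous_frac = 0.1) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    abort(sprintf("no records found in FASTA '%s'", path))
  }
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    abort(sprintf(
      "duplicate FASTA header(s): %s",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ))
  }
  out <- toupper(as.character(seqs))
  bad_frac <- vapply(out, function(s) {
    1 - sum(Biostrings::letterFrequency(
      Biostrings::DNAString(s), DNA_BASES
    )) / nchar(s)
  }, numeric(1))
  if (any(bad_frac > max_ambiguous_frac)) {
    abort(sprintf(
      "sequence(s) %s exceed the non-ACGT symbol cap (%.0f%%)",
      paste(nms[bad_frac > max_ambiguous_frac], collapse = ", "),
      100 * max_ambiguous_frac
    ))
  }
  setNames(as.list(out), nms)
}

#' Write a reference genome (or any named sequence set) as FASTA
#'
#' @param reference Named list or character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(unlist(reference))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read raw DNA sequencing reads
#'
#' Reads are tagged with the biological replicate they came from, taken from
#' the FASTA/FASTQ header formatted as `<replicate_id>:<read index>`.
#'
#' @param path FASTA or FASTQ file of reads.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return Tibble with columns `replicate_id`, `read`.
#' @export
read_dna_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  ids <- sub(":[^:]*$", "", sub("\\s.*$", "", names(seqs)))
  tibble(replicate_id = ids, read = unname(toupper(as.character(seqs))))
}

#' Write raw DNA reads as FASTA
#'
#' @param reads Tibble with columns `replicate_id`, `read`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dna_reads <- function(reads, path) {
  reads <- group_by(reads, .data$replicate_id)
  reads <- ungroup(mutate(reads, .idx = row_number()))
  seqs <- Biostrings::DNAStringSet(reads$read)
  names(seqs) <- paste0(reads$replicate_id, ":", reads$.idx)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

obs_columns <- c(
  "replicate_id", "chrom", "pos", "ref",
  "dnaA", "dnaC", "dnaG", "dnaT",
  "rnaA", "rnaC", "rnaG", "rnaT",
  "alt_base", "alt_fwd", "alt_rev", "cov_fwd", "cov_rev",
  "read_length", "alt_offsets"
)

parse_offsets <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

format_offsets <- function(x) {
  vapply(x, paste, character(1), collapse = ",")
}

rna_count <- function(obs, base) {
  col <- paste0("rna", base)
  vapply(seq_along(base), function(i) obs[[col[i]]][i], numeric(1))
}

dna_count <- function(obs, base) {
  col <- paste0("dna", base)
  vapply(seq_along(base), function(i) obs[[col[i]]][i], numeric(1))
}

#' Validate a site-observation tibble
#'
#' Enforces the pileup invariants: per-strand alt counts sum to the RNA count
#' of the alt allele, per-strand coverage sums to the RNA depth, and every
#' within-read offset lies in `[1, read_length]`. Violations are reported
#' with the offending row numbers.
#'
#' @param obs Tibble in the site-observation layout (see
#'   [read_site_observations()]).
#' @return `obs`, invisibly, if valid; otherwise an error.
#' @export
validate_site_observations <- function(obs) {
  missing <- setdiff(obs_columns, names(obs))
  if (length(missing) > 0L) {
    abort(paste0(
      "site observations are missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!is.list(obs$alt_offsets)) {
    abort("alt_offsets must be a list column of integer vectors")
  }
  fail <- function(rows, what) {
    abort(sprintf(
      "invalid site observation(s) [%s] at row(s) %s",
      what, paste(head(rows, 5L), collapse = ", ")
    ))
  }
  bad <- which(!is_base(obs$ref) | !is_base(obs$alt_base))
  if (length(bad)) fail(bad, "ref/alt_base not one of A,C,G,T")
  bad <- which(obs$pos < 1L)
  if (length(bad)) fail(bad, "pos < 1")
  alt_rna <- rna_count(obs, obs$alt_base)
  bad <- which(obs$alt_fwd + obs$alt_rev != alt_rna)
  if (length(bad)) {
    fail(bad, sprintf(
      "alt_fwd+alt_rev != RNA count of alt allele (e.g. %s:%d)",
      obs$chrom[bad[1]], obs$pos[bad[1]]
    ))
  }
  depth <- obs$rnaA + obs$rnaC + obs$rnaG + obs$rnaT
  bad <- which(obs$cov_fwd + obs$cov_rev != depth)
  if (length(bad)) fail(bad, "cov_fwd+cov_rev != RNA depth")
  bad <- which(map2_lgl(obs$alt_offsets, obs$read_length, function(off, rl) {
    length(off) > 0L && (min(off) < 1L || max(off) > rl)
  }))
  if (length(bad)) fail(bad, "alt offset outside [1, read_length]")
  invisible(obs)
}

#' Read per-site, per-replicate pileup observations
#'
#' The TSV dialect carries, for each biological replicate at each candidate
#' position: DNA and RNA allele counts, the candidate alternative allele,
#' its per-mapping-strand counts, per-strand total RNA coverage, the nominal
#' read length, and the 1-based within-read offsets (sequencing orientation)
#' of the RNA reads carrying the alternative allele.
#'
#' @param path Path to a tab-separated observation file.
#' @param max_coverage Sites whose DNA or RNA depth exceeds this cap trigger
#'   a warning; upstream pileup engines are expected to cap pileup depth.
#' @return Tibble with one row per replicate per site, `alt_offsets` as a
#'   list column, ordered by (chrom, pos, replicate_id).
#' @export
read_site_observations <- function(path, max_coverage = 10000L) {
  obs <- readr::read_tsv(
    path,
    col_types = readr::cols(
      replicate_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt_base = readr::col_character(),
      alt_offsets = readr::col_character(),
      read_length = readr::col_integer(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  missing <- setdiff(obs_columns, names(obs))
  if (length(missing) > 0L) {
    abort(sprintf(
      "'%s' is not in the site-observation dialect; missing column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  obs$alt_offsets <- parse_offsets(obs$alt_offsets)
  validate_site_observations(obs)
  depth_dna <- obs$dnaA + obs$dnaC + obs$dnaG + obs$dnaT
  depth_rna <- obs$rnaA + obs$rnaC + obs$rnaG + obs$rnaT
  over <- depth_dna > max_coverage | depth_rna > max_coverage
  if (any(over)) {
    warn(sprintf(
      "%d observation(s) exceed the %d-read coverage cap (first at %s:%d)",
      sum(over), max_coverage, obs$chrom[which(over)[1]], obs$pos[which(over)[1]]
    ))
  }
  arrange(obs, .data$chrom, .data$pos, .data$replicate_id)
}

#' Write site observations in the pipeline's TSV dialect
#'
#' @param obs Observation tibble (see [read_site_observations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_observations <- function(obs, path) {
  out <- obs[, obs_columns]
  out$alt_offsets <- format_offsets(out$alt_offsets)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Only `exon` and `CDS` features are used by the pipeline; each carries
#' `gene_id` and `gene_name` attributes. Intervals are 1-based closed.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `gene_name`, `chrom`, `strand`,
#'   `type`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  tibble(
    gene_id = as.character(gr$gene_id),
    gene_name = as.character(gr$gene_name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$gene_id, .data$type, .data$start)
}

#' Write gene annotation as GFF3
#'
#' Emits `gene`, `exon` and `CDS` features with `ID`/`Parent` links plus
#' `gene_id`/`gene_name` attributes so the file round-trips through
#' [read_annotation()].
#'
#' @param genes Annotation tibble (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  spans <- genes |>
    group_by(.data$gene_id) |>
    summarise(
      gene_name = first(.data$gene_name),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      type = "gene",
      .groups = "drop"
    )
  feat <- bind_rows(spans, genes) |>
    arrange(.data$chrom, .data$gene_id, .data$start)
  # CDS phase: bases to skip before the first complete codon, in
  # transcription order
  feat$phase <- NA_integer_
  for (gid in unique(feat$gene_id)) {
    i <- which(feat$gene_id == gid & feat$type == "CDS")
    if (length(i) == 0L) next
    if (feat$strand[i[1]] == "-") i <- rev(i)
    lens <- feat$end[i] - feat$start[i] + 1L
    feat$phase[i] <- as.integer((3L - cumsum(c(0L, head(lens, -1L))) %% 3L) %% 3L)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand,
    type = feat$type,
    source = "rddcascade",
    phase = feat$phase,
    ID = ifelse(feat$type == "gene", feat$gene_id, NA_character_),
    Parent = ifelse(feat$type == "gene", NA_character_, feat$gene_id),
    gene_id = feat$gene_id,
    gene_name = feat$gene_name
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
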