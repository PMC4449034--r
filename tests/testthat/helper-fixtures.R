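# In-code builders for small observation and candidate tables.

base_counts <- function(A = 0L, C = 0L, G = 0L, T = 0L) {
  c(A = A, C = C, G = G, T = T)
}

# One site-observation row with consistent strand/offset defaults.
make_obs <- function(replicate_id = "rep01", chrom = "c1", pos = 100L,
                     ref = "A",
                     dna = base_counts(A = 20L),
                     rna = base_counts(A = 12L, G = 8L),
                     alt = "G",
                     alt_fwd = NULL, alt_rev = NULL,
                     cov_fwd = NULL, cov_rev = NULL,
                     read_length = 100L, offsets = NULL) {
  na <- unname(rna[alt])
  depth <- sum(rna)
  if (is.null(alt_fwd)) alt_fwd <- na %/% 2L
  if (is.null(alt_rev)) alt_rev <- na - alt_fwd
  if (is.null(cov_fwd)) cov_fwd <- alt_fwd + (depth - na) %/% 2L
  if (is.null(cov_rev)) cov_rev <- depth - cov_fwd
  if (is.null(offsets)) {
    offsets <- if (na > 0L) as.integer(round(seq(30, 70, length.out = na))) else integer(0)
  }
  tibble::tibble(
    replicate_id = replicate_id, chrom = chrom, pos = as.integer(pos),
    ref = ref,
    dnaA = unname(dna["A"]), dnaC = unname(dna["C"]),
    dnaG = unname(dna["G"]), dnaT = unname(dna["T"]),
    rnaA = unname(rna["A"]), rnaC = unname(rna["C"]),
    rnaG = unname(rna["G"]), rnaT = unname(rna["T"]),
    alt_base = alt, alt_fwd = as.integer(alt_fwd),
    alt_rev = as.integer(alt_rev),
    cov_fwd = as.integer(cov_fwd), cov_rev = as.integer(cov_rev),
    read_length = as.integer(read_length),
    alt_offsets = list(as.integer(offsets))
  )
}

# A candidate row in the aggregate_candidates() layout, for exercising the
# pooled filters directly.
make_cand <- function(chrom = "c1", pos = 100L, ref = "A",
                      dna_allele = ref, edited_allele = "G",
                      n_reps = 2L, replicate_ids = paste0("rep0", 1:n_reps),
                      read_length = 100L,
                      offsets = c(40L, 50L, 60L),
                      alt_fwd = 10L, alt_rev = 8L,
                      cov_fwd = 20L, cov_rev = 20L,
                      rna = base_counts(A = 22L, G = 18L),
                      mean_freq = 0.45) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    dna_allele = dna_allele, edited_allele = edited_allele,
    n_edited_replicates = as.integer(n_reps),
    replicate_ids = list(replicate_ids),
    read_length = as.integer(read_length),
    alt_offsets = list(as.integer(offsets)),
    alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
    cov_fwd = as.integer(cov_fwd), cov_rev = as.integer(cov_rev),
    rnaA = unname(rna["A"]), rnaC = unname(rna["C"]),
    rnaG = unname(rna["G"]), rnaT = unname(rna["T"]),
    mean_depth = sum(rna), sd_depth = 0,
    mean_freq = mean_freq, sd_freq = 0
  )
}

# A one-gene annotation: coding (+ strand) unless cds is NULL.
make_gene <- function(gene_id = "G1", gene_name = "g1", chrom = "c1",
                      strand = "+",
                      exons = list(c(101L, 200L), c(301L, 400L)),
                      cds = NULL) {
  iv_tbl <- function(ivs, type) {
    tibble::tibble(
      gene_id = gene_id, gene_name = gene_name, chrom = chrom,
      strand = strand, type = type,
      start = vapply(ivs, `[[`, integer(1), 1L),
      end = vapply(ivs, `[[`, integer(1), 2L)
    )
  }
  out <- iv_tbl(exons, "exon")
  if (!is.null(cds)) out <- dplyr::bind_rows(out, iv_tbl(cds, "CDS"))
  out
}

# First failing stage per planted truth site, given a cascade result;
# "depth_genotype" when the site never became a candidate, "passed" when
# it survived the whole cascade.
removal_stage <- function(result, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    id <- paste0(truth$chrom[i], ":", truth$pos[i], ":", truth$edited_allele[i])
    f <- result$fates[result$fates$candidate == id, ]
    if (nrow(f) == 0L) {
      return("depth_genotype")
    }
    fails <- f$stage[f$result == "fail"]
    if (length(fails)) fails[1] else "passed"
  }, character(1))
}
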