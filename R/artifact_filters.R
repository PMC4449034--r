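# The ordered artifact-filter cascade with per-stage accounting. Each
# post-support filter is a pure predicate of a candidate and the loaded
# resources, so the final surviving set does not depend on stage order;
# only the per-stage report does.

cascade_stage_names <- c(
  "depth_genotype", "dna_alt_zero", "replicate_support",
  "read_extremity", "strand_bias", "biallelic",
  "splice_region", "homopolymer", "dna_pattern"
)

#' Cascade stage names in canonical order
#' @return Character vector of the 9 stage names.
#' @export
cascade_stages <- function() cascade_stage_names

#' Replicate-support filter
#'
#' Keeps candidates carried by at least `min_replicates` biological
#' replicates sharing both position and edited allele.
#'
#' @param candidates Candidate tibble from [aggregate_candidates()].
#' @param cfg A [filter_config()].
#' @return The filtered candidate tibble.
#' @export
replicate_support <- function(candidates, cfg = filter_config()) {
  filter(candidates, .data$n_edited_replicates >= cfg$min_replicates)
}

#' Read-extremity (median alt-offset) filter
#'
#' A candidate fails when the median within-read offset of its pooled
#' alt-carrying reads lies in the first or last `end_window` bases of the
#' read (boundaries inclusive; the median of an even number of offsets is
#' the mean of the central pair).
#'
#' @inheritParams replicate_support
#' @param on_empty What to do with a candidate that has no alt-read
#'   offsets: `"error"` (the default; offsets are required evidence) or
#'   `"fail"` (used inside the cascade, where a candidate whose edited
#'   allele has no positional evidence - e.g. the reference allele of a
#'   homozygous-alternative site - cannot be validated and is dropped).
#' @return Logical pass vector, one element per candidate.
#' @export
read_extremity_filter <- function(candidates, cfg = filter_config(),
                                  on_empty = c("error", "fail")) {
  on_empty <- match.arg(on_empty)
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  empty <- lengths(candidates$alt_offsets) == 0L
  if (any(empty) && on_empty == "error") {
    abort("candidate(s) with no alt-read offsets; cannot apply the read-extremity filter")
  }
  med <- map_dbl(candidates$alt_offsets, function(x) {
    if (length(x)) median(x) else NA_real_
  })
  pass <- !(med <= cfg$end_window |
    med >= candidates$read_length - cfg$end_window + 1L)
  pass[empty] <- FALSE
  pass
}

#' Strand-bias filter
#'
#' Passes when both mapping strands have RNA coverage and the difference
#' between the edited-allele proportions on the forward and reverse strand
#' is at most `strand_delta_max`. A strand with zero coverage makes the
#' delta undefined and is treated as a failure.
#'
#' @inheritParams replicate_support
#' @return Logical pass vector.
#' @export
strand_bias_filter <- function(candidates, cfg = filter_config()) {
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  ok <- candidates$cov_fwd > 0L & candidates$cov_rev > 0L
  delta <- abs(
    candidates$alt_fwd / pmax(candidates$cov_fwd, 1L) -
      candidates$alt_rev / pmax(candidates$cov_rev, 1L)
  )
  ok & delta <= cfg$strand_delta_max
}

#' Biallelic filter
#'
#' Passes when, in the pooled RNA of the supporting replicates, alleles
#' other than the DNA allele and the edited allele make up strictly less
#' than `third_allele_max` of the depth (a third allele below that level is
#' attributed to sequencing error).
#'
#' @inheritParams replicate_support
#' @return Logical pass vector.
#' @export
biallelic_filter <- function(candidates, cfg = filter_config()) {
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  rna <- as.matrix(candidates[, paste0("rna", DNA_BASES)])
  depth <- rowSums(rna)
  n <- nrow(candidates)
  ref_count <- rna[cbind(seq_len(n), match(candidates$dna_allele, DNA_BASES))]
  ed_count <- rna[cbind(seq_len(n), match(candidates$edited_allele, DNA_BASES))]
  third <- (depth - ref_count - ed_count) / pmax(depth, 1L)
  depth > 0 & third < cfg$third_allele_max
}

#' Non-coding splice-region windows of an annotation
#'
#' One window per side of each internal exon boundary whose exonic side is
#' non-coding (no CDS overlap): `splice_window_exonic` bases into the exon
#' and `splice_window_intronic` bases into the intron.
#'
#' @param genes Annotation tibble (see [read_annotation()]).
#' @param cfg A [filter_config()].
#' @param coding_too Also emit windows at coding boundaries (used for
#'   splice-region consequence annotation rather than filtering).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
noncoding_splice_windows <- function(genes, cfg = filter_config(),
                                     coding_too = FALSE) {
  we <- cfg$splice_window_exonic
  wi <- cfg$splice_window_intronic
  out <- list()
  for (gid in unique(genes$gene_id)) {
    g <- filter(genes, .data$gene_id == gid)
    ex <- arrange(filter(g, .data$type == "exon"), .data$start)
    cds <- filter(g, .data$type == "CDS")
    in_cds <- function(a, b) {
      nrow(cds) > 0L && any(cds$start <= b & cds$end >= a)
    }
    n_ex <- nrow(ex)
    for (i in seq_len(n_ex)) {
      if (i < n_ex) { # boundary at the right edge of exon i
        exonic <- c(ex$end[i] - we + 1L, ex$end[i])
        if (coding_too || !in_cds(exonic[1], exonic[2])) {
          out[[length(out) + 1L]] <- tibble(
            chrom = ex$chrom[i],
            start = exonic[1], end = ex$end[i] + wi
          )
        }
      }
      if (i > 1L) { # boundary at the left edge of exon i
        exonic <- c(ex$start[i], ex$start[i] + we - 1L)
        if (coding_too || !in_cds(exonic[1], exonic[2])) {
          out[[length(out) + 1L]] <- tibble(
            chrom = ex$chrom[i],
            start = ex$start[i] - wi, end = exonic[2]
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  distinct(list_rbind(out))
}

#' Non-coding splice-region filter
#'
#' Fails candidates lying within the intronic or exonic splice window of a
#' non-coding exon boundary, where misaligned reads are a known source of
#' spurious RNA-DNA differences.
#'
#' @inheritParams replicate_support
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @return Logical pass vector.
#' @export
splice_region_filter <- function(candidates, annotation,
                                 cfg = filter_config()) {
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  win <- noncoding_splice_windows(annotation, cfg)
  if (nrow(win) == 0L) {
    return(rep(TRUE, nrow(candidates)))
  }
  map_lgl(seq_len(nrow(candidates)), function(i) {
    !any(win$chrom == candidates$chrom[i] &
      win$start <= candidates$pos[i] &
      win$end >= candidates$pos[i])
  })
}

# Shared homopolymer test on a reference string.
site_in_homopolymer <- function(seq, pos, min_run, adjacent = TRUE) {
  lo <- max(1L, pos - min_run)
  hi <- min(nchar(seq), pos + min_run)
  r <- rle(strsplit(substr(seq, lo, hi), "")[[1]])
  ends <- cumsum(r$lengths) + lo - 1L
  starts <- ends - r$lengths + 1L
  pad <- if (adjacent) 1L else 0L
  any(r$lengths >= min_run & starts <= pos + pad & ends >= pos - pad)
}

#' Homopolymer filter
#'
#' Fails candidates lying inside - or, by default, immediately adjacent to
#' - a maximal single-nucleotide reference run of length at least
#' `homopolymer_min_run`; adjacency is included because slippage miscalls
#' concentrate at run edges.
#'
#' @inheritParams replicate_support
#' @param reference Named list of reference sequences
#'   (see [read_reference()]).
#' @param adjacent Include positions immediately flanking a run.
#' @return Logical pass vector.
#' @export
homopolymer_filter <- function(candidates, reference, cfg = filter_config(),
                               adjacent = TRUE) {
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  map_lgl(seq_len(nrow(candidates)), function(i) {
    seq <- reference[[candidates$chrom[i]]]
    if (is.null(seq)) {
      abort(sprintf("chromosome '%s' absent from the reference", candidates$chrom[i]))
    }
    if (candidates$pos[i] > nchar(seq)) {
      abort(sprintf(
        "position %s:%d lies beyond the chromosome end",
        candidates$chrom[i], candidates$pos[i]
      ))
    }
    !site_in_homopolymer(
      seq, candidates$pos[i], cfg$homopolymer_min_run, adjacent
    )
  })
}

#' Build the edited-site search pattern for a candidate
#'
#' Reference flanks of `pattern_flank` bases per side with the edited base
#' substituted at the centre. Flanks extending past a chromosome end are
#' truncated symmetrically, with a warning.
#'
#' @param reference Named list of reference sequences.
#' @param chrom,pos,edited_allele Candidate coordinates and allele.
#' @param flank Bases per side.
#' @return A character pattern of length `2 * flank + 1` (or less near
#'   chromosome ends).
#' @export
edited_site_pattern <- function(reference, chrom, pos, edited_allele,
                                flank = 20L) {
  seq <- reference[[chrom]]
  if (is.null(seq)) {
    abort(sprintf("chromosome '%s' absent from the reference", chrom))
  }
  eff <- min(flank, pos - 1L, nchar(seq) - pos)
  if (eff < flank) {
    warn(sprintf(
      "pattern flank truncated to %d bases at %s:%d (chromosome end)",
      eff, chrom, pos
    ))
  }
  seq_substitute(ref_slice(reference, chrom, pos - eff, pos + eff),
    eff + 1L, edited_allele
  )
}

#' Genomic-read pattern filter
#'
#' Fails a candidate when the edited-site pattern (reference flanks with
#' the edited base at the centre) occurs - forward or reverse-complement,
#' within `pattern_max_mismatch` mismatches - in the raw DNA reads of the
#' replicates supporting the candidate. A hit means the "edited" sequence
#' exists somewhere in the sampled genome (an unassembled or diverged
#' paralog), so the RNA evidence is explained without editing. Reads of
#' non-supporting replicates are not searched.
#'
#' @inheritParams replicate_support
#' @param reference Named list of reference sequences.
#' @param dna_reads Tibble with `replicate_id`, `read`
#'   (see [read_dna_reads()]).
#' @return Logical pass vector.
#' @export
dna_pattern_filter <- function(candidates, reference, dna_reads,
                               cfg = filter_config()) {
  if (nrow(candidates) == 0L) {
    return(logical(0))
  }
  map_lgl(seq_len(nrow(candidates)), function(i) {
    pat <- edited_site_pattern(
      reference, candidates$chrom[i], candidates$pos[i],
      candidates$edited_allele[i], cfg$pattern_flank
    )
    reads <- dna_reads$read[
      dna_reads$replicate_id %in% candidates$replicate_ids[[i]]
    ]
    if (length(reads) == 0L) {
      return(TRUE)
    }
    subject <- Biostrings::DNAStringSet(reads)
    hits <- sum(Biostrings::vcountPattern(
      pat, subject,
      max.mismatch = cfg$pattern_max_mismatch
    )) + sum(Biostrings::vcountPattern(
      revcomp(pat), subject,
      max.mismatch = cfg$pattern_max_mismatch
    ))
    hits == 0L
  })
}

#' Run the full RDD detection and filtering cascade
#'
#' Applies, in order: per-replicate depth/genotype calling, the strict
#' DNA alternative-allele zero-count rule, replicate support, and the
#' read-extremity, strand-bias, biallelic, non-coding splice-region,
#' homopolymer and genomic-read pattern filters, recording the surviving
#' candidate count after every stage and each candidate's per-stage fate
#' (a candidate that fails a stage is not evaluated at later stages).
#'
#' @param observations Site-observation tibble
#'   (see [read_site_observations()]).
#' @param reference Named list of reference sequences, or `NULL` to skip
#'   the reference-dependent stages.
#' @param annotation Annotation tibble, or `NULL` to skip the splice stage.
#' @param dna_reads DNA read tibble, or `NULL` to skip the pattern stage.
#' @param cfg A [filter_config()].
#' @param stage_order Order of the six post-support stages; the default is
#'   the canonical cascade order. The final surviving set is invariant to
#'   this order; the per-stage report is not.
#' @return List of class `rdd_cascade_result` with `candidates` (the
#'   survivors, including a serialized `fate` column), `report` (tibble
#'   `stage`, `surviving`, `removed`), `fates` (long per-candidate fate
#'   tibble) and `calls` (the per-replicate calls).
#' @export
run_cascade <- function(observations, reference = NULL, annotation = NULL,
                        dna_reads = NULL, cfg = filter_config(),
                        stage_order = NULL) {
  post_support <- cascade_stage_names[4:9]
  stage_order <- stage_order %||% post_support
  if (!setequal(stage_order, post_support)) {
    abort("stage_order must be a permutation of the post-support stages")
  }

  calls <- call_replicates(observations, cfg)
  cand <- aggregate_candidates(calls)
  n_input_groups <- nrow(distinct(
    observations, .data$chrom, .data$pos, .data$alt_base
  ))

  alive <- rep(TRUE, nrow(cand))
  cand_id <- paste0(cand$chrom, ":", cand$pos, ":", cand$edited_allele)
  fates <- list()
  report <- list(tibble(
    stage = "depth_genotype",
    surviving = nrow(cand),
    removed = n_input_groups - nrow(cand)
  ))
  record <- function(stage, idx, pass) {
    fates[[length(fates) + 1L]] <<- tibble(
      candidate = cand_id[idx], stage = stage,
      result = ifelse(pass, "pass", "fail")
    )
  }

  apply_stage <- function(stage, pass_fun) {
    idx <- which(alive)
    if (length(idx) > 0L) {
      pass <- pass_fun(cand[idx, ])
      record(stage, idx, pass)
      alive[idx] <<- pass
    }
    report[[length(report) + 1L]] <<- tibble(
      stage = stage, surviving = sum(alive),
      removed = length(idx) - sum(alive)
    )
  }

  apply_stage("dna_alt_zero", function(x) dna_alt_zero(x, observations))
  apply_stage("replicate_support", function(x) {
    x$n_edited_replicates >= cfg$min_replicates
  })

  stage_funs <- list(
    read_extremity = function(x) read_extremity_filter(x, cfg, on_empty = "fail"),
    strand_bias = function(x) strand_bias_filter(x, cfg),
    biallelic = function(x) biallelic_filter(x, cfg),
    splice_region = function(x) {
      if (is.null(annotation)) rep(TRUE, nrow(x))
      else splice_region_filter(x, annotation, cfg)
    },
    homopolymer = function(x) {
      if (is.null(reference)) rep(TRUE, nrow(x))
      else homopolymer_filter(x, reference, cfg)
    },
    dna_pattern = function(x) {
      if (is.null(reference) || is.null(dna_reads)) rep(TRUE, nrow(x))
      else dna_pattern_filter(x, reference, dna_reads, cfg)
    }
  )
  for (stage in stage_order) apply_stage(stage, stage_funs[[stage]])

  fates <- if (length(fates)) list_rbind(fates) else
    tibble(candidate = character(0), stage = character(0), result = character(0))
  fate_str <- fates |>
    group_by(.data$candidate) |>
    summarise(
      fate = paste(.data$stage, .data$result, sep = ":", collapse = ";"),
      .groups = "drop"
    )
  survivors <- cand[alive, ] |>
    mutate(
      dna_base = .data$dna_allele, rdd_base = .data$edited_allele,
      candidate = paste0(.data$chrom, ":", .data$pos, ":", .data$edited_allele)
    ) |>
    left_join(fate_str, by = "candidate") |>
    select(-"candidate")

  report <- list_rbind(report) # rows in execution order
  class(report) <- c("rdd_filter_report", class(report))
  structure(
    list(candidates = survivors, report = report, fates = fates, calls = calls),
    class = "rdd_cascade_result"
  )
}

#' @export
print.rdd_cascade_result <- function(x, ...) {
  cat("<rdd_cascade_result>\n")
  print(x$report)
  cat(sprintf("%d final candidate(s)\n", nrow(x$candidates)))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report Report tibble from [run_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}
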