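# Seedable generator of a toy genome, annotation, matched DNA/RNA pileup
# observations and raw DNA reads, with planted true editing sites and one
# planted instance class for every artifact the detection cascade targets.
#
# Counts are generated at the site-observation level rather than by full
# read simulation; only the DNA reads consumed by the pattern-search filter
# are emitted as literal substrings of the paralogous copy, plus a
# background of reads drawn from the reference.

ARTIFACT_CLASSES <- c(
  "germline_het_snp", "read_end_artifact", "strand_bias_artifact",
  "multiallelic_artifact", "homopolymer_artifact", "paralog_artifact",
  "splice_region_artifact"
)

#' Cascade stage targeted by each planted artifact class
#'
#' @return Named character vector mapping artifact class to the filter stage
#'   designed to remove it.
#' @export
artifact_target_stage <- function() {
  c(
    germline_het_snp = "depth_genotype",
    read_end_artifact = "read_extremity",
    strand_bias_artifact = "strand_bias",
    multiallelic_artifact = "biallelic",
    homopolymer_artifact = "homopolymer",
    paralog_artifact = "dna_pattern",
    splice_region_artifact = "splice_region",
    true_edit = "none"
  )
}

# Break every single-base run of length >= max_run in a sequence string by
# substituting a different base; iterates until no such run remains.
break_homopolymers <- function(bases, max_run = 4L) {
  repeat {
    r <- rle(bases)
    long <- which(r$lengths > max_run)
    if (length(long) == 0L) break
    ends <- cumsum(r$lengths)
    for (i in long) {
      s <- ends[i] - r$lengths[i] + 1L
      fix <- seq(s + max_run, ends[i], by = max_run + 1L)
      for (p in fix) {
        bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
      }
    }
  }
  bases
}

# TRUE if `pos` lies inside, or immediately adjacent to, a run of length
# >= min_run in the character vector `bases`.
near_homopolymer <- function(bases, pos, min_run = 5L) {
  lo <- max(1L, pos - min_run)
  hi <- min(length(bases), pos + min_run)
  r <- rle(bases[lo:hi])
  ends <- cumsum(r$lengths) + lo - 1L
  starts <- ends - r$lengths + 1L
  any(r$lengths >= min_run & starts <= pos + 1L & ends >= pos - 1L)
}

sim_chrom <- "sim1"

#' Generate a toy genome and gene annotation
#'
#' Builds a single random chromosome hosting: a multi-exon coding gene, a
#' multi-exon non-coding gene, a block of planted homopolymer runs
#' (flanked so each run is maximal at its configured length), a duplicated
#' segment whose copy diverges at `paralog_divergence` positions spaced 50
#' bp apart, and open intergenic space for planting sites. Outside the
#' planted block the sequence is rejection-sampled to contain no
#' single-base run of length 5 or more, so planted sites interact only with
#' the features they are assigned to.
#'
#' @param config An [simulation_config()] object.
#' @return List with elements `reference` (named list of sequences),
#'   `genes` (annotation tibble as in [read_annotation()]) and `features`
#'   (placement bookkeeping used by [plant_truth()]).
#' @export
generate_genome <- function(config) {
  withr::with_seed(config$seed, {
    glen <- config$genome_length
    margin <- 300L
    run <- config$homopolymer_run
    n_art <- config$n_per_artifact_class
    bases <- break_homopolymers(sample(DNA_BASES, glen, replace = TRUE))

    gene_a_start <- margin + 1L
    exon_a <- list(c(0L, 399L), c(800L, 1399L), c(1900L, 1999L))
    cds_a <- list(c(100L, 399L), c(800L, 1399L), c(1900L, 1959L))
    gene_b_start <- gene_a_start + 2500L
    exon_b <- list(c(0L, 199L), c(400L, 599L), c(800L, 999L), c(1200L, 1399L))

    hp_start <- gene_b_start + 1900L
    hp_step <- run + 54L
    hp_starts <- hp_start + (seq_len(n_art) - 1L) * hp_step
    hp_bases <- sample(DNA_BASES, n_art, replace = TRUE)
    for (i in seq_len(n_art)) {
      s <- hp_starts[i]
      b <- hp_bases[i]
      bases[s:(s + run - 1L)] <- b
      for (fl in c(s - 1L, s + run)) {
        avoid <- unique(c(b, bases[c(fl - 1L, fl + 1L)]))
        bases[fl] <- sample(setdiff(DNA_BASES, avoid), 1L)
      }
    }

    src_start <- hp_starts[n_art] + hp_step + 500L
    seg_len <- 2000L
    copy_start <- glen - seg_len - margin + 1L
    free_start <- src_start + seg_len + 500L
    free_end <- copy_start - 500L
    needed <- 55L * (config$n_true_edits + 4L * n_art)
    if (free_end - free_start < needed) {
      abort(sprintf(
        "genome_length %d is too small to host the requested features (need ~%d free bases)",
        glen, needed
      ))
    }
    if (config$paralog_divergence * 50L + 25L > seg_len) {
      abort("paralog_divergence too large for the 2 kb duplicated segment")
    }

    bases[copy_start:(copy_start + seg_len - 1L)] <-
      bases[src_start:(src_start + seg_len - 1L)]
    sub_offsets <- 25L + 50L * (seq_len(config$paralog_divergence) - 1L)
    for (off in sub_offsets) {
      p <- copy_start + off
      bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
    }

    iv <- function(base, offs) {
      s <- base + vapply(offs, `[[`, integer(1), 1L)
      e <- base + vapply(offs, `[[`, integer(1), 2L)
      tibble(start = s, end = e)
    }
    genes <- bind_rows(
      mutate(iv(gene_a_start, exon_a), gene_id = "SIMG001",
             gene_name = "simA", type = "exon"),
      mutate(iv(gene_a_start, cds_a), gene_id = "SIMG001",
             gene_name = "simA", type = "CDS"),
      mutate(iv(gene_b_start, exon_b), gene_id = "SIMG002",
             gene_name = "simB", type = "exon")
    ) |>
      mutate(chrom = sim_chrom, strand = "+") |>
      select("gene_id", "gene_name", "chrom", "strand", "type", "start", "end")

    list(
      reference = setNames(list(paste(bases, collapse = "")), sim_chrom),
      genes = genes,
      features = list(
        margin = margin,
        homopolymers = tibble(
          start = hp_starts, end = hp_starts + run - 1L, base = hp_bases
        ),
        paralog = list(
          src_start = src_start, copy_start = copy_start,
          seg_len = seg_len, sub_offsets = sub_offsets
        ),
        free_zone = c(free_start, free_end),
        noncoding_gene = "SIMG002"
      )
    )
  })
}

# Sample `n` positions from [zone[1], zone[2]] at pairwise distance >= spacing,
# avoiding homopolymer neighbourhoods and positions in `taken`.
sample_positions <- function(bases, n, zone, taken = integer(0), spacing = 50L) {
  out <- integer(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      abort("could not place planted sites; free zone too crowded")
    }
    p <- sample(zone[1]:zone[2], 1L)
    if (length(out) && min(abs(out - p)) < spacing) next
    if (length(taken) && min(abs(taken - p)) < spacing) next
    if (near_homopolymer(bases, p)) next
    out <- c(out, p)
  }
  sort(out)
}

#' Plant truth sites on a generated genome
#'
#' Assigns positions, edited alleles and apparent frequencies for the
#' configured number of true editing sites and for each artifact class in
#' `classes`. True edits are placed on an A (edited to G) or T (edited to
#' C) reference base - the canonical A-to-I change read on either strand -
#' overwriting the reference base where needed. Artifact alleles are drawn
#' uniformly among the three non-reference bases, except paralog artifacts
#' whose allele is the diverged base of the duplicated copy.
#'
#' @param config An [simulation_config()] object.
#' @param genome Output of [generate_genome()].
#' @param classes Artifact classes to plant (default: all seven).
#' @return List with the (possibly updated) `genome` and a `truth` tibble
#'   with columns `chrom`, `pos`, `planted_class`, `edited_allele`,
#'   `true_editing_frequency`, `ref_base` plus simulation nuisance columns
#'   (`sim_freq`, `sim_second_allele`, `sim_side`).
#' @export
plant_truth <- function(config, genome, classes = ARTIFACT_CLASSES) {
  bad <- setdiff(classes, ARTIFACT_CLASSES)
  if (length(bad)) {
    abort(paste0("unknown artifact class(es): ", paste(bad, collapse = ", ")))
  }
  withr::with_seed(config$seed + 1L, {
    bases <- strsplit(genome$reference[[sim_chrom]], "")[[1]]
    zone <- genome$features$free_zone
    n_art <- config$n_per_artifact_class
    taken <- integer(0)
    rows <- list()

    add <- function(pos, class, allele, freq, sim_freq,
                    second = NA_character_, side = NA_character_) {
      tibble(
        chrom = sim_chrom, pos = pos, planted_class = class,
        edited_allele = allele, true_editing_frequency = freq,
        ref_base = bases[pos], sim_freq = sim_freq,
        sim_second_allele = second, sim_side = side
      )
    }
    rfreq <- function(n) runif(n, config$freq_range[1], config$freq_range[2])

    canonical_partner <- c(A = "G", C = "T", G = "A", T = "C")
    if (config$n_true_edits > 0L) {
      pos <- sample_positions(bases, config$n_true_edits, zone, taken)
      taken <- c(taken, pos)
      for (p in pos) {
        # put the site on an A (plus strand) or T (minus strand) template,
        # keeping the original base if the rewrite would create a
        # homopolymer; the edited allele is always the canonical partner
        old <- bases[p]
        bases[p] <- sample(c("A", "T"), 1L)
        if (near_homopolymer(bases, p)) bases[p] <- old
        f <- rfreq(1)
        rows[[length(rows) + 1L]] <-
          add(p, "true_edit", unname(canonical_partner[bases[p]]), f, f)
      }
    }

    other_allele <- function(p) sample(setdiff(DNA_BASES, bases[p]), 1L)

    for (class in classes) {
      if (n_art == 0L) break
      if (class == "homopolymer_artifact") {
        hp <- genome$features$homopolymers
        idx <- seq_len(min(n_art, nrow(hp)))
        pos <- hp$start[idx] + (hp$end[idx] - hp$start[idx]) %/% 2L
      } else if (class == "paralog_artifact") {
        par <- genome$features$paralog
        if (length(par$sub_offsets) < n_art) {
          abort("paralog_divergence must be >= n_per_artifact_class")
        }
        pos <- par$src_start + par$sub_offsets[seq_len(n_art)]
      } else if (class == "splice_region_artifact") {
        nc <- filter(genome$genes,
          .data$gene_id == genome$features$noncoding_gene,
          .data$type == "exon"
        ) |> arrange(.data$start)
        win <- integer(0)
        for (i in seq_len(nrow(nc))) {
          if (i < nrow(nc)) win <- c(win, (nc$end[i] + 1L):(nc$end[i] + 8L),
                                     (nc$end[i] - 2L):nc$end[i])
          if (i > 1L) win <- c(win, (nc$start[i] - 8L):(nc$start[i] - 1L),
                               nc$start[i]:(nc$start[i] + 2L))
        }
        win <- sort(unique(win))
        if (length(win) < n_art) {
          abort("not enough non-coding splice-window positions for the requested sites")
        }
        pos <- sort(sample(win, n_art))
      } else {
        pos <- sample_positions(bases, n_art, zone, taken)
        taken <- c(taken, pos)
      }
      for (k in seq_along(pos)) {
        p <- pos[k]
        allele <- if (class == "paralog_artifact") {
          par <- genome$features$paralog
          cp <- par$copy_start + (p - par$src_start)
          bases[cp]
        } else {
          other_allele(p)
        }
        side <- NA_character_
        second <- NA_character_
        f <- rfreq(1)
        if (class == "germline_het_snp") f <- 0.5
        if (class == "read_end_artifact") side <- sample(c("low", "high"), 1L)
        if (class == "strand_bias_artifact") {
          # one-strand artifacts need a per-strand alt fraction above the
          # delta threshold to be detectable: 2f/(1+f) > 0.5 needs f > 1/3
          f <- runif(1, 0.40, 0.60)
          side <- sample(c("fwd", "rev"), 1L)
        }
        if (class == "multiallelic_artifact") {
          f <- runif(1, 0.25, 0.40)
          second <- sample(setdiff(DNA_BASES, c(bases[p], allele)), 1L)
        }
        rows[[length(rows) + 1L]] <- add(p, class, allele, 0, f, second, side)
      }
    }

    genome$reference[[sim_chrom]] <- paste(bases, collapse = "")
    truth <- arrange(list_rbind(rows), .data$pos)
    truth$ref_base <- bases[truth$pos]
    list(genome = genome, truth = truth)
  })
}

multiallelic_second_freq <- c(0.10, 0.18)

# Per-site, per-replicate multinomial pileup counts.
sim_counts <- function(depth, probs) {
  drop(rmultinom(1L, depth, probs))
}

#' Simulate matched DNA/RNA pileup observations and raw DNA reads
#'
#' For every planted site and biological replicate, DNA and RNA allele
#' counts are drawn from multinomials encoding the site's class: true edits
#' have clean homozygous DNA and an RNA alternative fraction at the
#' planted frequency with uniform read offsets and balanced strands;
#' read-end artifacts confine alt offsets to one read extremity; strand
#' artifacts put every alt read on one mapping strand; germline
#' heterozygotes have ~50% alternative in DNA; multiallelic artifacts add a
#' second alternative allele above the sequencing-error level. Sequencing
#' error is symmetric across the three non-reference bases. DNA reads are
#' emitted for the pattern-search filter: literal substrings of the
#' diverged paralog copy spanning each paralog site, on a background of
#' error-bearing reads drawn from the reference.
#'
#' @param config An [simulation_config()] object.
#' @param genome Output of [generate_genome()] (as updated by
#'   [plant_truth()]).
#' @param truth Truth tibble from [plant_truth()].
#' @return List with `observations` (site-observation tibble) and
#'   `dna_reads` (tibble with `replicate_id`, `read`).
#' @export
simulate_observations <- function(config, genome, truth) {
  glen <- nchar(genome$reference[[sim_chrom]])
  if (any(truth$pos < 1L | truth$pos > glen)) {
    abort("truth positions must lie on the generated genome")
  }
  withr::with_seed(config$seed + 2L, {
    L <- config$read_length
    e <- config$error_rate
    reps <- sprintf("rep%02d", seq_len(config$n_replicates))
    idx <- setNames(seq_along(DNA_BASES), DNA_BASES)

    site_rows <- map(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      ref <- tr$ref_base
      alt <- tr$edited_allele
      f <- tr$sim_freq
      p_dna <- rep(e / 3, 4L)
      p_dna[idx[ref]] <- 1 - e
      if (tr$planted_class == "germline_het_snp") {
        p_dna <- rep(e / 3, 4L)
        p_dna[idx[ref]] <- 0.5 - e / 3
        p_dna[idx[alt]] <- 0.5 - e / 3
      }
      p_rna <- rep(e / 3, 4L)
      p_rna[idx[alt]] <- f
      p_rna[idx[ref]] <- 1 - f - 2 * e / 3
      if (tr$planted_class == "multiallelic_artifact") {
        f2 <- runif(1, multiallelic_second_freq[1], multiallelic_second_freq[2])
        p_rna <- rep(0, 4L)
        p_rna[idx[tr$sim_second_allele]] <- f2
        p_rna[idx[alt]] <- f
        rest <- setdiff(DNA_BASES, c(alt, tr$sim_second_allele, ref))
        p_rna[idx[rest]] <- e / 3
        p_rna[idx[ref]] <- 1 - sum(p_rna)
      }
      out <- map(seq_along(reps), function(r) {
        dd <- max(1L, rpois(1L, config$dna_depth))
        dr <- max(1L, rpois(1L, config$rna_depth))
        dna <- sim_counts(dd, p_dna)
        rna <- sim_counts(dr, p_rna)
        na <- rna[idx[alt]]
        alt_fwd <- if (tr$planted_class == "strand_bias_artifact") {
          if (tr$sim_side == "fwd") na else 0L
        } else {
          rbinom(1L, na, 0.5)
        }
        nonalt_fwd <- rbinom(1L, dr - na, 0.5)
        offs <- if (tr$planted_class == "read_end_artifact") {
          zone <- if (tr$sim_side == "low") 1:10 else (L - 9L):L
          sample(zone, na, replace = TRUE)
        } else {
          sample.int(L, na, replace = TRUE)
        }
        tibble(
          replicate_id = reps[r], chrom = tr$chrom, pos = tr$pos, ref = ref,
          dnaA = dna[1], dnaC = dna[2], dnaG = dna[3], dnaT = dna[4],
          rnaA = rna[1], rnaC = rna[2], rnaG = rna[3], rnaT = rna[4],
          alt_base = alt, alt_fwd = alt_fwd, alt_rev = na - alt_fwd,
          cov_fwd = alt_fwd + nonalt_fwd,
          cov_rev = dr - alt_fwd - nonalt_fwd,
          read_length = L, alt_offsets = list(sort(offs))
        )
      })
      list_rbind(out)
    })
    obs <- arrange(
      list_rbind(site_rows),
      .data$chrom, .data$pos, .data$replicate_id
    )

    genome_seq <- genome$reference[[sim_chrom]]
    par <- genome$features$paralog
    par_truth <- filter(truth, .data$planted_class == "paralog_artifact")
    read_rows <- list()
    for (r in reps) {
      if (nrow(par_truth) > 0L) {
        cp <- par$copy_start + (par_truth$pos - par$src_start)
        for (p in cp) {
          lo <- max(par$copy_start, p + 20L - L + 1L)
          hi <- min(par$copy_start + par$seg_len - L, p - 20L)
          starts <- sample(lo:hi, 4L, replace = TRUE)
          read_rows[[length(read_rows) + 1L]] <- tibble(
            replicate_id = r,
            read = substring(genome_seq, starts, starts + L - 1L)
          )
        }
      }
      starts <- sample.int(glen - L + 1L, 50L, replace = TRUE)
      bg <- substring(genome_seq, starts, starts + L - 1L)
      nerr <- rbinom(length(bg), L, e)
      for (j in which(nerr > 0L)) {
        for (p in sample.int(L, nerr[j])) {
          bg[j] <- seq_substitute(
            bg[j], p, sample(setdiff(DNA_BASES, substr(bg[j], p, p)), 1L)
          )
        }
      }
      read_rows[[length(read_rows) + 1L]] <- tibble(replicate_id = r, read = bg)
    }
    list(observations = obs, dna_reads = list_rbind(read_rows))
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_genome()], [plant_truth()] and
#' [simulate_observations()].
#'
#' @inheritParams plant_truth
#' @return List with `reference`, `genes`, `features`, `truth`,
#'   `observations` and `dna_reads`.
#' @export
simulate_dataset <- function(config, classes = ARTIFACT_CLASSES) {
  genome <- generate_genome(config)
  planted <- plant_truth(config, genome, classes = classes)
  sim <- simulate_observations(config, planted$genome, planted$truth)
  c(planted$genome, list(
    truth = planted$truth,
    observations = sim$observations,
    dna_reads = sim$dna_reads
  ))
}

#' Simulate a balanced tissue-by-stage editing-level dataset
#'
#' Editing levels are generated on the logit scale from a two-way
#' fixed-effects model (baseline + tissue + stage + interaction + Gaussian
#' noise) and mapped back through the inverse logit, so measurements stay
#' in (0, 1).
#'
#' @param config An [simulation_config()] object; `tissue_effects`,
#'   `stage_effects` and `interaction_effects` set the planted effects.
#' @return Tibble with columns `tissue`, `stage`, `replicate`,
#'   `editing_level`; balanced with `n_per_cell` rows per cell.
#' @export
generate_editing_level_dataset <- function(config) {
  withr::with_seed(config$seed + 3L, {
    grid <- tidyr::expand_grid(
      tissue = config$tissues,
      stage = config$stages,
      replicate = seq_len(config$n_per_cell)
    )
    ti <- match(grid$tissue, config$tissues)
    si <- match(grid$stage, config$stages)
    eta <- config$baseline_logit +
      config$tissue_effects[ti] +
      config$stage_effects[si] +
      config$interaction_effects[cbind(ti, si)] +
      rnorm(nrow(grid), 0, config$noise_sd)
    mutate(grid,
      tissue = factor(.data$tissue, levels = config$tissues),
      stage = factor(.data$stage, levels = config$stages),
      editing_level = plogis(eta)
    )
  })
}

#' Write the truth table emitted by the simulator
#'
#' @param truth Truth tibble from [plant_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(
    select(
      truth, "chrom", "pos", "planted_class", "edited_allele",
      "true_editing_frequency", "ref_base"
    ),
    path,
    progress = FALSE
  )
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#'
#' @param path Path to the truth TSV.
#' @return Truth tibble.
#' @export
read_truth <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      planted_class = readr::col_character(),
      edited_allele = readr::col_character(),
      true_editing_frequency = readr::col_double(),
      ref_base = readr::col_character()
    ),
    progress = FALSE
  )
}
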