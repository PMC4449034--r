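# The ordered filter cascade: exact boundary behaviour of each predicate,
# per-stage accounting, and the removal guarantees on synthetic data.

test_that("replicate support requires a shared position AND allele", {
  cfg <- filter_config()
  two <- make_cand(n_reps = 2L)
  expect_identical(nrow(replicate_support(two, cfg)), 1L)
  one <- make_cand(n_reps = 1L)
  expect_identical(nrow(replicate_support(one, cfg)), 0L)
  # two replicates calling different alleles aggregate into two
  # single-replicate candidates, and both fail
  split_alleles <- dplyr::bind_rows(
    make_cand(n_reps = 1L, edited_allele = "G"),
    make_cand(n_reps = 1L, edited_allele = "T")
  )
  expect_identical(nrow(replicate_support(split_alleles, cfg)), 0L)
})

test_that("read-extremity filter uses an inclusive median-offset boundary", {
  cfg <- filter_config()
  cases <- list(
    list(offs = c(50L, 51L, 52L), pass = TRUE),
    list(offs = c(3L, 5L, 9L), pass = FALSE),   # median 5
    list(offs = c(10L, 55L, 95L), pass = TRUE), # median 55
    list(offs = c(9L, 10L, 91L), pass = FALSE), # median exactly 10 fails
    list(offs = c(10L, 11L), pass = TRUE),      # even n: median 10.5 > 10
    list(offs = c(9L, 11L), pass = FALSE),      # even n: median 10 fails
    list(offs = c(91L, 95L), pass = FALSE),     # median 93 >= L - 10 + 1
    list(offs = c(90L, 90L), pass = TRUE)       # median 90 < 91
  )
  for (cs in cases) {
    cand <- make_cand(offsets = cs$offs)
    expect_identical(read_extremity_filter(cand, cfg), cs$pass)
  }
  expect_error(
    read_extremity_filter(make_cand(offsets = integer(0)), cfg),
    "offsets"
  )
})

test_that("strand-bias filter applies delta <= 0.5 and fails zero-coverage strands", {
  cfg <- filter_config()
  ok <- make_cand(alt_fwd = 10L, cov_fwd = 20L, alt_rev = 8L, cov_rev = 20L)
  expect_true(strand_bias_filter(ok, cfg)) # delta 0.10
  bad <- make_cand(alt_fwd = 10L, cov_fwd = 10L, alt_rev = 0L, cov_rev = 10L)
  expect_false(strand_bias_filter(bad, cfg)) # delta 1.0
  at <- make_cand(alt_fwd = 10L, cov_fwd = 10L, alt_rev = 5L, cov_rev = 10L)
  expect_true(strand_bias_filter(at, cfg)) # delta exactly 0.5 passes
  zero <- make_cand(alt_fwd = 18L, cov_fwd = 40L, alt_rev = 0L, cov_rev = 0L)
  expect_false(strand_bias_filter(zero, cfg)) # undefined delta -> fail
})

test_that("biallelic filter is strict at the 5% third-allele boundary", {
  cfg <- filter_config()
  at_boundary <- make_cand(rna = base_counts(A = 50L, G = 45L, T = 5L))
  expect_false(biallelic_filter(at_boundary, cfg)) # exactly 5% fails
  below <- make_cand(rna = base_counts(A = 50L, G = 48L, T = 2L))
  expect_true(biallelic_filter(below, cfg)) # 2% passes
  clean <- make_cand(rna = base_counts(A = 50L, G = 50L))
  expect_true(biallelic_filter(clean, cfg)) # 0 passes
})

test_that("splice filter removes non-coding boundary windows only", {
  cfg <- filter_config()
  genes <- dplyr::bind_rows(
    make_gene(gene_id = "NC", gene_name = "nc",
              exons = list(c(1001L, 1100L), c(1501L, 1600L))),
    make_gene(gene_id = "CO", gene_name = "co",
              exons = list(c(5001L, 5100L), c(5501L, 5600L)),
              cds = list(c(5001L, 5100L), c(5501L, 5600L)))
  )
  at <- function(pos) make_cand(pos = pos)
  # intronic position 5 bp past the non-coding donor site -> removed
  expect_false(splice_region_filter(at(1105L), genes, cfg))
  # exonic side of the same boundary, 2 bases in -> removed
  expect_false(splice_region_filter(at(1099L), genes, cfg))
  # 9 bases into the intron is outside the 8-base window -> kept
  expect_true(splice_region_filter(at(1109L), genes, cfg))
  # mid-intron, far from boundaries -> kept
  expect_true(splice_region_filter(at(1300L), genes, cfg))
  # the same geometry at a coding boundary is NOT removed
  expect_true(splice_region_filter(at(5105L), genes, cfg))
  expect_true(splice_region_filter(at(5099L), genes, cfg))
})

test_that("homopolymer filter matches an exhaustive run-scan oracle", {
  cfg <- filter_config()
  ref <- list(c1 = "ACGTAAAAACGTGGGGGTACCCCAGTAAAATTC")
  #                 123456789...
  # AAAAA at 5-9, GGGGG at 13-17, CCCC at 21-24 (run 4), AAAA at 28-31
  expect_false(homopolymer_filter(make_cand(pos = 7L), ref, cfg))  # inside run 5
  expect_true(homopolymer_filter(make_cand(pos = 22L), ref, cfg))  # run of 4
  expect_false(homopolymer_filter(make_cand(pos = 18L), ref, cfg)) # adjacent 3' of GGGGG
  expect_false(homopolymer_filter(make_cand(pos = 4L), ref, cfg))  # adjacent 5' of AAAAA
  expect_true(homopolymer_filter(make_cand(pos = 18L), ref, cfg,
                                 adjacent = FALSE)) # strict containment mode

  # oracle: full-sequence rle scan marking runs >= 5 plus 1-base flanks
  withr::with_seed(4, {
    seq <- paste(sample(c("A", "C", "G", "T"), 600,
                        replace = TRUE, prob = c(.45, .05, .05, .45)),
                 collapse = "")
  })
  bases <- strsplit(seq, "")[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flagged <- rep(FALSE, length(bases))
  for (i in which(r$lengths >= 5L)) {
    flagged[max(1L, starts[i] - 1L):min(length(bases), ends[i] + 1L)] <- TRUE
  }
  expect_gt(sum(flagged), 0L) # the composition makes runs near-certain
  cand <- dplyr::bind_rows(lapply(seq_along(bases), make_cand, chrom = "c1"))
  expect_identical(
    homopolymer_filter(cand, list(c1 = seq), cfg),
    !flagged
  )
})

test_that("pattern filter searches only the reads of supporting replicates", {
  cfg <- filter_config()
  withr::with_seed(8, {
    ref <- list(c1 = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                           collapse = ""))
  })
  cand <- make_cand(pos = 100L, edited_allele = "G",
                    replicate_ids = c("rep01", "rep02"))
  pat <- edited_site_pattern(ref, "c1", 100L, "G")
  expect_identical(nchar(pat), 41L)
  expect_identical(substr(pat, 21L, 21L), "G")

  carrier <- paste0("ACGT", pat, "ACGT")
  neutral <- substr(ref$c1, 1, 49)
  # pattern in a supporting replicate's reads -> fail
  reads <- tibble::tibble(replicate_id = c("rep01", "rep02"),
                          read = c(carrier, neutral))
  expect_false(dna_pattern_filter(cand, ref, reads, cfg))
  # reverse-complement hit -> fail
  reads_rc <- tibble::tibble(replicate_id = "rep02", read = revcomp(carrier))
  expect_false(dna_pattern_filter(cand, ref, reads_rc, cfg))
  # pattern present only in a NON-supporting replicate -> pass
  reads_other <- tibble::tibble(replicate_id = c("rep07", "rep01"),
                                read = c(carrier, neutral))
  expect_true(dna_pattern_filter(cand, ref, reads_other, cfg))
  # no hit anywhere -> pass
  expect_true(dna_pattern_filter(
    cand, ref, tibble::tibble(replicate_id = "rep01", read = neutral), cfg
  ))

  # flank truncation near the chromosome start warns but still works
  edge <- make_cand(pos = 10L, replicate_ids = "rep01")
  expect_warning(
    dna_pattern_filter(edge, ref,
                       tibble::tibble(replicate_id = "rep01", read = neutral),
                       cfg),
    "truncated"
  )
})

test_that("cascade counts are weakly decreasing and empty input yields a zero report", {
  cfg <- simulation_config(seed = 21, n_true_edits = 10L, n_per_artifact_class = 5L)
  ds <- simulate_dataset(cfg)
  res <- run_cascade(ds$observations, ds$reference, ds$genes, ds$dna_reads)
  expect_identical(res$report$stage, cascade_stages())
  expect_true(all(diff(res$report$surviving) <= 0L))
  expect_true(all(res$report$removed >= 0L))
  # fates appear in cascade order and stop at the first failure
  first_fail <- dplyr::summarise(
    dplyr::group_by(res$fates, candidate),
    n_after_fail = sum(cumsum(result == "fail") > 1L),
    .groups = "drop"
  )
  expect_true(all(first_fail$n_after_fail == 0L))

  empty <- run_cascade(make_obs()[0, ], ds$reference, ds$genes, ds$dna_reads)
  expect_identical(nrow(empty$candidates), 0L)
  expect_true(all(empty$report$surviving == 0L))
})

test_that("the final surviving set is invariant to post-support stage order", {
  cfg <- simulation_config(seed = 33, n_true_edits = 15L, n_per_artifact_class = 6L)
  ds <- simulate_dataset(cfg)
  canonical <- run_cascade(ds$observations, ds$reference, ds$genes, ds$dna_reads)
  key <- function(res) {
    sort(paste0(res$candidates$chrom, ":", res$candidates$pos, ":",
                res$candidates$rdd_base))
  }
  post <- cascade_stages()[4:9]
  withr::with_seed(1, orders <- replicate(3, sample(post), simplify = FALSE))
  for (ord in orders) {
    permuted <- run_cascade(ds$observations, ds$reference, ds$genes,
                            ds$dna_reads, stage_order = ord)
    expect_identical(key(permuted), key(canonical))
    expect_true(all(diff(permuted$report$surviving) <= 0L))
  }
})

test_that("each artifact class, planted in isolation, dies at its targeted stage", {
  targets <- artifact_target_stage()
  for (class in names(targets)[names(targets) != "true_edit"]) {
    cfg <- simulation_config(seed = 55, n_true_edits = 0L,
                             n_per_artifact_class = 30L)
    ds <- simulate_dataset(cfg, classes = class)
    res <- run_cascade(ds$observations, ds$reference, ds$genes, ds$dna_reads)
    stages <- removal_stage(res, ds$truth)
    expect_gte(mean(stages == targets[[class]]), 0.95)
    expect_identical(nrow(res$candidates), 0L)
  }
})

test_that("canonical changes are enriched across the cascade stages", {
  # averaged over independent simulations: true edits are canonical by
  # construction, artifact alleles are drawn uniformly, so every stage
  # that removes artifacts raises the canonical fraction
  canon_by_stage <- function(seed) {
    cfg <- simulation_config(seed = seed, n_true_edits = 25L,
                             n_per_artifact_class = 12L)
    ds <- simulate_dataset(cfg)
    res <- run_cascade(ds$observations, ds$reference, ds$genes, ds$dna_reads)
    fates <- tidyr::pivot_wider(res$fates, names_from = "stage",
                                values_from = "result")
    all_cand <- unique(res$fates$candidate)
    alleles <- do.call(rbind, strsplit(all_cand, ":"))
    dna <- ds$truth$ref_base[match(as.integer(alleles[, 2]), ds$truth$pos)]
    canonical <- classify_change(dna, alleles[, 3])$is_canonical
    stages <- cascade_stages()[-1]
    vapply(seq_along(stages), function(k) {
      alive <- rep(TRUE, length(all_cand))
      for (s in stages[1:k]) {
        if (s %in% names(fates)) {
          st <- fates[[s]][match(all_cand, fates$candidate)]
          alive <- alive & !is.na(st) & st == "pass"
        }
      }
      mean(canonical[alive])
    }, numeric(1))
  }
  curves <- vapply(101:108, canon_by_stage, numeric(8))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) >= -0.02)) # non-decreasing up to averaging noise
  expect_gt(avg[length(avg)] - avg[1], 0.2)
  expect_gt(avg[length(avg)], 0.95)
})
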