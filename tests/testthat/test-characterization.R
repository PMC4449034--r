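# Post-cascade characterization: change-type collapse, clustering, gene
# summaries, consequence classification and editing levels.

test_that("change classification collapses all 12 ordered pairs consistently", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- expand.grid(d = bases, r = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$d != pairs$r, ]
  for (i in seq_len(nrow(pairs))) {
    a <- classify_change(pairs$d[i], pairs$r[i])
    b <- classify_change(comp[[pairs$d[i]]], comp[[pairs$r[i]]])
    expect_identical(a$collapsed_label, b$collapsed_label)
    expect_identical(a$is_canonical, b$is_canonical)
  }
  expect_identical(length(unique(
    classify_change(pairs$d, pairs$r)$collapsed_label
  )), 6L)
  expect_true(classify_change("T", "C")$is_canonical)
  expect_true(classify_change("G", "A")$is_canonical)
  expect_false(classify_change("A", "C")$is_canonical)
  expect_error(classify_change("A", "A"), "differ")
})

test_that("change spectrum sums to one and matches hand-built sets", {
  toy <- tibble::tibble(dna_base = rep("A", 4), rdd_base = rep("G", 4))
  sp <- change_spectrum(toy)
  expect_identical(sp$collapsed_label, "A>G")
  expect_equal(sp$proportion, 1)
  expect_error(change_spectrum(toy[0, ]), "empty")

  cand <- load_final_candidates()
  sp36 <- change_spectrum(cand)
  expect_equal(sum(sp36$proportion), 1)
  expect_identical(sum(sp36$n[!sp36$is_canonical]), 1L)
})

test_that("cluster scan matches hand-computed groupings", {
  toy <- tibble::tibble(chrom = "c1", pos = c(100L, 200L, 5000L))
  cl <- find_clusters(toy, max_gap = 1000L)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$positions[[1]], c(100L, 200L))
  expect_identical(cl$span, 100L)

  # chromosome boundaries never join
  two_chr <- tibble::tibble(chrom = c("c1", "c2"), pos = c(100L, 150L))
  expect_identical(nrow(find_clusters(two_chr, 1000L)), 0L)
})

test_that("clusters are a maximal partition (brute-force oracle on random sets)", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(5:50, 1)
      pos <- sort(sample.int(20000L, n))
      gap <- sample(c(100L, 500L, 1000L), 1)
      sites <- tibble::tibble(chrom = "c1", pos = pos)
      cl <- find_clusters(sites, gap)
      member <- unlist(cl$positions)
      expect_identical(anyDuplicated(member), 0L) # a partition
      for (i in seq_len(nrow(cl))) {
        p <- cl$positions[[i]]
        expect_true(all(diff(p) <= gap)) # internal gaps respect the cap
        outside <- setdiff(pos, p)
        if (length(outside)) { # not extendable in either direction
          expect_true(all(abs(outside - min(p)) > gap | outside > min(p)))
          expect_true(all(abs(outside - max(p)) > gap | outside < max(p)))
        }
      }
      # singletons are exactly the sites > gap from every other site
      lonely <- pos[vapply(pos, function(p) {
        all(abs(setdiff(pos, p) - p) > gap)
      }, logical(1))]
      expect_true(all(!lonely %in% member))
    }
  })
})

test_that("the published candidate set shows 7 clusters with the printed statistics", {
  cand <- load_final_candidates()
  cl <- find_clusters(cand, max_gap = 1000L)
  expect_identical(nrow(cl), 7L)
  st <- cluster_statistics(cl)
  expect_identical(st$size_min, 2L)
  expect_identical(st$size_max, 5L)
  expect_identical(st$span_min, 12L)   # chr3:2384093-2384105
  expect_identical(st$span_max, 1439L) # chr1:74991790-74993229
  expect_identical(st$gap_min, 3L)     # chrZ:27752047-27752050
  expect_identical(st$gap_max, 807L)
})

test_that("cluster statistics sit on a plateau of the gap threshold", {
  cand <- load_final_candidates()
  stats <- lapply(c(807L, 1000L, 1500L, 2300L, 2864L), function(g) {
    cluster_statistics(find_clusters(cand, g))
  })
  for (s in stats[-1]) expect_identical(s, stats[[1]])
  # the plateau ends on both sides: at 806 the widest intra-cluster gap
  # breaks, above 2864 two groups merge
  below <- cluster_statistics(find_clusters(cand, 806L))
  expect_lt(below$gap_max, 807L)
  expect_false(identical(below, stats[[1]]))
  expect_false(identical(
    cluster_statistics(find_clusters(cand, 2865L)), stats[[1]]
  ))
})

test_that("gene summary counts distinct gene identifiers across multi-gene sites", {
  cand <- load_final_candidates()
  genes <- summarize_genes(cand)
  expect_identical(nrow(genes), 17L)
  # multi-gene rows contribute each identifier
  expect_true(all(c("ENSGALG00000003738", "ENSGALG00000003799") %in% genes$gene_id))
  # the missense subset is COG3, GRIA2, CYFIP2
  mis <- summarize_genes(cand[grepl("missense", cand$consequence), ])
  expect_setequal(mis$gene_name, c("COG3", "GRIA2", "CYFIP2"))
  expect_identical(nrow(summarize_genes(cand[0, ])), 0L)
})

test_that("consequence classifier places sites in the gene architecture", {
  # a + strand gene: exon1 101-140 (5'UTR 101-110, CDS 111-140 starting
  # AAA TTT GCT ...), intron 141-200, exon2 201-240 (CDS 201-212, then
  # 3'UTR); codon arithmetic checked by hand
  ref <- list(c1 = paste0(
    strrep("ACGT", 25),                          # 1..100 upstream
    strrep("C", 10), "AAATTTGCT", strrep("AG", 10), "A", # exon1
    strrep("GA", 30),                            # intron 141..200
    "ATGCATGCATGC", strrep("TC", 14)             # exon2
  ))
  genes <- make_gene(
    exons = list(c(101L, 140L), c(201L, 240L)),
    cds = list(c(111L, 140L), c(201L, 212L))
  )
  cfg <- filter_config()
  cls <- function(pos, allele) {
    classify_consequence("c1", pos, allele, genes, ref, cfg)
  }
  # AAA -> GAA is K -> E
  expect_identical(cls(111L, "G"), "missense")
  # GCT -> GCC: third codon position, alanine either way
  expect_identical(cls(119L, "C"), "synonymous")
  expect_true("intron" %in% cls(170L, "G"))
  expect_true("splice_region" %in% cls(141L, "G")) # intron side of donor
  expect_true("5_prime_UTR" %in% cls(105L, "G"))
  expect_true("3_prime_UTR" %in% cls(225L, "G"))
  # 2 kb past the gene end, inside the 5 kb flank
  expect_identical(cls(2240L, "G"), "downstream_gene")
  expect_identical(cls(50L, "G"), "upstream_gene")
  # far beyond every flank
  far_ref <- list(c1 = strrep("ACGT", 3000))
  expect_identical(
    classify_consequence("c1", 11000L, "G", genes, far_ref, cfg),
    "intergenic"
  )
})

test_that("minus-strand codons are translated on the gene strand", {
  # minus-strand CDS of 6 bases: genomic 101..106 = "TTTCAT";
  # revcomp = "ATGAAA" -> M K; editing genomic T102 -> C gives
  # revcomp "ATGAGA" wait: compute explicitly below
  ref <- list(c1 = paste0(strrep("G", 100), "TTTCAT", strrep("G", 100)))
  genes <- make_gene(strand = "-", exons = list(c(101L, 106L)),
                     cds = list(c(101L, 106L)))
  cfg <- filter_config()
  # genomic A at 105 -> G: revcomp codon ATG -> ACG? transcript base is
  # comp(G) = C at transcript position 2: ATG (M) -> ACG (T): missense
  expect_identical(
    classify_consequence("c1", 105L, "G", genes, ref, cfg)[1], "missense"
  )
  # genomic T at 101 -> C: transcript position 6 (third of codon 2):
  # AAA (K) -> AAG (K): synonymous
  expect_identical(
    classify_consequence("c1", 101L, "C", genes, ref, cfg)[1], "synonymous"
  )
})

test_that("editing level is the edited fraction of RNA reads", {
  obs <- make_obs(rna = base_counts(A = 52L, G = 48L), alt = "G")
  expect_equal(editing_level(obs), 0.48)
  none <- make_obs(rna = base_counts(A = 50L), alt = "G",
                   alt_fwd = 0L, alt_rev = 0L, offsets = integer(0))
  expect_equal(editing_level(none), 0)
  zero <- make_obs(rna = base_counts(), alt = "G",
                   alt_fwd = 0L, alt_rev = 0L,
                   cov_fwd = 0L, cov_rev = 0L, offsets = integer(0))
  expect_error(editing_level(zero), "zero")
  # pyrosequencing through the reverse complement of a T>C site reports
  # A/G counts; the edited allele is read as G
  pyro <- make_obs(ref = "T", rna = base_counts(A = 53L, G = 47L), alt = "G",
                   dna = base_counts(T = 30L),
                   alt_fwd = 23L, alt_rev = 24L,
                   offsets = rep(50L, 47L))
  expect_equal(editing_level(pyro), 0.47)
})
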