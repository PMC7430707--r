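test_that("structure inference recovers constructed exon-intron layouts", {
  # intron-less gene: genomic equals CDS
  cds <- random_dna(90)
  st <- infer_structure(cds, cds)
  expect_equal(unname(st$exons), cbind(1L, 90L), ignore_attr = TRUE)
  expect_equal(st$n_introns, 0L)

  # one canonical intron at a known position
  set.seed(51)
  e1 <- random_dna(50); e2 <- random_dna(40)
  intron <- paste0("GT", random_dna(60), "AG")
  st <- infer_structure(paste0(e1, intron, e2), paste0(e1, e2))
  expect_equal(st$exons[, "start"], c(1L, 115L), ignore_attr = TRUE)
  expect_equal(st$exons[, "end"], c(50L, 154L), ignore_attr = TRUE)
  expect_equal(st$splice_sites, "GT..AG")

  # unreconstructible CDS errors with an offset
  expect_error(infer_structure("AAAA", "AAAT"), "offset")
  expect_error(infer_structure("CCCC", "TTTT"), "offset 1")
})

test_that("structure inference inverts the generator on a seeded batch", {
  fam <- generate_family(family_config(n_genes = 25, seed = 52))
  for (id in names(fam$proteins)) {
    st <- infer_structure(fam$genomic[[id]], fam$cds[[id]], id)
    expect_equal(unname(st$exons), unname(fam$truth$exons[[id]]),
                 info = id)
    # every recovered intron is canonical by construction
    if (st$n_introns > 0) {
      expect_true(all(st$splice_sites == "GT..AG"), info = id)
    }
  }
})

test_that("local similarity follows the EMBOSS convention", {
  s <- random_protein(30)
  expect_equal(as.numeric(smith_waterman_similarity(s, s)), 100)
  # sequences over residue sets with no positive substitution score
  expect_equal(as.numeric(smith_waterman_similarity(
    strrep("G", 10), strrep("L", 10))), 0)
  expect_warning(sim0 <- smith_waterman_similarity("", "AAA"), "empty")
  expect_equal(as.numeric(sim0), 0)
  # symmetry
  set.seed(53)
  for (i in 1:5) {
    a <- random_protein(sample(8:20, 1))
    b <- random_protein(sample(8:20, 1))
    expect_equal(as.numeric(smith_waterman_similarity(a, b)),
                 as.numeric(smith_waterman_similarity(b, a)))
  }
})

test_that("local scores equal exhaustive enumeration on tiny inputs", {
  sub <- substitution_matrix("DNA")
  set.seed(54)
  for (i in 1:6) {
    a <- random_dna(sample(2:5, 1))
    b <- random_dna(sample(2:5, 1))
    ours <- attr(smith_waterman_similarity(a, b, sub), "score")
    if (is.null(ours)) ours <- 0
    expect_equal(as.numeric(ours), brute_local_score(a, b, sub),
                 info = paste(a, b))
  }
})

test_that("local scores agree with an independent aligner", {
  set.seed(55)
  for (i in 1:8) {
    a <- random_protein(sample(10:25, 1))
    b <- random_protein(sample(10:25, 1))
    ours <- attr(smith_waterman_similarity(a, b), "score")
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 9.5,
      gapExtension = 0.5, type = "local"))
    expect_equal(as.numeric(ours), ref, info = paste(a, b))
  }
})

test_that("tandem detection applies window and similarity jointly", {
  p <- random_protein(100)
  prot <- seq_set(c(g1 = p, g2 = p, g3 = p), alphabet = "AA")
  # adjacent identical genes: pair at 100% similarity
  loci <- gene_loci(c("g1", "g2"), c("Chr01", "Chr01"), c(1000, 12000),
                    c(4000, 15000))
  td <- detect_tandem(loci, prot)
  expect_equal(nrow(td), 1L)
  expect_equal(td$similarity, 100)
  expect_equal(td$gap_bp, 12000 - 4000 - 1)
  # identical genes 200 kbp apart fail the window
  far <- gene_loci(c("g1", "g2"), c("Chr01", "Chr01"), c(1000, 204000),
                   c(4000, 207000))
  expect_equal(nrow(detect_tandem(far, prot)), 0L)
  # different chromosomes never pair
  diffc <- gene_loci(c("g1", "g2"), c("Chr01", "Chr02"), c(1000, 12000),
                     c(4000, 15000))
  expect_equal(nrow(detect_tandem(diffc, prot)), 0L)
  # output independent of input ordering
  td2 <- detect_tandem(loci[2:1, ], prot)
  expect_equal(td2, td, ignore_attr = TRUE)
  expect_error(detect_tandem(loci, prot[c("g3")]), "no protein")
})

test_that("cluster chaining is transitive within the window", {
  loci <- gene_loci(c("a", "b", "c"), rep("Chr01", 3),
                    c(1, 50001, 90001), c(1000, 51000, 91000))
  cl <- find_clusters(loci, 1e5)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 3L)
  expect_equal(cl$members, "a,b,c")

  two <- gene_loci(c("a", "b"), rep("Chr01", 2), c(1, 150001),
                   c(1000, 151000))
  expect_equal(nrow(find_clusters(two, 1e5)), 0L)

  # inserting a midpoint gene merges the flanking clusters
  spread <- gene_loci(c("a", "b"), rep("Chr01", 2), c(1, 190001),
                      c(1000, 191000))
  expect_equal(nrow(find_clusters(spread, 1e5)), 0L)
  merged <- gene_loci(c("a", "m", "b"), rep("Chr01", 3),
                      c(1, 95001, 190001), c(1000, 96000, 191000))
  cl <- find_clusters(merged, 1e5)
  expect_equal(cl$n, 3L)
})
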