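test_that("FASTA reading normalizes case and wrapping, and round-trips", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "mkAa", "VW", ">p2", "ACDEFG"), path)
  ss <- read_fasta(path, "AA")
  expect_equal(names(ss), c("p1", "p2"))
  expect_equal(as.character(ss), c("MKAAVW", "ACDEFG"))

  # unwrapped upper-case input gives the identical record
  path2 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKAAVW"), path2)
  expect_equal(read_fasta(path2, "AA")[["p1"]], ss[["p1"]])

  # write -> read identity
  out <- withr::local_tempfile(fileext = ".faa")
  write_fasta(ss, out)
  expect_equal(unclass(read_fasta(out, "AA")), unclass(ss),
               ignore_attr = TRUE)
})

test_that("FASTA errors: duplicates, empty file, alphabet violations", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "MK", ">a", "MV"), path)
  expect_error(read_fasta(path, "AA"), "duplicate.*a")

  empty <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty, "AA"))

  bad <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "MKZ"), bad)
  expect_error(read_fasta(bad, "AA"), "Z")

  # X tolerated in proteins, B rejected
  expect_silent(seq_set(c(a = "MXK"), alphabet = "AA"))
  expect_error(seq_set(c(a = "MBK"), alphabet = "AA"), "B")
})

test_that("census table writing is deterministic and round-trips", {
  tab <- data.frame(gene = c("W2", "W1"), chromosome = c("Chr02", "Chr01"),
                    start = c(10, 5), end = c(100, 50), pi = c(6.1, 9.4),
                    mw_kda = c(42.5, 46.08),
                    heptapeptide = c("WRKYGQK", "WRKYGEK"),
                    zinc_finger = c("C2H2", "C2HC"), domains = c(1L, 2L),
                    group = c("IIe", "III"), length_aa = c(392L, 434L),
                    stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_census(tab, f1)
  write_census(tab, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_census(f1)
  expect_equal(back, validate_census(tab), ignore_attr = TRUE)

  tab$group[1] <- NA
  expect_error(write_census(tab, f1), "W2.*group|group.*W2")
  tab$group[1] <- "IV"
  expect_error(write_census(tab, f1), "invalid group")
})

test_that("newick writing preserves topology, lengths and supports", {
  tr <- ape::read.tree(text = "(a:1,b:2,c:3);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)

  tr2 <- ape::read.tree(text = "((a:1,b:1)95:0.5,(c:1,d:1)80:0.5);")
  write_newick(tr2, f)
  expect_match(paste(readLines(f), collapse = ""), "95")
  expect_error(write_newick(list(), f), "phylo")
})

test_that("chromosome labels sort by numeric suffix, not lexicographically", {
  labs <- c("Chr10", "Chr2", "Chr1")
  expect_equal(order(chromosome_rank(labs)), c(3, 2, 1))
  labs2 <- c("Chr01", "Chr10", "Chr09")
  expect_equal(order(chromosome_rank(labs2)), c(1, 3, 2))
})

test_that("gene loci enforce coordinate invariants", {
  expect_error(gene_loci("g", "Chr01", 0, 10), ">= 1")
  expect_error(gene_loci("g", "Chr01", 10, 5), ">= start")
  expect_error(gene_loci("g", "", 1, 5), "non-empty")
  ok <- gene_loci(c("g1", "g2"), c("Chr01", "Chr02"), c(1, 5), c(10, 8))
  expect_s3_class(ok, "gene_loci")
})

test_that("GFF3 writer emits 1-based inclusive exon features", {
  st <- list(list(gene_id = "g1",
                  exons = cbind(start = c(1L, 101L), end = c(50L, 180L))))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_structures_gff3(st, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  exons <- grep("\texon\t", lines, value = TRUE)
  expect_length(exons, 2)
  expect_match(exons[1], "\t1\t50\t")
  expect_match(exons[2], "\t101\t180\t")
})
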