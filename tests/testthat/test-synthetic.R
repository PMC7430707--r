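test_that("the generator is deterministic: same seed, byte-identical files", {
  cfg <- family_config(n_genes = 12, seed = 81)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_family(generate_family(cfg), d1)
  write_family(generate_family(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the sequences
  fam_b <- generate_family(family_config(n_genes = 12, seed = 82))
  fam_a <- generate_family(cfg)
  expect_false(identical(unclass(fam_a$proteins), unclass(fam_b$proteins)))
})

test_that("generated architectures match their subgroup by construction", {
  fam <- generate_family(family_config(n_genes = 21, divergence = 0,
                                       variant_rate = 0, seed = 83))
  for (id in names(fam$proteins)) {
    d <- scan_domains(fam$proteins[[id]])
    sg <- fam$truth$group[[id]]
    expect_equal(nrow(d), if (sg == "I") 2L else 1L, info = id)
    expect_true(all(d$finger_type == if (sg == "III") "C2HC" else "C2H2"),
                info = id)
    expect_true(all(d$motif == "WRKYGQK"), info = id)
  }
})

test_that("every generated CDS concatenates exactly from its true exons", {
  fam <- generate_family(family_config(n_genes = 15, seed = 84))
  for (id in names(fam$proteins)) {
    ex <- fam$truth$exons[[id]]
    spliced <- paste(vapply(seq_len(nrow(ex)), function(k) {
      substr(fam$genomic[[id]], ex[k, "start"], ex[k, "end"])
    }, character(1)), collapse = "")
    expect_equal(spliced, fam$cds[[id]], info = id)
    expect_equal(nrow(ex) - 1L, unname(fam$truth$n_introns[id]))
  }
  # CDS translates back to the protein (with a stop codon appended)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unclass(fam$cds))))
  expect_equal(unname(substr(aa, 1, nchar(aa) - 1)),
               as.character(fam$proteins))
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "*"))
})

test_that("heptapeptide variants appear at the configured rate", {
  fam <- generate_family(family_config(n_genes = 60, variant_rate = 0,
                                       seed = 85))
  hp <- vapply(names(fam$proteins), function(id) {
    scan_domains(fam$proteins[[id]])$motif[1]
  }, character(1))
  expect_true(all(hp == "WRKYGQK"))

  fam2 <- generate_family(family_config(n_genes = 60, variant_rate = 1,
                                        seed = 86))
  expect_true(all(fam2$truth$heptapeptide %in%
                    c("WRKYGEK", "WRKYGKK", "WRKYGSK", "WRKSGQR")))
})

test_that("planted promoter elements are recorded and recoverable", {
  fam <- generate_family(family_config(n_genes = 6, seed = 87))
  lib <- cis_element_library()
  planted <- fam$truth$planted_elements
  expect_true(all(table(planted$gene) == 3))  # W-box + ABRE + MBS
  for (r in seq_len(nrow(planted))) {
    hits <- scan_elements(fam$promoters[[planted$gene[r]]], lib)
    match_here <- hits[hits$element == planted$element[r] &
                         hits$strand == "+", ]
    expect_true(planted$position[r] %in% match_here$position,
                info = paste(planted$gene[r], planted$element[r]))
  }
})

test_that("corruption removes genes from the family", {
  fam <- generate_family(family_config(n_genes = 8, seed = 88))
  ids <- names(fam$proteins)[1:3]
  cor <- corrupt(fam, setNames(c("break-heptapeptide",
                                 "delete-zinc-finger",
                                 "shuffle-sequence"), ids))
  for (id in ids) {
    expect_equal(nrow(scan_domains(cor$proteins[[id]])), 0L, info = id)
    expect_true(is.na(cor$truth$group[[id]]))
  }
  # untouched genes keep their domains
  others <- setdiff(names(fam$proteins), ids)
  for (id in others) {
    expect_gt(nrow(scan_domains(cor$proteins[[id]])), 0L)
  }
  # empty op list is the identity
  expect_identical(corrupt(fam, character(0)), fam)
  expect_error(corrupt(fam, c(NOPE = "shuffle-sequence")), "unknown gene")
})

test_that("shuffling essentially never recreates a WRKY domain", {
  fam <- generate_family(family_config(n_genes = 2, n_tandem_pairs = 0L,
                                       seed = 89))
  id <- names(fam$proteins)[1]
  broken <- 0L
  for (s in 1:50) {
    cor <- corrupt(fam, setNames("shuffle-sequence", id), seed = s)
    if (nrow(scan_domains(cor$proteins[[id]])) == 0L) broken <- broken + 1L
  }
  expect_gte(broken, 49L)
})

test_that("configuration invariants are enforced", {
  expect_error(family_config(n_genes = 10, seed = 1, n_tandem_pairs = 6),
               "tandem")
  expect_error(family_config(n_genes = 10, divergence = 0.9, seed = 1))
  expect_error(family_config(n_genes = 10), "seed")
})
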