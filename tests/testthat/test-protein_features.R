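test_that("heptapeptide scanning admits the documented variants", {
  p <- paste0(strrep("A", 20), "WRKYGQK", strrep("A", 20))
  hp <- find_heptapeptides(p)
  expect_equal(hp$position, 21L)
  expect_equal(hp$variant_class, "canonical")
  expect_equal(hp$hamming, 0L)

  expect_equal(nrow(find_heptapeptides("AAAA")), 0L)

  # named variants at their observed Hamming distances
  for (v in c("WRKYGEK", "WRKYGKK", "WRKYGSK", "WRKSGQR")) {
    hp <- find_heptapeptides(paste0("AAA", v, "AAA"))
    expect_equal(hp$motif, v)
    expect_equal(hp$variant_class, v)
  }
  # WRK prefix with <=2 mismatches, not a named variant -> "other"
  hp <- find_heptapeptides("AAAWRKAGQAAA")
  expect_equal(hp$variant_class, "other")
  # broken prefix never matches even at distance 1
  expect_equal(nrow(find_heptapeptides("AAAARKYGQKAAA")), 0L)
  # strict mode admits the canonical motif only
  expect_equal(nrow(find_heptapeptides("AAAWRKYGEKAAA", max_mismatch = 0)),
               0L)
})

test_that("zinc finger scanning matches the generalized spacer layout", {
  mk <- function(s1, s2, term) {
    paste0(strrep("A", 10), "C", strrep("A", s1), "C", strrep("A", s2),
           "H", "A", term, strrep("A", 10))
  }
  z <- find_zinc_fingers(mk(4, 23, "H"))
  expect_equal(nrow(z), 1L)
  expect_equal(z$finger_type, "C2H2")
  expect_equal(c(z$spacer1, z$spacer2), c(4L, 23L))

  z <- find_zinc_fingers(mk(7, 23, "C"))
  expect_equal(z$finger_type, "C2HC")
  expect_equal(z$spacer1, 7L)

  # out-of-range spacers do not match
  expect_equal(nrow(find_zinc_fingers(mk(8, 23, "H"))), 0L)
  expect_equal(nrow(find_zinc_fingers(mk(4, 21, "H"))), 0L)
  expect_equal(nrow(find_zinc_fingers(strrep("A", 60))), 0L)

  # X never satisfies a coordinating position
  s <- mk(4, 23, "H")
  sx <- sub("C", "X", s)  # first Cys replaced
  expect_equal(nrow(find_zinc_fingers(sx)), 0L)

  expect_error(find_zinc_fingers(s, search_start = 1000), "outside")
})

test_that("domain scanning pairs signatures with downstream fingers", {
  one <- domain_protein()
  d <- scan_domains(one)
  expect_equal(nrow(d), 1L)
  expect_equal(d$finger_type, "C2H2")
  expect_true(d$finger_position > d$position + 6)

  two <- paste0(domain_protein(), domain_protein(type = "C2HC", s1 = 7))
  d2 <- scan_domains(two)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$finger_type, c("C2H2", "C2HC"))

  expect_equal(nrow(scan_domains(strrep("A", 100))), 0L)

  # a heptapeptide too far from its finger is not a domain
  far <- paste0(strrep("A", 5), "WRKYGQK", strrep("A", 60),
                "C", strrep("A", 4), "C", strrep("A", 23), "HAH")
  expect_equal(nrow(scan_domains(far, linker_max = 50)), 0L)
  expect_equal(nrow(scan_domains(far, linker_max = 70)), 1L)
})

test_that("domain scanning is position-shift equivariant", {
  base <- domain_protein()
  d0 <- scan_domains(base)
  for (k in c(1L, 7L, 23L)) {
    dk <- scan_domains(paste0(strrep("G", k), base))
    expect_equal(dk$position, d0$position + k)
    expect_equal(dk$finger_position, d0$finger_position + k)
    expect_equal(dk$span_end, d0$span_end + k)
  }
})

test_that("HARF motif matching covers both alternates", {
  expect_equal(find_harf(paste0("AAA", "RTGHARFRRAP", "AA")), 4L)
  expect_equal(find_harf(paste0("RTGHARFRRGP")), 1L)
  expect_length(find_harf("RTGHARFRRTP"), 0)
})

test_that("redundancy removal clusters by global identity", {
  s <- random_protein(100)
  cc <- strsplit(s, "")[[1]]
  cc[50] <- setdiff(c("A", "G"), cc[50])[1]
  s_mut <- paste(cc, collapse = "")
  set.seed(4)
  u1 <- random_protein(80)
  u2 <- random_protein(90)

  # identical pair collapses
  dd <- dedup_sequences(seq_set(c(a = s, b = s), alphabet = "AA"))
  expect_equal(length(dd), 1L)

  # 1 substitution in 100 residues: identity 0.99 >= 0.95 -> one rep
  dd <- dedup_sequences(seq_set(c(a = s, b = s_mut), alphabet = "AA"), 0.95)
  expect_equal(length(dd), 1L)
  expect_equal(unname(attr(dd, "clusters")[["b"]]),
               unname(attr(dd, "clusters")[["a"]]))

  # unrelated sequences are both retained, in input order
  dd <- dedup_sequences(seq_set(c(x = u1, y = u2), alphabet = "AA"), 0.95)
  expect_equal(names(dd), c("x", "y"))
  expect_error(dedup_sequences(seq_set(c(a = s), alphabet = "AA"), 0.4))
})

test_that("per-protein feature report summarizes domains and physchem", {
  set <- seq_set(c(g1 = domain_protein(),
                   g2 = paste0(domain_protein(),
                               domain_protein(type = "C2HC", s1 = 7))),
                 alphabet = "AA")
  ft <- protein_features(set)
  expect_equal(ft$n_domains, c(1L, 2L))
  expect_equal(ft$zinc_finger, c("C2H2", "mixed"))
  expect_true(all(ft$mw_kda > 0))
  expect_true(all(ft$pi > 0 & ft$pi < 14))
})
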