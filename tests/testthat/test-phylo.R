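test_that("p-distance implements pairwise deletion", {
  expect_equal(p_distance_matrix(as_msa(c(a = "AAAA", b = "AAAA")))["a", "b"],
               0)
  expect_equal(p_distance_matrix(as_msa(c(a = "AAAA", b = "AAAT")))["a", "b"],
               0.25)
  # the gap column is excluded: 0 mismatches over 3 comparable sites
  D <- p_distance_matrix(as_msa(c(a = "A-CG", b = "AACG")))
  expect_equal(D["a", "b"], 0)
  expect_equal(attr(D, "sites")["a", "b"], 3)
  # no comparable sites is an error naming the pair
  expect_error(p_distance_matrix(as_msa(c(a = "A--", b = "-AA"))),
               "a.*b|b.*a")
  # premetric properties on random gapped rows
  set.seed(41)
  rows <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), 30, TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = "")
  }, character(1))
  names(rows) <- paste0("r", 1:4)
  D <- p_distance_matrix(as_msa(rows))
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(0, 4))
})

test_that("three-taxon NJ solves the three-point equations exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # la = (3+4-5)/2 = 1, lb = (3+5-4)/2 = 2, lc = (4+5-3)/2 = 3
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["a"]], 1)
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
})

test_that("NJ exactly recovers additive matrices from known trees", {
  set.seed(42)
  for (rep in 1:12) {
    ntax <- sample(4:8, 1)
    tr <- ape::rtree(ntax, rooted = FALSE,
                     br = function(n) runif(n, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
                 ignore_attr = TRUE)
    D2 <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
    expect_lt(max(abs(D - D2)), 1e-9)
  }
})

test_that("NJ is invariant to taxon order and validates input", {
  set.seed(43)
  tr <- ape::rtree(6, rooted = FALSE, br = function(n) runif(n, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  nj1 <- neighbor_joining(D)
  nj2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(nj1, nj2), 0, ignore_attr = TRUE)

  bad <- D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(neighbor_joining(bad), "symmetric")
  expect_error(neighbor_joining(D[1:2, 1:2]), "three")
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(44)
  for (rep in 1:5) {
    tr <- ape::rtree(7, rooted = FALSE, br = function(n) runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    noise <- matrix(runif(49, 0, 0.02), 7)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Dn <- D + noise
    expect_equal(ape::dist.topo(neighbor_joining(Dn), ape::nj(Dn)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic and detect strong signal", {
  set.seed(45)
  base1 <- paste(sample(c("A", "C", "D", "E", "F", "G"), 120, TRUE),
                 collapse = "")
  base2 <- paste(sample(c("H", "I", "K", "L", "M", "N"), 120, TRUE),
                 collapse = "")
  mut <- function(s, k) {
    cc <- strsplit(s, "")[[1]]
    i <- sample(length(cc), k)
    cc[i] <- sample(c("P", "Q", "R", "S", "T"), k, TRUE)
    paste(cc, collapse = "")
  }
  seqs <- c(a1 = mut(base1, 4), a2 = mut(base1, 4), a3 = mut(base1, 4),
            b1 = mut(base2, 4), b2 = mut(base2, 4), b3 = mut(base2, 4))
  tr <- bootstrap_supports(as_msa(seqs), 200, seed = 7)
  sup <- attr(tr, "supports")
  central <- sup[["b1|b2|b3"]]
  expect_gte(central, 95)

  tr2 <- bootstrap_supports(as_msa(seqs), 200, seed = 7)
  expect_identical(attr(tr2, "supports"), sup)

  # identical sequences: degenerate star-like case must not crash
  same <- setNames(rep(paste(rep("ACDE", 10), collapse = ""), 4),
                   paste0("t", 1:4))
  expect_no_error(bootstrap_supports(as_msa(same), 10, seed = 1))
  expect_error(bootstrap_supports(as_msa(seqs), 10), "seed")
})
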