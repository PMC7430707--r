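# Independent oracles used by the tests.  These deliberately avoid the
# package's own dynamic-programming / scanning code paths: alignments are
# scored by enumerating every monotone alignment path, pattern hits by a
# position-by-position check.

# all monotone alignment paths for sequence lengths (n, m), cached; each
# path is a character vector over D (pair), U (consume a), L (consume b)
.path_cache <- new.env(parent = emptyenv())
enumerate_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  rec <- function(i, j) {
    if (i == n && j == m) return(list(character(0)))
    out <- list()
    if (i < n && j < m) {
      out <- c(out, lapply(rec(i + 1, j + 1), function(p) c("D", p)))
    }
    if (i < n) out <- c(out, lapply(rec(i + 1, j), function(p) c("U", p)))
    if (j < m) out <- c(out, lapply(rec(i, j + 1), function(p) c("L", p)))
    out
  }
  paths <- rec(0, 0)
  .path_cache[[key]] <- paths
  paths
}

# score one alignment path under EMBOSS affine costs: first gap residue of
# a run costs `open`, later residues `ext`; U-runs and L-runs are distinct
score_path <- function(path, ca, cb, submat, open, ext) {
  i <- 0; j <- 0; s <- 0; prev <- ""
  for (mv in path) {
    if (mv == "D") {
      i <- i + 1; j <- j + 1
      s <- s + submat[ca[i], cb[j]]
    } else if (mv == "U") {
      i <- i + 1
      s <- s - if (prev == "U") ext else open
    } else {
      j <- j + 1
      s <- s - if (prev == "L") ext else open
    }
    prev <- mv
  }
  s
}

# brute-force optimal global score by exhaustive path enumeration
brute_global_score <- function(a, b, submat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  paths <- enumerate_paths(length(ca), length(cb))
  max(vapply(paths, score_path, numeric(1), ca = ca, cb = cb,
             submat = submat, open = open, ext = ext))
}

# brute-force optimal local score: best global score over all substring
# pairs, floored at 0 (the empty local alignment)
brute_local_score <- function(a, b, submat, open = 10, ext = 0.5) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) {
    for (j1 in 1:nb) for (j2 in j1:nb) {
      s <- brute_global_score(substr(a, i1, i2), substr(b, j1, j2),
                              submat, open, ext)
      if (s > best) best <- s
    }
  }
  best
}

# position-by-position IUPAC match oracle (forward strand only)
brute_iupac_positions <- function(seq, pattern) {
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
             B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  hits <- integer(0)
  if (length(sc) < w) return(hits)
  for (pos in 1:(length(sc) - w + 1)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!grepl(sc[pos + k - 1], codes[[pc[k]]], fixed = TRUE)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, pos)
  }
  hits
}

# random sequence helpers
random_protein <- function(n, alphabet = setdiff(names(wrkycensus:::AA_AVG_MASS), "X")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a minimal protein with one complete WRKY domain, by construction
domain_protein <- function(hept = "WRKYGQK", type = "C2H2", s1 = 4, s2 = 23,
                           lead = 10, tail = 10) {
  filler <- function(n) paste(rep("A", n), collapse = "")
  paste0(filler(lead), hept, filler(8),
         "C", filler(s1), "C", filler(s2), "H", "A",
         if (type == "C2H2") "H" else "C", filler(tail))
}
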