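# Pairwise and progressive alignment.
#
# All aligners share one affine-gap dynamic-programming kernel (src/) fed
# with a precomputed column-score matrix, so sequence-sequence and
# profile-profile alignment use identical gap bookkeeping.  Gap costs follow
# the EMBOSS convention: the first residue of a run costs `gap_open`, each
# further residue `gap_extend`.

#' Substitution matrix for an alphabet
#'
#' `"BLOSUM62"` is taken from Biostrings.  `"DNA"` builds the usual
#' match/mismatch matrix (+5/-4, ambiguity letter N scores 0).
#'
#' @param name `"BLOSUM62"` or `"DNA"`.
#' @return numeric substitution matrix with dimnames.
#' @export
substitution_matrix <- function(name = c("BLOSUM62", "DNA")) {
  name <- match.arg(name)
  if (name == "BLOSUM62") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    keep <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X")
    return(m[keep, keep])
  }
  letters4 <- c("A", "C", "G", "T", "N")
  m <- matrix(-4, 5, 5, dimnames = list(letters4, letters4))
  diag(m) <- 5
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

.encode_cols <- function(a, b, submat) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  bad <- setdiff(unique(c(ca, cb)), rownames(submat))
  if (length(bad)) {
    stop("character(s) absent from the substitution matrix: ",
         paste(sort(bad), collapse = ", "))
  }
  submat[ca, cb, drop = FALSE]
}

.path_to_strings <- function(a, b, path) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sa <- ifelse(path$ai == 0L, "-", ca[pmax(path$ai, 1L)])
  sb <- ifelse(path$bi == 0L, "-", cb[pmax(path$bi, 1L)])
  list(aligned_a = paste(sa, collapse = ""),
       aligned_b = paste(sb, collapse = ""))
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b sequences (plain strings).
#' @param submat substitution matrix; defaults to BLOSUM62.
#' @param gap_open,gap_extend positive gap penalties (EMBOSS convention).
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped strings)
#'   and `score`.
#' @export
needleman_wunsch <- function(a, b, submat = substitution_matrix("BLOSUM62"),
                             gap_open = 10, gap_extend = 0.5) {
  if (nchar(a) == 0L && nchar(b) == 0L) {
    return(list(aligned_a = "", aligned_b = "", score = 0))
  }
  if (nchar(a) == 0L || nchar(b) == 0L) {
    n <- max(nchar(a), nchar(b))
    gaps <- strrep("-", n)
    sc <- -(gap_open + (n - 1) * gap_extend)
    if (nchar(a) == 0L) {
      return(list(aligned_a = gaps, aligned_b = b, score = sc))
    }
    return(list(aligned_a = a, aligned_b = gaps, score = sc))
  }
  S <- .encode_cols(a, b, submat)
  res <- .align_affine_cpp(S, gap_open, gap_extend, FALSE)
  out <- .path_to_strings(a, b, res)
  out$score <- res$score
  out
}

#' Global alignment identity
#'
#' Identity of the optimal global alignment: matching columns divided by
#' total alignment columns (gap columns included in the denominator).
#'
#' @inheritParams needleman_wunsch
#' @return fraction in `[0, 1]`.
#' @export
alignment_identity <- function(a, b, submat = substitution_matrix("BLOSUM62"),
                               gap_open = 10, gap_extend = 0.5) {
  al <- needleman_wunsch(a, b, submat, gap_open, gap_extend)
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  if (length(ca) == 0L) return(1)
  sum(ca == cb & ca != "-") / length(ca)
}

.msa_new <- function(rows) structure(rows, class = "msa")

#' @export
print.msa <- function(x, ...) {
  cat("multiple alignment:", length(x), "rows x", nchar(x[[1]]), "columns\n")
  for (i in head(seq_along(x), 8L)) {
    cat(sprintf("  %-20s %s\n", names(x)[i], substr(x[[i]], 1, 50)))
  }
  if (length(x) > 8L) cat("  ...\n")
  invisible(x)
}

# shared 3-mer distance used for the guide tree
.kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  tabs <- lapply(kmers, table)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ti <- tabs[[i]]; tj <- tabs[[j]]
      common <- intersect(names(ti), names(tj))
      shared <- sum(pmin(ti[common], tj[common]))
      denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
      D[i, j] <- D[j, i] <- 1 - shared / denom
    }
  }
  D
}

# frequency profile of a gapped row set: (alphabet x columns), gaps excluded,
# normalised by the number of rows so sparse columns carry less weight
.profile_freq <- function(rows, alphabet) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  L <- ncol(mat)
  P <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (a in alphabet) P[a, ] <- colSums(mat == a)
  P / length(rows)
}

.merge_profiles <- function(pa, pb, submat, gap_open, gap_extend) {
  alphabet <- rownames(submat)
  FA <- .profile_freq(pa, alphabet)
  FB <- .profile_freq(pb, alphabet)
  S <- t(FA) %*% submat %*% FB
  res <- .align_affine_cpp(S, gap_open, gap_extend, FALSE)
  insert_gaps <- function(rows, idx, L) {
    vapply(rows, function(r) {
      cr <- strsplit(r, "")[[1]]
      out <- rep("-", length(idx))
      out[idx != 0L] <- cr[idx[idx != 0L]]
      paste(out, collapse = "")
    }, character(1))
  }
  c(insert_gaps(pa, res$ai), insert_gaps(pb, res$bi))
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from 3-mer distances clustered by UPGMA (average-linkage
#' [stats::hclust]); profiles are merged leaves-inward with profile-profile
#' alignment under the same affine-gap kernel as [needleman_wunsch()].
#' Gaps, once introduced, are never removed.
#'
#' @param set a [seq_set()] or named character vector of sequences.
#' @inheritParams needleman_wunsch
#' @return an `"msa"` object: named character vector of equal-length gapped
#'   rows, in input order.
#' @export
progressive_msa <- function(set, submat = substitution_matrix("BLOSUM62"),
                            gap_open = 10, gap_extend = 0.5) {
  seqs <- setNames(as.character(set), names(set))
  n <- length(seqs)
  if (n == 0L) stop("no sequences to align")
  if (n == 1L) return(.msa_new(seqs))
  if (n == 2L) {
    al <- needleman_wunsch(seqs[[1]], seqs[[2]], submat, gap_open, gap_extend)
    return(.msa_new(setNames(c(al$aligned_a, al$aligned_b), names(seqs))))
  }
  D <- .kmer_distance(seqs)
  hc <- hclust(as.dist(D), method = "average")
  profiles <- vector("list", n - 1L)
  get_profile <- function(idx) {
    if (idx < 0L) seqs[-idx] else profiles[[idx]]
  }
  for (s in seq_len(nrow(hc$merge))) {
    pa <- get_profile(hc$merge[s, 1])
    pb <- get_profile(hc$merge[s, 2])
    profiles[[s]] <- .merge_profiles(pa, pb, submat, gap_open, gap_extend)
  }
  final <- profiles[[n - 1L]]
  .msa_new(final[names(seqs)])
}

#' Coerce a gapped FASTA or named vector to an msa object
#' @param rows named character vector of equal-length gapped rows.
#' @return an `"msa"` object.
#' @export
as_msa <- function(rows) {
  rows <- setNames(as.character(rows), names(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  .msa_new(rows)
}
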