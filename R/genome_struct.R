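# Exon-intron inference from genomic + CDS pairs, plus tandem-duplication
# and gene-cluster detection under the 100-kbp / 70%-similarity criterion.

# maximal run of equality between genomic (from gi) and cds (from cj)
.max_run <- function(g, c, gi, cj) {
  ng <- length(g); nc <- length(c)
  L <- min(ng - gi + 1L, nc - cj + 1L)
  if (L <= 0L) return(0L)
  neq <- which(g[gi:(gi + L - 1L)] != c[cj:(cj + L - 1L)])
  if (!length(neq)) L else neq[1] - 1L
}

#' Infer exon-intron structure from genomic and CDS sequences
#'
#' Exons are recovered by exact-match chaining: the longest common prefix
#' anchors the first exon; after each exon the next exon resumes at an
#' exact match of the remaining CDS.  Among candidate splits, introns with
#' canonical `GT..AG` termini are preferred, then longer exons, then the
#' leftmost resumption point.  The concatenation of the recovered exons
#' must equal the CDS exactly.
#'
#' @param genomic genomic (unspliced) nucleotide string; must begin at the
#'   CDS start (trailing sequence beyond the final exon is ignored).
#' @param cds coding sequence string.
#' @param gene_id identifier carried into the result.
#' @return list with `gene_id`, `exons` (matrix of 1-based inclusive
#'   `start`/`end` on the genomic sequence), `n_introns`, and
#'   `splice_sites` (character vector of `"GT..AG"`-style dinucleotide
#'   pairs, one per intron).
#' @export
infer_structure <- function(genomic, cds, gene_id = "gene") {
  g <- strsplit(toupper(as.character(genomic)[[1]]), "")[[1]]
  cc <- strsplit(toupper(as.character(cds)[[1]]), "")[[1]]
  ng <- length(g); nc <- length(cc)
  if (nc == 0L) stop("empty CDS")
  if (ng < nc) stop("genomic sequence shorter than CDS")
  if (g[1] != cc[1]) {
    stop("CDS not reconstructible from genomic sequence: mismatch at CDS ",
         "offset 1")
  }
  solve <- function(gi, cj) {
    # returns list of exon start/end pairs on genomic, or NULL
    m <- .max_run(g, cc, gi, cj)
    if (m == 0L) return(NULL)
    if (cj + m - 1L == nc) {
      return(list(c(gi, gi + m - 1L)))  # final exon
    }
    # candidate splits: exon length L (<= m), resumption point p
    cands <- list()
    for (L in seq(m, 1L)) {
      nxt <- cj + L  # next CDS position to place
      rest_start <- gi + L + 1L  # intron must be non-empty
      if (rest_start > ng) next
      gstr <- paste(g[rest_start:ng], collapse = "")
      # probe with the longest CDS prefix that still occurs downstream
      # (the next exon may be shorter than the probe ceiling)
      hits <- -1L
      for (k in seq(min(12L, nc - nxt + 1L), 1L)) {
        probe <- paste(cc[nxt:(nxt + k - 1L)], collapse = "")
        hits <- gregexpr(probe, gstr, fixed = TRUE)[[1]]
        if (hits[1] != -1L) break
      }
      if (hits[1] == -1L) next
      for (h in as.integer(hits)) {
        p <- rest_start + h - 1L
        intron_start <- gi + L
        canonical <- (p - intron_start >= 4L) &&
          g[intron_start] == "G" && g[intron_start + 1L] == "T" &&
          g[p - 2L] == "A" && g[p - 1L] == "G"
        cands[[length(cands) + 1L]] <- list(L = L, p = p,
                                            canonical = canonical)
      }
    }
    if (!length(cands)) return(NULL)
    score <- vapply(cands, function(x)
      c(-as.integer(x$canonical), -x$L, x$p), numeric(3))
    ord <- order(score[1, ], score[2, ], score[3, ])
    for (idx in ord) {
      cand <- cands[[idx]]
      rest <- solve(cand$p, cj + cand$L)
      if (!is.null(rest)) {
        return(c(list(c(gi, gi + cand$L - 1L)), rest))
      }
    }
    NULL
  }
  exons <- solve(1L, 1L)
  if (is.null(exons)) {
    # locate first irreconcilable CDS offset for the error message
    m <- .max_run(g, cc, 1L, 1L)
    stop("CDS not reconstructible from genomic sequence: failure near CDS ",
         "offset ", m + 1L)
  }
  ex <- do.call(rbind, exons)
  colnames(ex) <- c("start", "end")
  spliced <- paste(unlist(lapply(exons, function(e)
    g[e[1]:e[2]])), collapse = "")
  if (spliced != paste(cc, collapse = "")) {
    stop("internal error: exon concatenation does not equal the CDS")
  }
  ni <- nrow(ex) - 1L
  ss <- character(0)
  if (ni > 0L) {
    for (k in seq_len(ni)) {
      i0 <- ex[k, "end"] + 1L; i1 <- ex[k + 1L, "start"] - 1L
      ss <- c(ss, paste0(g[i0], g[i0 + 1L], "..", g[i1 - 1L], g[i1]))
    }
  }
  list(gene_id = gene_id, exons = ex, n_introns = ni, splice_sites = ss)
}

#' Local alignment percent similarity (Smith-Waterman)
#'
#' Optimal local alignment under affine gaps; similarity is the EMBOSS
#' convention: positively scoring aligned pairs divided by total alignment
#' columns (gap columns included), times 100.
#'
#' @inheritParams needleman_wunsch
#' @return percent similarity in `[0, 100]`, with the alignment attached
#'   as attributes `aligned_a`/`aligned_b`/`score`.
#' @export
smith_waterman_similarity <- function(a, b,
                                      submat = substitution_matrix("BLOSUM62"),
                                      gap_open = 10, gap_extend = 0.5) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    warning("empty sequence: similarity 0")
    return(0)
  }
  S <- .encode_cols(a, b, submat)
  res <- .align_affine_cpp(S, gap_open, gap_extend, TRUE)
  if (length(res$ai) == 0L) return(0)
  st <- .path_to_strings(a, b, res)
  ca <- strsplit(st$aligned_a, "")[[1]]
  cb <- strsplit(st$aligned_b, "")[[1]]
  pairup <- ca != "-" & cb != "-"
  pos <- sum(submat[cbind(ca[pairup], cb[pairup])] > 0)
  out <- 100 * pos / length(ca)
  attr(out, "aligned_a") <- st$aligned_a
  attr(out, "aligned_b") <- st$aligned_b
  attr(out, "score") <- res$score
  out
}

# gap in bp between two loci spans: 0 if they overlap
.span_gap <- function(s1, e1, s2, e2) {
  if (e1 >= s2 && e2 >= s1) return(0)
  if (s2 > e1) s2 - e1 - 1 else s1 - e2 - 1
}

#' Detect tandem duplications
#'
#' Same-chromosome gene pairs whose span gap is at most `window_bp` and
#' whose protein similarity ([smith_waterman_similarity()]) is at least
#' `min_similarity` percent.
#'
#' @param loci a [gene_loci()] data.frame.
#' @param proteins a [seq_set()] containing one protein per locus
#'   (matched by `gene_id`).
#' @param window_bp maximum genomic gap in bp (default 100 kbp).
#' @param min_similarity minimum percent similarity (default 70).
#' @param submat substitution matrix for the local alignment.
#' @return data.frame with `gene_a`, `gene_b` (a before b in positional
#'   order), `gap_bp`, `similarity`.
#' @export
detect_tandem <- function(loci, proteins, window_bp = 1e5,
                          min_similarity = 70,
                          submat = substitution_matrix("BLOSUM62")) {
  missing_prot <- setdiff(loci$gene_id, names(proteins))
  if (length(missing_prot)) {
    stop("no protein for locus/loci: ",
         paste(missing_prot, collapse = ", "))
  }
  ord <- order(chromosome_rank(loci$chromosome), loci$start, loci$end,
               loci$gene_id)
  loci <- loci[ord, , drop = FALSE]
  out <- list()
  for (chrom in unique(loci$chromosome)) {
    sub <- loci[loci$chromosome == chrom, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        gap <- .span_gap(sub$start[i], sub$end[i], sub$start[j], sub$end[j])
        if (gap > window_bp) next
        sim <- as.numeric(smith_waterman_similarity(
          proteins[[sub$gene_id[i]]], proteins[[sub$gene_id[j]]], submat))
        if (sim >= min_similarity) {
          out[[length(out) + 1L]] <- data.frame(
            gene_a = sub$gene_id[i], gene_b = sub$gene_id[j],
            gap_bp = gap, similarity = sim, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      gap_bp = numeric(0), similarity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect gene clusters by transitive chaining
#'
#' Consecutive genes on a chromosome whose start-to-start distance is at
#' most `chain_window_bp` join one cluster; clusters with at least two
#' members are reported.
#'
#' @param loci a [gene_loci()] data.frame.
#' @param chain_window_bp chaining window in bp (default 100 kbp).
#' @return data.frame with `chromosome`, `members` (comma-joined ids in
#'   positional order), `n`, `span_bp`.
#' @export
find_clusters <- function(loci, chain_window_bp = 1e5) {
  ord <- order(chromosome_rank(loci$chromosome), loci$start, loci$end,
               loci$gene_id)
  loci <- loci[ord, , drop = FALSE]
  out <- list()
  for (chrom in unique(loci$chromosome)) {
    sub <- loci[loci$chromosome == chrom, , drop = FALSE]
    if (nrow(sub) < 2L) next
    grp <- cumsum(c(1, diff(sub$start) > chain_window_bp))
    for (gid in unique(grp)) {
      members <- sub[grp == gid, , drop = FALSE]
      if (nrow(members) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom,
        members = paste(members$gene_id, collapse = ","),
        n = nrow(members),
        span_bp = max(members$end) - min(members$start) + 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), members = character(0),
                      n = integer(0), span_bp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
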