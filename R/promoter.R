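# Promoter extraction and cis-element scanning with IUPAC degeneracy on
# both strands.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Default cis-element library
#'
#' Literature-standard IUPAC cores for the named elements commonly screened
#' in plant promoters.  The library is a plain data.frame and can be
#' edited, extended or replaced; a TSV copy ships in
#' `inst/extdata/cis_elements.tsv`.
#'
#' @return data.frame with columns `name`, `iupac`, `class`.
#' @export
cis_element_library <- function() {
  read.delim(system.file("extdata", "cis_elements.tsv",
                         package = "wrkycensus"),
             stringsAsFactors = FALSE)
}

.iupac_to_regex <- function(pat) {
  cc <- strsplit(toupper(pat), "")[[1]]
  bad <- setdiff(cc, names(IUPAC_CODES))
  if (length(bad)) stop("non-IUPAC character(s): ",
                        paste(unique(bad), collapse = ", "))
  paste(vapply(cc, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

#' Extract a fixed-length promoter (upstream region)
#'
#' For `+`-strand genes, the `length_bp` bases ending immediately before
#' the gene start; for `-`-strand genes, the reverse complement of the
#' `length_bp` bases beginning immediately after the gene end.  Promoters
#' are truncated (with a warning) at chromosome edges.
#'
#' @param chrom_seq chromosome/contig sequence string.
#' @param start,end 1-based inclusive gene coordinates on `chrom_seq`.
#' @param length_bp promoter length (default 1500).
#' @param strand `"+"` or `"-"`.
#' @return promoter string, 5' to 3' on the gene's strand.
#' @export
extract_promoter <- function(chrom_seq, start, end, length_bp = 1500L,
                             strand = "+") {
  stopifnot(length_bp >= 1L)
  L <- nchar(chrom_seq)
  if (start < 1L || end > L || end < start) {
    stop("locus outside the chromosome sequence")
  }
  if (strand == "+") {
    to <- start - 1L
    if (to < 1L) {
      warning("no upstream sequence: empty promoter")
      return("")
    }
    from <- max(1L, to - length_bp + 1L)
    if (to - from + 1L < length_bp) {
      warning("promoter truncated at chromosome edge (",
              to - from + 1L, " bp)")
    }
    substr(chrom_seq, from, to)
  } else if (strand == "-") {
    from <- end + 1L
    if (from > L) {
      warning("no upstream sequence: empty promoter")
      return("")
    }
    to <- min(L, from + length_bp - 1L)
    if (to - from + 1L < length_bp) {
      warning("promoter truncated at chromosome edge (",
              to - from + 1L, " bp)")
    }
    revcomp(substr(chrom_seq, from, to))
  } else stop("strand must be '+' or '-'")
}

#' Scan a promoter for cis-elements
#'
#' Reports every match of every library pattern on both strands,
#' overlapping matches included.  Positions are 1-based on the promoter as
#' given (5' to 3' of the gene's strand); minus-strand hits are matches of
#' the pattern's reverse complement, positioned by their leftmost base.
#'
#' @param promoter promoter string.
#' @param library data.frame with columns `name`, `iupac` (see
#'   [cis_element_library()]).
#' @param gene_id optional id carried into the hits.
#' @return data.frame ordered by (position, name, strand) with columns
#'   `gene`, `element`, `position`, `strand`, `match`.
#' @export
scan_elements <- function(promoter, library = cis_element_library(),
                          gene_id = NA_character_) {
  if (!nrow(library)) stop("empty element library")
  if (anyDuplicated(library$name)) stop("duplicate element names in library")
  hits <- list()
  for (k in seq_len(nrow(library))) {
    pat <- library$iupac[k]
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp(pat)
      rx <- paste0("(?=", .iupac_to_regex(p), ")")
      m <- gregexpr(rx, promoter, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      starts <- as.integer(m)
      hits[[length(hits) + 1L]] <- data.frame(
        gene = gene_id, element = library$name[k], position = starts,
        strand = strand,
        match = substring(promoter, starts, starts + nchar(pat) - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(gene = character(0), element = character(0),
                      position = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$element, out$strand), , drop = FALSE]
}

#' Summarize cis-element hits per gene
#'
#' @param hits data.frame of hits (rbind of [scan_elements()] results over
#'   genes).
#' @param genes character vector of all gene ids (zero rows included).
#' @param elements character vector of element names (defaults to those in
#'   the hits).
#' @return list with `counts` (gene x element matrix), `presence`
#'   (logical matrix), and `genes_with_element` (named vector of gene
#'   counts per element).
#' @export
element_summary <- function(hits, genes,
                            elements = sort(unique(hits$element))) {
  counts <- matrix(0L, length(genes), length(elements),
                   dimnames = list(genes, elements))
  if (nrow(hits)) {
    tab <- table(factor(hits$gene, levels = genes),
                 factor(hits$element, levels = elements))
    counts[] <- as.integer(tab)
  }
  presence <- counts > 0L
  list(counts = counts, presence = presence,
       genes_with_element = colSums(presence))
}
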