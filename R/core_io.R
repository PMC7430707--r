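# Shared domain types and format I/O.
#
# Sequences travel as a "seq_set": a named character vector of upper-case
# sequences with an "alphabet" attribute ("AA" or "DNA").  Coordinates are
# 1-based inclusive throughout; conversion to other conventions happens only
# inside format writers.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
DNA_LETTERS <- c("A", "C", "G", "T", "N")

#' Construct a sequence set
#'
#' A sequence set is a named character vector of upper-case sequences
#' carrying an `alphabet` attribute.  Ambiguous amino acids other than `X`
#' (and nucleotides other than `N`) are rejected: downstream pattern
#' matching and pI/MW computation are defined only for canonical residues.
#'
#' @param seqs character vector of sequences.
#' @param ids character vector of unique identifiers.
#' @param alphabet `"AA"` or `"DNA"`.
#' @return A named character vector of class `"seq_set"`.
#' @export
seq_set <- function(seqs, ids = names(seqs), alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (is.null(ids)) stop("sequence ids are required")
  ids <- as.character(ids)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  allowed <- if (alphabet == "AA") AA_LETTERS else DNA_LETTERS
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), allowed)
  if (length(bad)) {
    stop("character(s) outside the ", alphabet, " alphabet: ",
         paste(sort(bad), collapse = ", "))
  }
  structure(setNames(seqs, ids), alphabet = alphabet, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), attr(x, "alphabet"), "sequences\n")
  show <- head(seq_along(x), 6L)
  for (i in show) {
    cat(sprintf("  %-20s %6d %s\n", names(x)[i], nchar(x[[i]]),
                substr(x[[i]], 1, 40)))
  }
  if (length(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  structure(NextMethod(), alphabet = attr(x, "alphabet"), class = "seq_set")
}

#' Read a FASTA file into a sequence set
#'
#' Headers are truncated at the first whitespace to form the id; sequence
#' lines are concatenated, whitespace-stripped and upper-cased.  Duplicate
#' ids, empty files and alphabet violations are errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"AA"` or `"DNA"`.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  seq_set(as.character(ss), ids = ids, alphabet = alphabet)
}

#' Write a sequence set (or named character vector) as FASTA
#'
#' @param seqs named character vector of sequences (gapped rows allowed,
#'   e.g. an alignment).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a table of gene loci
#'
#' @param gene_id character gene identifiers.
#' @param chromosome chromosome labels, e.g. `"Chr01"`.
#' @param start,end 1-based inclusive coordinates.
#' @return data.frame of class `"gene_loci"`.
#' @export
gene_loci <- function(gene_id, chromosome, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 1)) stop("start coordinates must be >= 1")
  if (any(end < start)) stop("end must be >= start")
  if (any(!nzchar(chromosome))) stop("chromosome labels must be non-empty")
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = as.character(chromosome),
                   start = start, end = end, stringsAsFactors = FALSE)
  class(df) <- c("gene_loci", "data.frame")
  df
}

#' Natural order for chromosome labels
#'
#' Sorts by the numeric suffix (Chr1 < Chr2 < ... < Chr10), falling back to
#' lexicographic order for labels without a number.
#'
#' @param chrom character vector of chromosome labels.
#' @return integer ranks usable with [order()].
#' @export
chromosome_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)\\s*$", "\\1", chrom)))
  has <- !is.na(num)
  key <- ifelse(has, sprintf("%012.0f", num), chrom)
  match(key, sort(unique(key)))
}

CENSUS_COLUMNS <- c("gene", "chromosome", "start", "end", "pi", "mw_kda",
                    "heptapeptide", "zinc_finger", "domains", "group",
                    "length_aa")
GROUP_LEVELS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "NG")

#' Validate a census table
#'
#' A census table has one row per gene with the columns gene, chromosome,
#' start, end, pi, mw_kda, heptapeptide, zinc_finger, domains, group and
#' length_aa (mirroring a family summary table).
#'
#' @param table data.frame to validate.
#' @return the table, with columns ordered canonically.
#' @export
validate_census <- function(table) {
  miss <- setdiff(CENSUS_COLUMNS, names(table))
  if (length(miss)) stop("census table lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (col in CENSUS_COLUMNS) {
    bad <- is.na(table[[col]])
    if (any(bad)) {
      stop("gene ", table$gene[which(bad)[1]], ": missing field '", col, "'")
    }
  }
  if (anyDuplicated(table$gene)) stop("duplicate gene in census table")
  badg <- !table$group %in% GROUP_LEVELS
  if (any(badg)) {
    stop("gene ", table$gene[which(badg)[1]], ": invalid group label '",
         table$group[which(badg)[1]], "'")
  }
  badz <- !table$zinc_finger %in% c("C2H2", "C2HC", "mixed")
  if (any(badz)) {
    stop("gene ", table$gene[which(badz)[1]], ": invalid zinc finger type")
  }
  table[, c(CENSUS_COLUMNS, setdiff(names(table), CENSUS_COLUMNS))]
}

#' Write a census table as TSV
#'
#' Deterministic, fixed column order; round-trips through [read_census()].
#'
#' @param table census data.frame (see [validate_census()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(table, path) {
  table <- validate_census(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a census table written by [write_census()]
#' @param path TSV path.
#' @return census data.frame.
#' @export
read_census <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_census(tab)
}

#' Write a phylogenetic tree as Newick
#'
#' Bootstrap supports stored in `tree$node.label` are emitted as internal
#' node labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write inferred gene structures as GFF3
#'
#' One `gene` feature plus one `exon` feature per exon, 1-based inclusive
#' coordinates on the supplied genomic sequences.
#'
#' @param structures list of gene structures from [infer_structure()].
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_structures_gff3 <- function(structures, path, source = "wrkycensus") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (st in structures) {
    gid <- st$gene_id
    glen <- max(st$exons[, "end"])
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       gid, source, 1L, as.integer(glen), gid), con)
    for (k in seq_len(nrow(st$exons))) {
      writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t+\t.\tID=%s.exon%d;Parent=%s",
                         gid, source, as.integer(st$exons[k, "start"]),
                         as.integer(st$exons[k, "end"]), gid, k, gid), con)
    }
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
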