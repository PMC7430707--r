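# WRKY-specific protein features: the heptapeptide signature, the
# C2H2/C2HC zinc finger, complete domains, the HARF motif of subgroup IId,
# and redundancy removal.

CANONICAL_HEPTAPEPTIDE <- "WRKYGQK"
NAMED_VARIANTS <- c("WRKYGQK", "WRKYGEK", "WRKYGKK", "WRKYGSK", "WRKSGQR")

.hamming7 <- function(x, ref = CANONICAL_HEPTAPEPTIDE) {
  rc <- strsplit(ref, "")[[1]]
  vapply(strsplit(x, ""), function(cc) sum(cc != rc), integer(1))
}

#' Find WRKY heptapeptide signatures
#'
#' Admits every 7-mer with an exact `WRK` prefix whose Hamming distance to
#' the canonical `WRKYGQK` is at most `max_mismatch`, plus the named
#' variant `WRKSGQR` under a relaxed exact-`WR` rule.  Positions with `X`
#' never match a constrained position.
#'
#' @param protein a single protein string (or one element of a [seq_set()]).
#' @param max_mismatch maximum Hamming distance to `WRKYGQK` (0-2).
#' @return data.frame with columns `position` (1-based index of the W),
#'   `motif`, `variant_class` (`"canonical"`, a named variant, or
#'   `"other"`) and `hamming`.
#' @export
find_heptapeptides <- function(protein, max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0L, max_mismatch <= 2L)
  s <- as.character(protein)[[1]]
  L <- nchar(s)
  empty <- data.frame(position = integer(0), motif = character(0),
                      variant_class = character(0), hamming = integer(0),
                      stringsAsFactors = FALSE)
  if (L < 7L) return(empty)
  pos <- 1:(L - 6L)
  kmers <- substring(s, pos, pos + 6L)
  hd <- .hamming7(kmers)
  wrk <- substr(kmers, 1, 3) == "WRK"
  wr <- substr(kmers, 1, 2) == "WR"
  keep <- (wrk & hd <= max_mismatch) | (wr & hd <= 2L & kmers == "WRKSGQR")
  if (!any(keep)) return(empty)
  motif <- kmers[keep]
  vc <- ifelse(motif == CANONICAL_HEPTAPEPTIDE, "canonical",
               ifelse(motif %in% NAMED_VARIANTS, motif, "other"))
  data.frame(position = pos[keep], motif = motif, variant_class = vc,
             hamming = hd[keep], stringsAsFactors = FALSE)
}

#' Find zinc-finger motifs
#'
#' Scans left to right for the generalized layout
#' `C-X(3..7)-C-X(22..23)-H-X(1)-[H|C]`, the union of the spacer dialects
#' seen across WRKY groups.  The finger type is set by the terminal
#' coordinating residue (`H` for C2H2, `C` for C2HC).  Overlapping
#' candidates are resolved leftmost-first (smallest spacers first at equal
#' start), then scanning resumes after the accepted match.
#'
#' @param protein a single protein string.
#' @param search_start 1-based position at which scanning starts.
#' @return data.frame with columns `position` (first Cys), `end`,
#'   `pattern_string`, `finger_type`, `spacer1`, `spacer2`.
#' @export
find_zinc_fingers <- function(protein, search_start = 1L) {
  s <- as.character(protein)[[1]]
  L <- nchar(s)
  if (search_start < 1L || search_start > L) {
    stop("search_start outside the sequence")
  }
  cc <- strsplit(s, "")[[1]]
  hits <- list()
  p <- search_start
  cpos <- which(cc == "C")
  cpos <- cpos[cpos >= search_start]
  k <- 1L
  while (k <= length(cpos)) {
    p <- cpos[k]
    found <- NULL
    for (s1 in 3:7) {
      c2 <- p + s1 + 1L
      if (c2 > L || cc[c2] != "C") next
      for (s2 in 22:23) {
        h1 <- c2 + s2 + 1L
        term <- h1 + 2L
        if (term > L || cc[h1] != "H") next
        if (!cc[term] %in% c("H", "C")) next
        found <- data.frame(
          position = p, end = term,
          pattern_string = substr(s, p, term),
          finger_type = if (cc[term] == "H") "C2H2" else "C2HC",
          spacer1 = s1, spacer2 = s2, stringsAsFactors = FALSE)
        break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      k <- k + 1L
    } else {
      hits[[length(hits) + 1L]] <- found
      k <- match(TRUE, cpos > found$end)  # resume after the match
      if (is.na(k)) break
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(0), end = integer(0),
                      pattern_string = character(0),
                      finger_type = character(0), spacer1 = integer(0),
                      spacer2 = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Scan a protein for complete WRKY domains
#'
#' A domain is a heptapeptide hit paired with the nearest downstream zinc
#' finger whose first Cys lies within `linker_max` residues of the
#' heptapeptide's end.  Each finger is used at most once; unpaired
#' heptapeptides or fingers are not domains.
#'
#' @param protein a single protein string.
#' @param max_mismatch passed to [find_heptapeptides()].
#' @param linker_max maximum number of residues between the heptapeptide
#'   end and the first Cys of the finger.
#' @return data.frame with one row per domain: heptapeptide columns
#'   (`position`, `motif`, `variant_class`), finger columns
#'   (`finger_position`, `finger_type`) and the domain `span_start`,
#'   `span_end`.
#' @export
scan_domains <- function(protein, max_mismatch = 2L, linker_max = 50L) {
  hp <- find_heptapeptides(protein, max_mismatch)
  zf <- find_zinc_fingers(protein, 1L)
  out <- list()
  used <- rep(FALSE, nrow(zf))
  if (nrow(hp)) {
    for (i in seq_len(nrow(hp))) {
      hend <- hp$position[i] + 6L
      cand <- which(!used & zf$position > hp$position[i] &
                      (zf$position - hend - 1L) <= linker_max &
                      zf$position > hend)
      if (!length(cand)) next
      j <- cand[which.min(zf$position[cand])]
      used[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        position = hp$position[i], motif = hp$motif[i],
        variant_class = hp$variant_class[i],
        finger_position = zf$position[j], finger_type = zf$finger_type[j],
        span_start = hp$position[i], span_end = zf$end[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), motif = character(0),
                      variant_class = character(0),
                      finger_position = integer(0),
                      finger_type = character(0), span_start = integer(0),
                      span_end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Find the HARF motif of WRKY subgroup IId
#'
#' Matches `RTGHARFRR[A/G]P`.
#'
#' @param protein a single protein string.
#' @return integer vector of 1-based start positions (possibly empty).
#' @export
find_harf <- function(protein) {
  s <- as.character(protein)[[1]]
  m <- gregexpr("RTGHARFRR[AG]P", s)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Sequences are visited longest-first; a sequence joins the first existing
#' cluster whose representative it matches at or above
#' `identity_threshold` global-alignment identity
#' ([alignment_identity()]), otherwise it founds a new cluster.  Cluster
#' representatives are returned in input order.
#'
#' @param set a [seq_set()].
#' @param identity_threshold fraction in `(0.5, 1]`.
#' @return the deduplicated [seq_set()]; cluster membership is attached as
#'   attribute `"clusters"` (named vector: id -> representative id).
#' @export
dedup_sequences <- function(set, identity_threshold = 0.95) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  ids <- names(set)
  ord <- order(-nchar(set), seq_along(set))  # longest first, stable
  reps <- character(0)
  member <- setNames(character(length(set)), ids)
  submat <- substitution_matrix("BLOSUM62")
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      idy <- alignment_identity(set[[i]], set[[r]], submat)
      if (idy >= identity_threshold) {
        member[ids[i]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      member[ids[i]] <- ids[i]
    }
  }
  keep <- ids[ids %in% reps]
  out <- set[keep]
  attr(out, "clusters") <- member
  out
}

#' Per-protein WRKY feature report
#'
#' Convenience wrapper running domain scanning and physicochemical
#' prediction over a whole sequence set.
#'
#' @param set a [seq_set()] of proteins.
#' @param max_mismatch,linker_max see [scan_domains()].
#' @return data.frame with one row per protein: `id`, `length_aa`,
#'   `n_domains`, `heptapeptide` (of the first domain, `NA` if none),
#'   `zinc_finger` (`"C2H2"`, `"C2HC"` or `"mixed"`), `pi`, `mw_kda`,
#'   `harf` (logical).
#' @export
protein_features <- function(set, max_mismatch = 2L, linker_max = 50L) {
  rows <- lapply(names(set), function(id) {
    s <- set[[id]]
    dom <- scan_domains(s, max_mismatch, linker_max)
    zf <- if (nrow(dom) == 0L) NA_character_
      else if (length(unique(dom$finger_type)) > 1L) "mixed"
      else dom$finger_type[1]
    data.frame(id = id, length_aa = nchar(s), n_domains = nrow(dom),
               heptapeptide = if (nrow(dom)) dom$motif[nrow(dom)]
                              else NA_character_,
               zinc_finger = zf,
               pi = round(isoelectric_point(s), 2),
               mw_kda = round(molecular_weight(s), 2),
               harf = length(find_harf(s)) > 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
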