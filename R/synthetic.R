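# Seeded synthetic WRKY family generator with full ground truth.
#
# The generator emulates the statistical structure a family census assumes:
# subgroup-specific ancestors with the correct domain architecture, genes
# mutated at a configurable divergence with pattern-critical residues held
# fixed, heptapeptide variants at the observed family rates, 0-7 GT..AG
# introns, tandem duplicate pairs inside 100-kbp windows, promoters with
# planted IUPAC elements, and Ct tables realizing known fold changes.

SUBGROUPS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")

# filler alphabet excludes C and W so fillers can never seed a spurious
# heptapeptide or zinc-finger start
FILLER_AA <- setdiff(names(AA_AVG_MASS), c("C", "W"))
SPACER_AA <- setdiff(names(AA_AVG_MASS), c("C", "W", "H"))

STANDARD_CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG",
  "AGA", "AGG"), N = c("AAT", "AAC"), D = c("GAT", "GAC"),
  C = c("TGT", "TGC"), E = c("GAA", "GAG"), Q = c("CAA", "CAG"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), L = c("TTA", "TTG", "CTT", "CTC", "CTA",
  "CTG"), K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"), S = c("TCT", "TCC", "TCA", "TCG",
  "AGT", "AGC"), T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG",
  Y = c("TAT", "TAC"), V = c("GTT", "GTC", "GTA", "GTG"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic family generator
#'
#' Defaults mirror the family structure reported for the sorghum WRKY
#' census: group counts 11 (I), 4/8/20/6/12 (IIa-IIe) and 31 (III) out of
#' 92 grouped genes; heptapeptide variants in 13/94 of proteins split
#' 6:5:1:1 over WRKYGEK/WRKYGKK/WRKYGSK/WRKSGQR; intron counts 0-7 with
#' the observed 4/10/58/8/8/5/0/1 histogram; two tandem pairs inside
#' 100-kbp windows; 1,500-bp promoters.
#'
#' @param n_genes family size.
#' @param group_freq named frequency vector over the seven subgroups.
#' @param variant_rate probability a gene's heptapeptide is a variant.
#' @param variant_freq named frequencies over the named variants.
#' @param intron_freq frequencies for 0..7 introns.
#' @param n_tandem_pairs number of planted tandem duplicate pairs.
#' @param tandem_divergence substitutions/site within a tandem pair.
#' @param divergence substitutions/site from the subgroup ancestor, in
#'   `[0, 0.5]`.
#' @param refs_per_subgroup labelled reference sequences generated per
#'   subgroup.
#' @param promoter_length promoter length in bp.
#' @param planted_elements named integer vector: element name -> copies
#'   planted per promoter.
#' @param n_expression_genes genes carried into the synthetic Ct table.
#' @param ct_noise_sd replicate-level Ct noise (0 = noise-free).
#' @param seed mandatory integer seed.
#' @return a `family_config` list.
#' @export
family_config <- function(n_genes = 94L,
                          group_freq = c(I = 11, IIa = 4, IIb = 8,
                                         IIc = 20, IId = 6, IIe = 12,
                                         III = 31) / 92,
                          variant_rate = 13 / 94,
                          variant_freq = c(WRKYGEK = 6, WRKYGKK = 5,
                                           WRKYGSK = 1, WRKSGQR = 1) / 13,
                          intron_freq = c(4, 10, 58, 8, 8, 5, 0, 1) / 94,
                          n_tandem_pairs = 2L,
                          tandem_divergence = 0.10,
                          divergence = 0.15,
                          refs_per_subgroup = 3L,
                          promoter_length = 1500L,
                          planted_elements = c("W-box" = 1L, ABRE = 1L,
                                               MBS = 1L),
                          n_expression_genes = 5L,
                          ct_noise_sd = 0,
                          seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(abs(sum(group_freq) - 1) < 1e-8,
            divergence >= 0, divergence <= 0.5,
            all(names(group_freq) == SUBGROUPS))
  if (n_tandem_pairs > n_genes / 2) {
    stop("more tandem pairs than gene pairs available")
  }
  structure(list(n_genes = as.integer(n_genes), group_freq = group_freq,
                 variant_rate = variant_rate, variant_freq = variant_freq,
                 intron_freq = intron_freq,
                 n_tandem_pairs = as.integer(n_tandem_pairs),
                 tandem_divergence = tandem_divergence,
                 divergence = divergence,
                 refs_per_subgroup = as.integer(refs_per_subgroup),
                 promoter_length = as.integer(promoter_length),
                 planted_elements = planted_elements,
                 n_expression_genes = as.integer(n_expression_genes),
                 ct_noise_sd = ct_noise_sd, seed = as.integer(seed)),
            class = "family_config")
}

.rand_aa <- function(n, alphabet = FILLER_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# one WRKY domain string and the residue offsets that must stay fixed
.make_domain <- function(finger_type, s1, s2) {
  linker <- .rand_aa(10L, SPACER_AA)
  finger <- paste0("C", .rand_aa(s1, SPACER_AA), "C",
                   .rand_aa(s2, SPACER_AA), "H", .rand_aa(1L, SPACER_AA),
                   if (finger_type == "C2H2") "H" else "C")
  dom <- paste0(CANONICAL_HEPTAPEPTIDE, linker, finger)
  hept_at <- 1L
  fing_at <- 7L + 10L + 1L
  critical <- c(hept_at:(hept_at + 6L),            # heptapeptide
                fing_at, fing_at + s1 + 1L,        # the two Cys
                fing_at + s1 + 1L + s2 + 1L,       # the His
                fing_at + s1 + 1L + s2 + 3L)       # terminal H/C
  list(seq = dom, critical = critical, hept_at = hept_at)
}

# subgroup ancestor: M + filler + domain(s) + filler, with critical
# positions and heptapeptide start(s) tracked
.make_ancestor <- function(subgroup) {
  arch <- switch(subgroup,
                 I = list(n_dom = 2L, type = "C2H2", s1 = 4L, s2 = 22L),
                 III = list(n_dom = 1L, type = "C2HC", s1 = 7L, s2 = 23L),
                 list(n_dom = 1L, type = "C2H2", s1 = 4L, s2 = 23L))
  lead <- paste0("M", .rand_aa(59L + sample.int(40L, 1L)))
  seq <- lead
  critical <- integer(0)
  hept_at <- integer(0)
  for (d in seq_len(arch$n_dom)) {
    dom <- .make_domain(arch$type, arch$s1, arch$s2)
    off <- nchar(seq)
    critical <- c(critical, dom$critical + off)
    hept_at <- c(hept_at, dom$hept_at + off)
    seq <- paste0(seq, dom$seq)
    if (d < arch$n_dom) seq <- paste0(seq, .rand_aa(40L))
  }
  seq <- paste0(seq, .rand_aa(30L + sample.int(30L, 1L)))
  list(seq = seq, critical = c(critical, 1L), hept_at = hept_at,
       finger_type = arch$type, n_dom = arch$n_dom)
}

# point-mutate non-critical sites at the given per-site rate
.mutate <- function(seq, critical, rate) {
  if (rate <= 0) return(seq)
  cc <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(cc), critical)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) {
    cc[i] <- sample(setdiff(FILLER_AA, cc[i]), 1L)
  }
  paste(cc, collapse = "")
}

.reverse_translate <- function(protein) {
  cc <- strsplit(protein, "")[[1]]
  codons <- vapply(cc, function(a) {
    opts <- STANDARD_CODONS[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

# insert k GT..AG introns into a CDS; returns genomic string + exon matrix
.splice <- function(cds, k) {
  n <- nchar(cds)
  if (k == 0L) {
    return(list(genomic = cds,
                exons = matrix(c(1L, n), 1L,
                               dimnames = list(NULL, c("start", "end")))))
  }
  # cut points keep every exon >= 20 bp: ultra-short exons are rare in
  # plant genes and make the splicing inverse ill-posed
  min_exon <- 20L
  if (n < (k + 1L) * min_exon) stop("CDS too short for ", k, " introns")
  for (try in 1:200) {
    cuts <- sort(sample(seq(min_exon + 1L, n - min_exon + 1L), k))
    if (k == 1L || min(diff(cuts)) >= min_exon) break
    if (try == 200L) {
      cuts <- round(seq_len(k) * n / (k + 1L)) + 1L  # even fallback
    }
  }
  introns <- vapply(seq_len(k), function(i) {
    paste0("GT", .rand_dna(46L + sample.int(100L, 1L)), "AG")
  }, character(1))
  pieces <- character(0)
  exons <- matrix(0L, k + 1L, 2L, dimnames = list(NULL, c("start", "end")))
  prev <- 1L; gpos <- 0L
  for (i in seq_len(k)) {
    ex <- substr(cds, prev, cuts[i] - 1L)
    exons[i, ] <- c(gpos + 1L, gpos + nchar(ex))
    gpos <- gpos + nchar(ex) + nchar(introns[i])
    pieces <- c(pieces, ex, introns[i])
    prev <- cuts[i]
  }
  ex <- substr(cds, prev, n)
  exons[k + 1L, ] <- c(gpos + 1L, gpos + nchar(ex))
  pieces <- c(pieces, ex)
  list(genomic = paste(pieces, collapse = ""), exons = exons)
}

.plant_elements <- function(promoter, planted, library) {
  cc <- strsplit(promoter, "")[[1]]
  used <- rep(FALSE, length(cc))
  placed <- list()
  for (nm in names(planted)) {
    pat <- library$iupac[library$name == nm]
    if (!length(pat)) stop("planted element '", nm, "' not in library")
    w <- nchar(pat)
    concrete <- paste(vapply(strsplit(pat, "")[[1]], function(ch) {
      opts <- strsplit(IUPAC_CODES[[ch]], "")[[1]]
      opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
    for (rep_i in seq_len(planted[[nm]])) {
      ok <- FALSE
      for (try in 1:200) {
        pos <- sample.int(length(cc) - w + 1L, 1L)
        if (!any(used[pos:(pos + w - 1L)])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place element '", nm, "'")
      cc[pos:(pos + w - 1L)] <- strsplit(concrete, "")[[1]]
      used[pos:(pos + w - 1L)] <- TRUE
      placed[[length(placed) + 1L]] <- data.frame(
        element = nm, position = pos, match = concrete,
        stringsAsFactors = FALSE)
    }
  }
  list(promoter = paste(cc, collapse = ""),
       placed = do.call(rbind, placed))
}

#' Generate a ground-truthed synthetic WRKY family
#'
#' Builds subgroup ancestors with the correct domain architecture (two
#' C2H2 domains for group I, one C2H2 for IIa-IIe, one C2HC for III),
#' mutates each gene at the configured divergence while holding
#' pattern-critical residues fixed, reverse-translates to CDS, inserts
#' GT..AG introns, places genes on synthetic chromosomes with tandem
#' pairs inside 100-kbp windows, plants promoter elements, and emits Ct
#' tables realizing known folds.  Same seed, same output.
#'
#' @param config a [family_config()].
#' @return list with `proteins`, `cds`, `genomic` ([seq_set()]s), `loci`
#'   ([gene_loci()]), `promoters` (named character), `ct` (long
#'   data.frame), `references` (seq_set), `panel` (named labels), and
#'   `truth` (per-gene group, heptapeptide, exons, tandem pairs, planted
#'   elements, folds).
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ancestors <- setNames(lapply(SUBGROUPS, .make_ancestor), SUBGROUPS)

  # subgroup assignment: deterministic rounded counts, remainder by freq
  counts <- floor(config$group_freq * n)
  while (sum(counts) < n) {
    frac <- config$group_freq * n - counts
    counts[which.max(frac)] <- counts[which.max(frac)] + 1
  }
  subgroup <- rep(SUBGROUPS, times = counts)[seq_len(n)]

  ids <- sprintf("SYNW%03d", seq_len(n))
  tandem_partner <- rep(NA_integer_, n)
  if (config$n_tandem_pairs > 0L) {
    for (t in seq_len(config$n_tandem_pairs)) {
      a <- 2L * t - 1L; b <- 2L * t
      subgroup[b] <- subgroup[a]
      tandem_partner[b] <- a
    }
  }

  proteins <- character(n)
  hept_true <- character(n)
  for (i in seq_len(n)) {
    anc <- ancestors[[subgroup[i]]]
    base <- if (!is.na(tandem_partner[i])) proteins[tandem_partner[i]]
            else anc$seq
    rate <- if (!is.na(tandem_partner[i])) config$tandem_divergence
            else config$divergence
    s <- .mutate(base, anc$critical, rate)
    hept <- if (!is.na(tandem_partner[i])) hept_true[tandem_partner[i]]
      else if (stats::runif(1) < config$variant_rate) {
        sample(names(config$variant_freq), 1L, prob = config$variant_freq)
      } else CANONICAL_HEPTAPEPTIDE
    # the variant replaces the signature of the (C-terminal) domain
    hpos <- anc$hept_at[length(anc$hept_at)]
    substr(s, hpos, hpos + 6L) <- hept
    proteins[i] <- s
    hept_true[i] <- hept
  }

  cds <- vapply(proteins, .reverse_translate, character(1))
  intron_n <- sample(0:7, n, replace = TRUE, prob = config$intron_freq)
  spliced <- lapply(seq_len(n), function(i) .splice(cds[i], intron_n[i]))
  genomic <- vapply(spliced, `[[`, character(1), "genomic")

  # chromosome placement: ~12 genes per synthetic chromosome; tandem
  # partners are kept adjacent inside the 100-kbp window, all other
  # neighbours are spaced beyond it
  n_chr <- max(1L, ceiling(n / 12L))
  chrom <- sprintf("Chr%02d", rep(seq_len(n_chr), each = 12L)[seq_len(n)])
  start <- numeric(n); end <- numeric(n)
  pos <- setNames(rep(5e5, n_chr), sprintf("Chr%02d", seq_len(n_chr)))
  for (i in seq_len(n)) {
    glen <- nchar(genomic[i])
    if (!is.na(tandem_partner[i])) {
      chrom[i] <- chrom[tandem_partner[i]]
      start[i] <- end[tandem_partner[i]] + 5000 + sample.int(40000L, 1L)
    } else {
      start[i] <- pos[chrom[i]]
    }
    end[i] <- start[i] + glen - 1
    pos[chrom[i]] <- end[i] + 150000 + sample.int(250000L, 1L)
  }
  loci <- gene_loci(ids, chrom, start, end)

  # labelled references per subgroup at the same divergence
  ref_ids <- character(0); ref_seqs <- character(0); panel <- character(0)
  for (sg in SUBGROUPS) {
    anc <- ancestors[[sg]]
    for (r in seq_len(config$refs_per_subgroup)) {
      rid <- sprintf("REF_%s_%d", sg, r)
      ref_ids <- c(ref_ids, rid)
      ref_seqs <- c(ref_seqs, .mutate(anc$seq, anc$critical,
                                      config$divergence))
      panel[rid] <- sg
    }
  }

  library <- cis_element_library()
  promoters <- character(n)
  planted <- list()
  for (i in seq_len(n)) {
    pr <- .plant_elements(.rand_dna(config$promoter_length),
                          config$planted_elements, library)
    promoters[i] <- pr$promoter
    if (!is.null(pr$placed)) {
      pr$placed$gene <- ids[i]
      planted[[length(planted) + 1L]] <- pr$placed
    }
  }
  names(promoters) <- ids

  # Ct table realizing known folds (reference gene flat at Ct 20)
  conditions <- c("0h", "3h", "6h", "12h", "24h")
  eg <- ids[seq_len(min(config$n_expression_genes, n))]
  folds <- matrix(1, length(eg), length(conditions),
                  dimnames = list(eg, conditions))
  folds[, -1] <- 2^stats::runif(length(eg) * (length(conditions) - 1L),
                                -3, 3)
  ct_rows <- list()
  for (g in eg) {
    cal_ct <- stats::runif(1, 23, 27)
    for (cond in conditions) {
      for (r in 1:3) {
        noise <- if (config$ct_noise_sd > 0) {
          stats::rnorm(1, 0, config$ct_noise_sd)
        } else 0
        ct_rows[[length(ct_rows) + 1L]] <- data.frame(
          gene = g, condition = cond, replicate = r,
          ct = cal_ct - log2(folds[g, cond]) + noise,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (cond in conditions) {
    for (r in 1:3) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        gene = "GAPDH", condition = cond, replicate = r, ct = 20,
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, ct_rows)

  if (config$n_tandem_pairs > 0L) {
    bs <- which(!is.na(tandem_partner))
    tandem_truth <- data.frame(gene_a = ids[tandem_partner[bs]],
                               gene_b = ids[bs], stringsAsFactors = FALSE)
  } else {
    tandem_truth <- data.frame(gene_a = character(0),
                               gene_b = character(0),
                               stringsAsFactors = FALSE)
  }

  list(
    proteins = seq_set(setNames(proteins, ids), alphabet = "AA"),
    cds = seq_set(setNames(cds, ids), alphabet = "DNA"),
    genomic = seq_set(setNames(genomic, ids), alphabet = "DNA"),
    loci = loci,
    promoters = promoters,
    ct = ct,
    references = seq_set(setNames(ref_seqs, ref_ids), alphabet = "AA"),
    panel = panel,
    truth = list(
      group = setNames(subgroup, ids),
      heptapeptide = setNames(hept_true, ids),
      n_domains = setNames(vapply(SUBGROUPS[match(subgroup, SUBGROUPS)],
                                  function(sg) ancestors[[sg]]$n_dom,
                                  integer(1)), ids),
      finger_type = setNames(vapply(SUBGROUPS[match(subgroup, SUBGROUPS)],
                                    function(sg) ancestors[[sg]]$finger_type,
                                    character(1)), ids),
      exons = setNames(lapply(spliced, `[[`, "exons"), ids),
      n_introns = setNames(intron_n, ids),
      tandem_pairs = tandem_truth,
      planted_elements = if (length(planted)) do.call(rbind, planted)
        else NULL,
      folds = folds),
    config = config)
}

#' Corrupt genes of a synthetic family (negative controls)
#'
#' Supported operations: `"break-heptapeptide"` (the signature W becomes
#' A), `"delete-zinc-finger"` (the finger region is excised), and
#' `"shuffle-sequence"` (residues permuted).  Targeted genes no longer
#' satisfy the family inclusion criterion; the ground truth marks them
#' excluded.
#'
#' @param family output of [generate_family()].
#' @param ops named character vector: gene id -> operation.
#' @param seed seed for the shuffle op (default derived from the family
#'   seed).
#' @return the modified family.
#' @export
corrupt <- function(family, ops, seed = family$config$seed + 10000L) {
  if (!length(ops)) return(family)
  set.seed(seed)
  for (gid in names(ops)) {
    if (!gid %in% names(family$proteins)) stop("unknown gene: ", gid)
    s <- family$proteins[[gid]]
    op <- ops[[gid]]
    if (op == "break-heptapeptide") {
      hp <- find_heptapeptides(s)
      if (nrow(hp)) {
        for (p in hp$position) substr(s, p, p) <- "A"
      }
    } else if (op == "delete-zinc-finger") {
      zf <- find_zinc_fingers(s)
      while (nrow(zf)) {
        s <- paste0(substr(s, 1, zf$position[1] - 1L),
                    substr(s, zf$end[1] + 1L, nchar(s)))
        zf <- find_zinc_fingers(s)
      }
    } else if (op == "shuffle-sequence") {
      cc <- strsplit(s, "")[[1]]
      s <- paste(sample(cc), collapse = "")
    } else {
      stop("unknown corruption op: ", op)
    }
    sq <- unclass(family$proteins)
    sq[[gid]] <- s
    family$proteins <- seq_set(sq, alphabet = "AA")
    family$truth$group[gid] <- NA_character_
  }
  family
}

#' Write a synthetic family to disk
#'
#' Emits protein/CDS/genomic FASTA, true structures as GFF3, loci and
#' truth tables as TSV, promoters as FASTA and the Ct table as TSV.
#' Deterministic: identical families yield byte-identical files.
#'
#' @param family output of [generate_family()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$proteins, file.path(dir, "proteins.faa"))
  write_fasta(family$cds, file.path(dir, "cds.fna"))
  write_fasta(family$genomic, file.path(dir, "genomic.fna"))
  write_fasta(family$promoters, file.path(dir, "promoters.fna"))
  write_fasta(family$references, file.path(dir, "references.faa"))
  write.table(data.frame(id = names(family$panel),
                         subgroup = unname(family$panel)),
              file.path(dir, "panel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(family$loci), file.path(dir, "loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(family$ct, file.path(dir, "ct.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  structures <- lapply(names(family$truth$exons), function(gid) {
    list(gene_id = gid, exons = family$truth$exons[[gid]])
  })
  write_structures_gff3(structures, file.path(dir, "structures.gff3"))
  truth <- data.frame(gene = names(family$truth$group),
                      group = unname(family$truth$group),
                      heptapeptide = unname(family$truth$heptapeptide),
                      n_introns = unname(family$truth$n_introns),
                      stringsAsFactors = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
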