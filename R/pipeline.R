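# End-to-end census orchestration and summary statistics.

#' Run the full family census
#'
#' Executes, in order: redundancy removal, domain scanning (proteins
#' without a complete WRKY domain are excluded and logged), physicochemical
#' prediction, multiple alignment of family plus reference proteins,
#' neighbor-joining (with optional bootstrap), classification
#' (feature + tree + reconciliation), positional naming, exon-intron
#' structure, tandem/cluster detection, promoter scanning and qPCR
#' quantification.  Stages whose inputs are absent are skipped.
#'
#' @param proteins a [seq_set()] of candidate proteins (required).
#' @param references labelled reference proteins ([seq_set()]); required
#'   for subgroup classification.
#' @param panel named character vector: reference id -> subgroup label.
#' @param loci optional [gene_loci()] (enables naming, tandems, clusters).
#' @param cds,genomic optional [seq_set()]s keyed like `proteins`
#'   (enables structure inference).
#' @param promoters optional named character vector of promoter strings.
#' @param ct optional long-format Ct table (see [delta_delta_ct()]).
#' @param reference_gene,calibrator qPCR normalizer and baseline.
#' @param dedup_threshold identity threshold for redundancy removal
#'   (`NULL` disables the stage).
#' @param max_mismatch,linker_max domain-scan parameters.
#' @param n_bootstrap bootstrap replicates (0 skips supports).
#' @param k_neighbours neighbours for tree placement.
#' @param tandem_window_bp,tandem_min_similarity tandem criterion.
#' @param prefix gene-name prefix used with `loci`.
#' @param fold_threshold expression filter threshold.
#' @param seed seed for the bootstrap stage.
#' @param out_dir if given, census/tree/report files are written there.
#' @return list with `census` (data.frame), `tree` ([ape::phylo] or NULL),
#'   `names` (id -> positional name), `structures`, `tandem`, `clusters`,
#'   `cis`, `expression`, `excluded` (ids failing the domain criterion)
#'   and `log` (character).
#' @export
run_census <- function(proteins, references = NULL, panel = NULL,
                       loci = NULL, cds = NULL, genomic = NULL,
                       promoters = NULL, ct = NULL,
                       reference_gene = "GAPDH", calibrator = "0h",
                       dedup_threshold = 0.95, max_mismatch = 2L,
                       linker_max = 50L, n_bootstrap = 0L,
                       k_neighbours = 3L, tandem_window_bp = 1e5,
                       tandem_min_similarity = 70, prefix = "WRKY",
                       fold_threshold = 2.5, seed = 1L,
                       out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(dedup_threshold)) {
    n0 <- length(proteins)
    proteins <- dedup_sequences(proteins, dedup_threshold)
    if (length(proteins) < n0) {
      note("dedup: removed %d redundant sequence(s)", n0 - length(proteins))
    }
  }

  domains <- lapply(names(proteins),
                    function(id) scan_domains(proteins[[id]], max_mismatch,
                                              linker_max))
  names(domains) <- names(proteins)
  has_domain <- vapply(domains, nrow, integer(1)) > 0L
  excluded <- names(proteins)[!has_domain]
  for (id in excluded) note("excluded (no complete WRKY domain): %s", id)
  proteins <- proteins[names(proteins)[has_domain]]
  domains <- domains[names(proteins)]
  if (!length(proteins)) stop("no protein passes the domain criterion")

  feats <- protein_features(proteins, max_mismatch, linker_max)

  tree <- NULL
  tree_calls <- list()
  if (!is.null(references) && !is.null(panel)) {
    all_seqs <- seq_set(c(unclass(proteins)[names(proteins)],
                          unclass(references)[names(references)]),
                        alphabet = "AA")
    aln <- progressive_msa(all_seqs)
    if (n_bootstrap > 0L) {
      tree <- bootstrap_supports(aln, n_bootstrap, seed = seed)
    } else {
      tree <- neighbor_joining(p_distance_matrix(aln))
    }
    for (id in names(proteins)) {
      tree_calls[[id]] <- tree_subgroup(tree, panel, id, k_neighbours)
    }
  }

  group <- character(length(proteins))
  trace <- character(length(proteins))
  for (i in seq_along(proteins)) {
    id <- names(proteins)[i]
    fg <- feature_group(domains[[id]])
    if (length(tree_calls)) {
      rec <- reconcile(fg, tree_calls[[id]], feats$zinc_finger[i])
      group[i] <- rec$label
      trace[i] <- rec$trace
    } else {
      group[i] <- fg$group
      trace[i] <- "feature-only"
    }
  }

  nm <- setNames(names(proteins), names(proteins))
  chrom <- rep(NA_character_, length(proteins))
  start <- rep(NA_real_, length(proteins))
  end <- rep(NA_real_, length(proteins))
  tandem <- NULL; clusters <- NULL
  if (!is.null(loci)) {
    loci <- loci[loci$gene_id %in% names(proteins), , drop = FALSE]
    nm <- assign_names(loci, prefix)
    idx <- match(names(proteins), loci$gene_id)
    chrom <- loci$chromosome[idx]
    start <- loci$start[idx]
    end <- loci$end[idx]
    tandem <- detect_tandem(loci, proteins, tandem_window_bp,
                            tandem_min_similarity)
    clusters <- find_clusters(loci, tandem_window_bp)
  }

  structures <- NULL
  n_introns <- rep(NA_integer_, length(proteins))
  if (!is.null(cds) && !is.null(genomic)) {
    both <- intersect(names(proteins),
                      intersect(names(cds), names(genomic)))
    structures <- lapply(both, function(id) {
      infer_structure(genomic[[id]], cds[[id]], gene_id = id)
    })
    names(structures) <- both
    n_introns[match(both, names(proteins))] <-
      vapply(structures, `[[`, integer(1), "n_introns")
  }

  cis <- NULL
  if (!is.null(promoters)) {
    lib <- cis_element_library()
    hits <- do.call(rbind, lapply(names(promoters), function(id) {
      scan_elements(promoters[[id]], lib, gene_id = id)
    }))
    cis <- list(hits = hits,
                summary = element_summary(hits, names(promoters),
                                          lib$name))
  }

  expression <- NULL
  if (!is.null(ct)) {
    fc <- delta_delta_ct(ct, reference_gene, calibrator)
    expression <- list(fold = fc$fold, se = fc$se,
                       responsive = fold_filter(fc$fold, fold_threshold))
    if (nrow(fc$fold) >= 2L) {
      expression$clustering <- hierarchical_cluster(fc$fold)
    }
  }

  census <- data.frame(
    gene = unname(nm[names(proteins)]),
    chromosome = chrom, start = start, end = end,
    pi = feats$pi, mw_kda = feats$mw_kda,
    heptapeptide = feats$heptapeptide, zinc_finger = feats$zinc_finger,
    domains = feats$n_domains, group = group,
    length_aa = feats$length_aa, id = names(proteins),
    n_introns = n_introns, trace = trace, stringsAsFactors = FALSE)
  if (!is.null(loci)) {
    census <- census[order(chromosome_rank(census$chromosome),
                           census$start), , drop = FALSE]
    rownames(census) <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ctab <- census
    ctab$chromosome[is.na(ctab$chromosome)] <- "."
    ctab$start[is.na(ctab$start)] <- 0
    ctab$end[is.na(ctab$end)] <- 0
    write_census(ctab, file.path(out_dir, "census.tsv"))
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(tandem)) {
      write.table(tandem, file.path(out_dir, "tandem.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(structures)) {
      write_structures_gff3(structures, file.path(out_dir,
                                                  "structures.gff3"))
    }
    writeLines(log, file.path(out_dir, "census.log"))
  }

  list(census = census, tree = tree, names = nm, structures = structures,
       tandem = tandem, clusters = clusters, cis = cis,
       expression = expression, excluded = excluded, log = log)
}

#' Summary statistics of a census table
#'
#' Group and subgroup sizes, heptapeptide tallies, per-chromosome counts,
#' the intron-count histogram (when available) and protein length / pI /
#' MW ranges -- the usual in-text statistics of a family census.
#'
#' @param census census data.frame (columns as in [validate_census()];
#'   an `n_introns` column is used when present).
#' @return list of summary components.
#' @export
summarize_census <- function(census) {
  if (!nrow(census)) {
    warning("empty census")
    return(list(n = 0L))
  }
  top <- ifelse(census$group %in% c("IIa", "IIb", "IIc", "IId", "IIe"),
                "II", census$group)
  group_sizes <- table(factor(top, levels = c("I", "II", "III", "NG")))
  subgroup_sizes <- table(factor(census$group, levels = GROUP_LEVELS))
  hept <- sort(table(census$heptapeptide), decreasing = TRUE)
  per_chrom <- if (!all(is.na(census$chromosome))) {
    tab <- table(census$chromosome)
    tab[order(chromosome_rank(names(tab)))]
  } else NULL
  introns <- if ("n_introns" %in% names(census) &&
                 !all(is.na(census$n_introns))) {
    table(factor(census$n_introns, levels = 0:7))
  } else NULL
  list(n = nrow(census),
       group_sizes = group_sizes,
       group_percent = round(100 * prop.table(group_sizes), 1),
       subgroup_sizes = subgroup_sizes,
       heptapeptides = hept,
       per_chromosome = per_chrom,
       intron_histogram = introns,
       length_aa = c(min = min(census$length_aa),
                     mean = mean(census$length_aa),
                     max = max(census$length_aa)),
       pi = range(census$pi),
       mw_kda = range(census$mw_kda),
       n_domains = table(census$domains))
}

#' Load the packaged sorghum WRKY family summary table
#'
#' The per-gene census of the sorghum WRKY family (gene names, loci, pI,
#' MW, heptapeptide, zinc-finger type, domain count, group, protein
#' length) as published for the 94-member family; useful as a reference
#' input for naming, clustering and summary statistics.
#'
#' @return data.frame with one row per gene.
#' @export
sorghum_wrky_table <- function() {
  path <- system.file("extdata", "sbwrky_table1.tsv",
                      package = "wrkycensus")
  read.delim(path, stringsAsFactors = FALSE)
}
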