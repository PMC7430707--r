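# Relative expression from qPCR Ct tables: 2^-ddCt with reference-gene
# normalization, fold-change filtering, and hierarchical clustering of
# expression matrices.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the
#' mean calibrator `dCt` of the gene; the fold change is `2^-ddCt`
#' (100% amplification efficiency assumed).  Per-replicate folds are
#' averaged (the `"mean_of_folds"` aggregation; `"fold_of_means"`
#' exponentiates the mean ddCt instead), with a standard error across
#' replicates.
#'
#' @param ct long-format data.frame with columns `gene`, `condition`,
#'   `replicate`, `ct`.
#' @param reference_gene id of the normalizer (e.g. GAPDH); must be
#'   measured in every condition/replicate.
#' @param calibrator condition used as the unit baseline (e.g. `"0h"`).
#' @param aggregate `"mean_of_folds"` or `"fold_of_means"`.
#' @return list with `fold` (genes x conditions matrix, calibrator column
#'   1 under `"fold_of_means"`, mean 1 under `"mean_of_folds"`) and `se`
#'   (matching matrix of standard errors; 0 where a single replicate).
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator,
                           aggregate = c("mean_of_folds", "fold_of_means")) {
  aggregate <- match.arg(aggregate)
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!reference_gene %in% ct$gene) {
    stop("reference gene '", reference_gene, "' absent from the table")
  }
  if (!calibrator %in% ct$condition) {
    stop("calibrator condition '", calibrator, "' absent from the table")
  }
  conditions <- unique(ct$condition)
  genes <- setdiff(unique(ct$gene), reference_gene)
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  ref_key <- paste(ref$condition, ref$replicate)
  for (cond in conditions) {
    if (!cond %in% ref$condition) {
      stop("reference gene '", reference_gene,
           "' not measured in condition '", cond, "'")
    }
  }
  fold <- matrix(NA_real_, length(genes), length(conditions),
                 dimnames = list(genes, conditions))
  se <- fold
  for (gn in genes) {
    sub <- ct[ct$gene == gn, , drop = FALSE]
    ref_ct <- ref$ct[match(paste(sub$condition, sub$replicate), ref_key)]
    if (anyNA(ref_ct)) {
      stop("reference gene '", reference_gene,
           "' missing for some replicate of gene '", gn, "'")
    }
    dct <- sub$ct - ref_ct
    cal_mean <- mean(dct[sub$condition == calibrator])
    if (is.nan(cal_mean)) {
      stop("gene '", gn, "' not measured in the calibrator condition")
    }
    for (cond in conditions) {
      dd <- dct[sub$condition == cond] - cal_mean
      folds <- 2^(-dd)
      if (aggregate == "mean_of_folds") {
        fold[gn, cond] <- mean(folds)
        se[gn, cond] <- if (length(folds) > 1L) {
          sd(folds) / sqrt(length(folds))
        } else 0
      } else {
        fold[gn, cond] <- 2^(-mean(dd))
        se[gn, cond] <- 0
      }
    }
  }
  list(fold = fold, se = se, calibrator = calibrator,
       reference_gene = reference_gene)
}

#' Filter genes by fold change
#'
#' Keeps genes whose expression in any condition is at least `threshold`
#' fold up, or at most `1/threshold` fold down (both inclusive).
#'
#' @param fold genes x conditions fold-change matrix.
#' @param threshold fold threshold > 1 (default 2.5).
#' @return character vector of gene ids.
#' @export
fold_filter <- function(fold, threshold = 2.5) {
  stopifnot(threshold > 1)
  hit <- apply(fold, 1, function(x) any(x >= threshold | x <= 1 / threshold))
  rownames(fold)[hit]
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative average-linkage clustering under correlation distance
#' (`1 - Pearson`) across conditions, or Euclidean distance.
#'
#' @param mat genes x conditions numeric matrix.
#' @param distance `"correlation"` or `"euclidean"`.
#' @return list with `hclust` (the [stats::hclust] tree), `order` (leaf
#'   gene ids in dendrogram order) and `dendrogram_newick`.
#' @export
hierarchical_cluster <- function(mat, distance = c("correlation",
                                                   "euclidean")) {
  distance <- match.arg(distance)
  if (nrow(mat) < 2L) stop("need at least two genes")
  if (distance == "correlation") {
    v <- apply(mat, 1, sd)
    if (any(v == 0)) {
      stop("zero-variance gene(s) under correlation distance (",
           paste(rownames(mat)[v == 0], collapse = ", "),
           "); use distance = 'euclidean'")
    }
    d <- as.dist(1 - cor(t(mat)))
  } else {
    d <- stats::dist(mat)
  }
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = rownames(mat)[hc$order],
       dendrogram_newick = ape::write.tree(phy))
}
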