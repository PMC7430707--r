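# Distance-based phylogenetics: p-distance with pairwise deletion,
# neighbor-joining, and column bootstrap with bipartition supports.

#' p-distance matrix with pairwise deletion
#'
#' For each pair of rows, columns where either row carries a gap are
#' excluded; the distance is the fraction of mismatches among the remaining
#' comparable sites.
#'
#' @param aln an `"msa"` object (see [progressive_msa()], [as_msa()]).
#' @return symmetric matrix of distances in `[0, 1]` with a `"sites"`
#'   attribute holding the per-pair comparable-site counts.
#' @export
p_distance_matrix <- function(aln) {
  rows <- as.character(aln)
  n <- length(rows)
  if (n < 2L) stop("need at least two rows")
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  gap <- mat == "-"
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  Nsites <- D
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      ns <- sum(ok)
      if (ns == 0L) {
        stop("no comparable sites between '", names(aln)[i], "' and '",
             names(aln)[j], "'")
      }
      d <- sum(mat[i, ok] != mat[j, ok]) / ns
      D[i, j] <- D[j, i] <- d
      Nsites[i, j] <- Nsites[j, i] <- ns
    }
  }
  attr(D, "sites") <- Nsites
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion.  Ties are broken
#' by the first minimal pair in row-major order over the current matrix;
#' negative branch lengths are clamped to zero with the deficit moved to
#' the sister branch, so the two branches still sum to the joined distance.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("distance matrix is not symmetric")
  }
  n <- nrow(D)
  if (n < 3L) stop("need at least three taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active cluster is carried as a newick fragment
  frag <- labels
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (length(frag) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    frag <- c(frag[keep], newfrag)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

# non-trivial bipartitions of an unrooted tree as canonical keys: each
# internal edge is named by the tip set on the side NOT containing the
# first reference tip, sorted and pipe-joined
.bipartitions <- function(tree, ref_tip) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs)
  keys <- character(0)
  for (p in parts) {
    tips <- labs[p]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    if (ref_tip %in% tips) tips <- setdiff(labs, tips)
    keys <- c(keys, paste(sort(tips), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement; a tree is built
#' per replicate ([p_distance_matrix()] + [neighbor_joining()]); the
#' support of each internal bipartition of the full-data tree is the
#' percentage of replicate trees containing it.  Replicate `r` draws its
#' columns from its own RNG stream seeded with `seed + r`, so supports are
#' reproducible and independent of taxon order.
#'
#' @param aln an `"msa"` object.
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer root seed (mandatory).
#' @return the full-data [ape::phylo] tree with `node.label` carrying
#'   bootstrap percentages (empty for the basal node).
#' @export
bootstrap_supports <- function(aln, n_replicates = 100L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  rows <- setNames(as.character(aln), names(aln))
  L <- nchar(rows[[1]])
  full <- neighbor_joining(p_distance_matrix(aln))
  ref <- sort(names(aln))[1]
  keys <- .bipartitions(full, ref)
  counts <- setNames(numeric(length(keys)), keys)
  for (r in seq_len(n_replicates)) {
    cols <- withr_seed_sample(seed + r, L)
    boot_rows <- vapply(rows, function(s) {
      paste(strsplit(s, "")[[1]][cols], collapse = "")
    }, character(1))
    bt <- neighbor_joining(p_distance_matrix(.msa_new(boot_rows)))
    bk <- .bipartitions(bt, ref)
    hit <- keys %in% bk
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_replicates
  # attach supports as internal node labels of the full tree
  parts <- ape::prop.part(full)
  labs <- attr(parts, "labels")
  n <- length(labs)
  node.label <- character(full$Nnode)
  for (k in seq_along(parts)) {
    tips <- labs[parts[[k]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    if (ref %in% tips) tips <- setdiff(labs, tips)
    key <- paste(sort(tips), collapse = "|")
    if (key %in% names(supports)) {
      node.label[k] <- sprintf("%g", supports[[key]])
    }
  }
  full$node.label <- node.label
  attr(full, "supports") <- supports
  full
}

# draw a bootstrap column sample from an isolated RNG stream
withr_seed_sample <- function(seed, L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(L, L, replace = TRUE)
}
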