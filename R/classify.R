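# Group/subgroup assignment: domain architecture gives a provisional group,
# tree placement against labelled references refines it to a subgroup, and
# a reconciliation rule resolves conflicts (or declares NG).

#' Provisional group from domain architecture
#'
#' Two C2H2 domains -> I; one C2H2 domain -> II (subgroup undetermined);
#' one C2HC domain -> III; two domains with any C2HC finger -> a
#' III-leaning provisional call (architecture intermediate between I and
#' III).
#'
#' @param domains data.frame from [scan_domains()].
#' @return list with `group` (`"I"`, `"II"`, `"III"`) and `leaning`
#'   (`NA` or `"III"` for the mixed two-domain case).
#' @export
feature_group <- function(domains) {
  if (nrow(domains) == 0L) stop("no WRKY domain: not a family member")
  nd <- nrow(domains)
  types <- domains$finger_type
  if (nd >= 2L) {
    if (all(types == "C2H2")) return(list(group = "I", leaning = NA_character_))
    return(list(group = "I", leaning = "III"))
  }
  if (types[1] == "C2H2") return(list(group = "II", leaning = NA_character_))
  list(group = "III", leaning = NA_character_)
}

#' Subgroup label from tree placement
#'
#' The query's label is the majority label among its `k` nearest labelled
#' reference leaves by patristic (path-length) distance.  Ties are broken
#' by the smallest total path length to the tied label's neighbours, then
#' lexicographically.
#'
#' @param tree an [ape::phylo] tree containing the query and the panel.
#' @param panel named character vector: reference leaf id -> subgroup label
#'   (labels from `I`, `IIa`..`IIe`, `III`).
#' @param query_id leaf id to classify.
#' @param k number of nearest labelled neighbours.
#' @return list with `label`, `unanimous` (all k neighbours agree),
#'   `neighbours` (data.frame id/label/distance).
#' @export
tree_subgroup <- function(tree, panel, query_id, k = 3L) {
  if (!query_id %in% tree$tip.label) stop("query '", query_id,
                                          "' is not a leaf of the tree")
  refs <- intersect(names(panel), tree$tip.label)
  if (!length(refs)) stop("no reference leaves present in the tree")
  bad <- setdiff(unique(panel), c("I", "IIa", "IIb", "IIc", "IId", "IIe",
                                  "III"))
  if (length(bad)) stop("invalid panel label(s): ",
                        paste(bad, collapse = ", "))
  dm <- ape::cophenetic.phylo(tree)
  d <- dm[query_id, refs]
  ord <- order(d, refs)
  k <- min(k, length(refs))
  nb <- data.frame(id = refs[ord][1:k],
                   label = unname(panel[refs[ord][1:k]]),
                   distance = unname(d[ord][1:k]),
                   stringsAsFactors = FALSE)
  tab <- table(nb$label)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    tot <- vapply(top, function(lb) sum(nb$distance[nb$label == lb]),
                  numeric(1))
    top <- top[tot == min(tot)]
    top <- sort(top)[1]
  }
  list(label = top, unanimous = length(unique(nb$label)) == 1L,
       neighbours = nb)
}

.top_group <- function(label) {
  if (label %in% c("IIa", "IIb", "IIc", "IId", "IIe", "II")) "II" else label
}

#' Reconcile feature-based and tree-based labels
#'
#' If the top-level groups agree, the tree's subgroup wins.  If they
#' disagree but the tree evidence is strong (all `k` neighbours share the
#' label), the tree label wins -- this is what places single-domain group-I
#' members and two-domain C2HC proteins.  If they disagree with mixed tree
#' evidence, or the query's finger type contradicts the expected finger
#' type of every neighbour, the gene is NG (no group).
#'
#' @param feature list from [feature_group()].
#' @param tree_call list from [tree_subgroup()].
#' @param finger_type the query's zinc-finger type (`"C2H2"`, `"C2HC"`,
#'   `"mixed"`).
#' @return list with `label` (final group label, possibly `"NG"`) and a
#'   human/machine-readable `trace` of the decision.
#' @export
reconcile <- function(feature, tree_call, finger_type = NA_character_) {
  fg <- .top_group(feature$group)
  tg <- .top_group(tree_call$label)
  expected_finger <- function(lab) {
    if (.top_group(lab) == "III") "C2HC" else "C2H2"
  }
  finger_conflict <- !is.na(finger_type) && finger_type != "mixed" &&
    all(vapply(tree_call$neighbours$label, expected_finger, character(1)) !=
          finger_type)
  if (fg == tg) {
    lab <- tree_call$label
    trace <- sprintf("agree:%s", lab)
  } else if (finger_conflict) {
    lab <- "NG"
    trace <- sprintf("finger-contradicts-neighbourhood:feature=%s,tree=%s",
                     feature$group, tree_call$label)
  } else if (tree_call$unanimous) {
    lab <- tree_call$label
    trace <- sprintf("tree-overrides:%s->%s", feature$group, lab)
  } else {
    lab <- "NG"
    trace <- sprintf("conflict-unresolved:feature=%s,tree=%s",
                     feature$group, tree_call$label)
  }
  list(label = lab, trace = trace,
       evidence = if (fg == tg) "reconciled" else
         if (lab == "NG") "none" else "tree-based")
}

#' Positional gene naming along chromosomes
#'
#' Genes are sorted by natural chromosome order then ascending start
#' coordinate and named `prefix1 .. prefixN` (duplicated positions are
#' tie-broken by end then id, with a warning).
#'
#' @param loci a [gene_loci()] data.frame.
#' @param prefix name prefix, e.g. `"SbWRKY"`.
#' @return named character vector: gene_id -> assigned name.
#' @export
assign_names <- function(loci, prefix = "WRKY") {
  key <- paste(loci$chromosome, loci$start)
  if (anyDuplicated(key)) {
    warning("duplicate (chromosome, start) pairs; tie-breaking by end, id")
  }
  ord <- order(chromosome_rank(loci$chromosome), loci$start, loci$end,
               loci$gene_id)
  nm <- character(nrow(loci))
  nm[ord] <- paste0(prefix, seq_len(nrow(loci)))
  setNames(nm, loci$gene_id)
}
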