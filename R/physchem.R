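# Physicochemical prediction: average-mass molecular weight and
# isoelectric point by charge-balance bisection.

# average (isotope-abundance weighted) residue masses, Da
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Molecular weight of a protein (kDa)
#'
#' Sum of average residue masses plus one water, in kilodaltons.  `X`
#' residues contribute `x_mass` daltons (0 by default).
#'
#' @param protein a single protein string.
#' @param x_mass mass assigned to `X`, in Da.
#' @return molecular weight in kDa.
#' @export
molecular_weight <- function(protein, x_mass = 0) {
  s <- as.character(protein)[[1]]
  if (!nzchar(s)) stop("empty sequence")
  cc <- strsplit(s, "")[[1]]
  m <- AA_AVG_MASS[cc]
  m[cc == "X"] <- x_mass
  if (anyNA(m)) stop("non-canonical residue(s): ",
                     paste(sort(unique(cc[is.na(m)])), collapse = ", "))
  (sum(m) + WATER_MASS) / 1000
}

# Bjellqvist-style pKa set (side chains as used by the common proteomics
# calculators); termini per the package default
PKA_DEFAULT <- list(
  nterm = 9.094, cterm = 2.869,
  positive = c(H = 5.98, K = 10.0, R = 12.0),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0))

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side
#' chains (D, E, C, Y, H, K, R).  Strictly decreasing in pH.
#'
#' @param protein a single protein string.
#' @param pH pH value(s).
#' @param pka pKa set (see `PKA_DEFAULT` layout).
#' @return net charge at each pH.
#' @export
net_charge <- function(protein, pH, pka = PKA_DEFAULT) {
  s <- as.character(protein)[[1]]
  cc <- strsplit(s, "")[[1]]
  counts_pos <- vapply(names(pka$positive), function(a) sum(cc == a),
                       numeric(1))
  counts_neg <- vapply(names(pka$negative), function(a) sum(cc == a),
                       numeric(1))
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pka$nterm)) +
      sum(counts_pos / (1 + 10^(p - pka$positive)))
    neg <- 1 / (1 + 10^(pka$cterm - p)) +
      sum(counts_neg / (1 + 10^(pka$negative - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' The pH in `[0, 14]` at which [net_charge()] vanishes, found by
#' bisection to `|charge| < tol`.  The charge function is strictly
#' decreasing in pH, so the root is unique.
#'
#' @param protein a single protein string.
#' @param pka pKa set.
#' @param tol charge tolerance at the root.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein, pka = PKA_DEFAULT, tol = 1e-4) {
  s <- as.character(protein)[[1]]
  if (!nzchar(s)) stop("empty sequence")
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(s, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}
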