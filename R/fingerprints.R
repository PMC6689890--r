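#' @importFrom ChemmineR smiles2sdf atomblock bondblock rings propOB smartsSearchOB
NULL

# ---- molecular graph -------------------------------------------------------
#
# Internal graph representation built from an SDF molecule: element symbols,
# bond list with orders, implicit hydrogen counts from standard valences,
# aromaticity flags from ring perception, and the SSSR ring set (used for
# aromatic-ring and bridge-bond counts). Structures are expected to be
# standardized (neutral parent), so formal charges are taken as zero.

.DEFAULT_VALENCE <- list(C = 4L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L,
                         I = 1L, B = 3L, S = c(2L, 4L, 6L), P = c(3L, 5L))

.molGraph <- function(sdf, ringInfo) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (is.null(dim(bb)) || nrow(ab) == 0) bb <- matrix(0L, 0, 3)
  if (nrow(bb)) bb <- bb[bb[, 1] >= 1 & bb[, 2] >= 1, , drop = FALSE]
  nb <- nrow(bb)
  b1 <- if (nb) as.integer(bb[, 1]) else integer(0)
  b2 <- if (nb) as.integer(bb[, 2]) else integer(0)
  bo <- if (nb) as.integer(bb[, 3]) else integer(0)

  # aromaticity from perceived rings
  aromAtoms <- logical(n)
  sssr <- list()
  if (length(ringInfo$RINGS)) {
    ringIdx <- lapply(ringInfo$RINGS, function(r) as.integer(gsub("^.*_", "", r)))
    sizes <- lengths(ringIdx)
    bondKeys <- lapply(ringIdx, function(idx) {
      a <- idx; b <- c(idx[-1], idx[1])
      paste(pmin(a, b), pmax(a, b))
    })
    allKeys <- unique(unlist(bondKeys))
    covered <- character(0)
    for (i in order(sizes)) {
      if (!all(bondKeys[[i]] %in% covered)) {
        sssr <- c(sssr, list(list(atoms = ringIdx[[i]], bonds = bondKeys[[i]],
                                  aromatic = unname(ringInfo$AROMATIC[i]))))
        covered <- union(covered, bondKeys[[i]])
      }
    }
    for (r in sssr) if (isTRUE(r$aromatic)) aromAtoms[r$atoms] <- TRUE
  }
  aromBonds <- logical(nb)
  if (nb && length(sssr)) {
    key <- paste(pmin(b1, b2), pmax(b1, b2))
    aromKeys <- unlist(lapply(sssr, function(r) if (isTRUE(r$aromatic)) r$bonds))
    aromBonds <- key %in% aromKeys
  }

  # implicit hydrogens: smallest standard valence covering the bond order sum
  bosum <- numeric(n)
  if (nb) {
    ord <- ifelse(aromBonds, 1.5, bo)
    for (k in seq_len(nb)) {
      bosum[b1[k]] <- bosum[b1[k]] + ord[k]
      bosum[b2[k]] <- bosum[b2[k]] + ord[k]
    }
  }
  bosum <- ceiling(bosum)
  hcount <- integer(n)
  for (i in seq_len(n)) {
    vals <- .DEFAULT_VALENCE[[elements[i]]]
    if (is.null(vals)) { hcount[i] <- 0L; next }
    v <- vals[vals >= bosum[i]]
    hcount[i] <- if (length(v)) as.integer(min(v) - bosum[i]) else 0L
  }

  adj <- vector("list", n)
  bondOrderCode <- integer(nb)
  if (nb) {
    bondOrderCode <- ifelse(aromBonds, 4L, bo)
    for (k in seq_len(nb)) {
      adj[[b1[k]]] <- rbind(adj[[b1[k]]], c(b2[k], bondOrderCode[k]))
      adj[[b2[k]]] <- rbind(adj[[b2[k]]], c(b1[k], bondOrderCode[k]))
    }
  }
  list(elements = elements, n = n, b1 = b1, b2 = b2, order = bondOrderCode,
       adj = adj, hcount = hcount, aromatic = aromAtoms, sssr = sssr)
}

# ---- pharmacophore (functional-class) atom typing --------------------------
#
# The six standard functional classes: H-bond acceptor, H-bond donor,
# positively ionizable, negatively ionizable, aromatic, halogen. Encoded as a
# 6-bit integer per atom; plain aliphatic carbon is class 0 and contributes
# to the fingerprint through connectivity only.

.atomClasses <- function(g) {
  el <- g$elements
  n <- g$n
  cls <- integer(n)
  isN <- el == "N"; isO <- el == "O"
  # neighbours double-bonded to O (for carboxyl / amide / nitro recognition)
  dblO <- logical(n)
  if (length(g$b1)) {
    d <- g$order == 2
    dblO[g$b1[d & isO[g$b2]]] <- TRUE
    dblO[g$b2[d & isO[g$b1]]] <- TRUE
  }
  for (i in seq_len(n)) {
    bits <- 0L
    nbr <- g$adj[[i]]
    nbrIdx <- if (is.null(nbr)) integer(0) else nbr[, 1]
    # acceptor: any O; N except pyrrole-type aromatic N carrying 3 connections
    if (isO[i] || (isN[i] && !(g$aromatic[i] && (length(nbrIdx) + g$hcount[i]) >= 3)))
      bits <- bits + 1L
    # donor: N/O with at least one hydrogen
    if ((isN[i] || isO[i]) && g$hcount[i] > 0) bits <- bits + 2L
    # positively ionizable: basic aliphatic amine (no adjacent C=O, no multiple bonds)
    if (isN[i] && !g$aromatic[i] && g$hcount[i] + length(nbrIdx) == 3 &&
        (!length(nbrIdx) || all(nbr[, 2] == 1)) && !any(dblO[nbrIdx]))
      bits <- bits + 4L
    # negatively ionizable: acidic OH on a carbonyl/sulfonyl/phosphoryl centre
    if (isO[i] && g$hcount[i] > 0 && length(nbrIdx) && any(dblO[nbrIdx]))
      bits <- bits + 8L
    if (g$aromatic[i]) bits <- bits + 16L
    if (el[i] %in% c("F", "Cl", "Br", "I")) bits <- bits + 32L
    cls[i] <- bits
  }
  cls
}

# ---- circular fingerprint --------------------------------------------------

.MOD31 <- 2147483647

.hashInts <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 31 + x) %% .MOD31
  as.integer(h)
}

# Iteratively hashed circular environments (diameter = 2 * radius) over
# functional-class initial invariants, collected across all iterations.
.fcfpFeatures <- function(g, radius = 3L) {
  inv <- .atomClasses(g)
  feats <- inv
  if (g$n == 0) return(integer(0))
  for (t in seq_len(radius)) {
    newInv <- integer(g$n)
    for (i in seq_len(g$n)) {
      nbr <- g$adj[[i]]
      if (is.null(nbr)) {
        newInv[i] <- .hashInts(c(t, inv[i]))
      } else {
        pairs <- cbind(nbr[, 2], inv[nbr[, 1]])
        o <- order(pairs[, 1], pairs[, 2])
        newInv[i] <- .hashInts(c(t, inv[i], t(pairs[o, , drop = FALSE])))
      }
    }
    inv <- newInv
    feats <- c(feats, inv)
  }
  unique(feats)
}

#' Functional-class circular fingerprint
#'
#' Computes an FCFP-style circular fingerprint: atoms are typed by six
#' pharmacophoric roles (H-bond acceptor/donor, positively/negatively
#' ionizable, aromatic, halogen), circular neighborhoods up to `radius`
#' bonds (diameter `2 * radius`) are iteratively hashed, and the resulting
#' feature identifiers are folded onto `nBits` positions by OR. Deterministic
#' for identical input.
#'
#' @param smiles character vector of standardized SMILES.
#' @param radius neighborhood radius in bonds (default 3, i.e. diameter 6).
#' @param nBits fingerprint length, a power of two (default 512).
#' @return a `length(smiles) x nBits` 0/1 integer matrix, rownames =
#'   `names(smiles)` when present.
#' @export
circularFingerprint <- function(smiles, radius = 3L, nBits = 512L) {
  stopifnot(nBits >= 2, bitwAnd(nBits, nBits - 1L) == 0L)
  graphs <- .molGraphs(smiles)
  fp <- matrix(0L, length(smiles), nBits,
               dimnames = list(names(smiles), sprintf("FP%04d", seq_len(nBits))))
  for (i in seq_along(graphs)) {
    f <- .fcfpFeatures(graphs[[i]], radius = radius)
    if (length(f)) fp[i, (f %% nBits) + 1L] <- 1L
  }
  fp
}

# Parse a batch of SMILES into an SDF set plus per-molecule ring info.
# Ring perception is skipped for molecules that cannot contain a ring
# (fewer than three bonds).
.parseBatch <- function(smiles) {
  smi <- as.character(smiles)
  nm <- paste0("m", seq_along(smi))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smi, nm)))
  if (length(sdf) != length(smi))
    stop("structure parse failure in descriptor input")
  empty <- list(RINGS = list(), AROMATIC = logical(0))
  ringInfo <- rep(list(empty), length(smi))
  nbonds <- vapply(seq_along(smi), function(i) {
    bb <- ChemmineR::bondblock(sdf[[i]])
    if (is.null(dim(bb))) 0L else sum(bb[, 1] >= 1 & bb[, 2] >= 1)
  }, 0L)
  canRing <- which(nbonds >= 3L)
  if (length(canRing)) {
    r <- ChemmineR::rings(sdf[canRing], type = "all", arom = TRUE)
    if (length(canRing) == 1L) r <- list(r)
    ringInfo[canRing] <- r
  }
  list(sdf = sdf, ringInfo = ringInfo)
}

.molGraphs <- function(smiles) {
  if (!length(smiles)) return(list())
  b <- .parseBatch(smiles)
  lapply(seq_along(b$ringInfo), function(i) .molGraph(b$sdf[[i]], b$ringInfo[[i]]))
}

#' Tanimoto similarity between fingerprints
#'
#' @param fp1 a 0/1 matrix (rows = compounds) or single vector.
#' @param fp2 same, defaults to `fp1`.
#' @return matrix of pairwise Tanimoto similarities \eqn{|A \cap B| / |A \cup B|};
#'   two empty fingerprints have similarity 0 by convention.
#' @export
tanimoto <- function(fp1, fp2 = fp1) {
  if (is.null(dim(fp1))) fp1 <- matrix(fp1, 1)
  if (is.null(dim(fp2))) fp2 <- matrix(fp2, 1)
  common <- fp1 %*% t(fp2)
  n1 <- rowSums(fp1); n2 <- rowSums(fp2)
  union <- outer(n1, n2, "+") - common
  out <- ifelse(union > 0, common / union, 0)
  dimnames(out) <- list(rownames(fp1), rownames(fp2))
  out
}
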