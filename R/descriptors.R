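# Rotatable bond: single acyclic bond between two non-terminal heavy atoms,
# neither of which is triple-bonded (the classic Daylight definition; amide
# C-N bonds are counted, which matches a permissive rotor count).
.ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Physicochemical descriptor block
#'
#' Computes the seven-property ligand block: molecular weight (Da), ALogP
#' (atom-contribution logP), H-bond acceptor count, H-bond donor count,
#' rotatable-bond count, bridge-bond count (bonds shared by two or more
#' rings of the smallest ring set, i.e. ring-fusion/bridge bonds), and
#' aromatic-ring count.
#'
#' @param smiles character vector of standardized SMILES.
#' @return numeric matrix with columns `MW`, `ALogP`, `HBA`, `HBD`, `RotB`,
#'   `BridgeB`, `AromRings`.
#' @export
physchemBlock <- function(smiles) {
  smi <- as.character(smiles)
  out <- matrix(NA_real_, length(smi), 7,
                dimnames = list(names(smiles),
                                c("MW", "ALogP", "HBA", "HBD", "RotB", "BridgeB", "AromRings")))
  if (!length(smi)) return(out)
  b <- .parseBatch(smi)
  sdf <- b$sdf
  p <- ChemmineR::propOB(sdf)
  out[, "MW"] <- p$MW
  out[, "ALogP"] <- p$logP
  out[, "HBA"] <- p$HBA2
  out[, "HBD"] <- p$HBD
  out[, "RotB"] <- ChemmineR::smartsSearchOB(sdf, .ROTOR_SMARTS, uniqueMatches = TRUE)
  for (i in seq_along(smi)) {
    g <- .molGraph(sdf[[i]], b$ringInfo[[i]])
    out[i, "AromRings"] <- sum(vapply(g$sssr, function(r) isTRUE(r$aromatic), TRUE))
    if (length(g$sssr)) {
      bondTab <- table(unlist(lapply(g$sssr, `[[`, "bonds")))
      out[i, "BridgeB"] <- sum(bondTab >= 2)
    } else out[i, "BridgeB"] <- 0
  }
  out
}

# ---- z-scale protein descriptors -------------------------------------------

#' Z-scale lookup table
#'
#' The first three z-scales per amino acid (lipophilicity, steric bulk,
#' polarity), shipped as a packaged CSV (Sandberg et al. 1998 values).
#'
#' @return data.frame with columns `aa`, `z1`, `z2`, `z3`.
#' @export
zscaleTable <- function() {
  read.csv(system.file("extdata", "zscales.csv", package = "pcmscreen"),
           stringsAsFactors = FALSE)
}

.zscaleMatrix <- function() {
  z <- zscaleTable()
  m <- as.matrix(z[, c("z1", "z2", "z3")])
  rownames(m) <- z$aa
  m
}

#' Z-scale protein descriptor for one panel member
#'
#' Converts the target's aligned sequence into z-scale features. In
#' `per_position_variable` mode, each alignment column that is not identical
#' across the whole panel contributes the target residue's (z1, z2, z3);
#' a gap contributes (0, 0, 0). In `sequence_mean` mode, the mean (z1, z2,
#' z3) over the target's non-gap positions is returned (length 3, invariant
#' to gap insertion).
#'
#' @param panel a [ProteinPanel].
#' @param targetId target to describe.
#' @param mode `"per_position_variable"` (default) or `"sequence_mean"`.
#' @return named numeric vector of z-scale features.
#' @export
zscaleDescriptor <- function(panel, targetId,
                             mode = c("per_position_variable", "sequence_mean")) {
  mode <- match.arg(mode)
  i <- match(targetId, targetIds(panel))
  if (is.na(i)) stop("unknown target: ", targetId)
  zm <- .zscaleMatrix()
  seqs <- as.matrix(alignment(panel))
  gapChars <- c("-", ".")
  bad <- !(seqs %in% c(rownames(zm), gapChars))
  if (any(bad)) {
    pos <- which(matrix(bad, nrow(seqs)), arr.ind = TRUE)[1, ]
    stop(sprintf("unknown residue symbol '%s' at alignment column %d (entry %s)",
                 seqs[pos[1], pos[2]], pos[2], targetIds(panel)[pos[1]]))
  }
  mine <- seqs[i, ]
  if (mode == "sequence_mean") {
    res <- mine[!(mine %in% gapChars)]
    v <- colMeans(zm[res, , drop = FALSE])
    names(v) <- c("Zmean_1", "Zmean_2", "Zmean_3")
    return(v)
  }
  variable <- apply(seqs, 2, function(col) length(unique(col)) > 1)
  cols <- which(variable)
  if (!length(cols)) return(setNames(numeric(0), character(0)))
  v <- matrix(0, length(cols), 3)
  resid <- mine[cols]
  known <- !(resid %in% gapChars)
  v[known, ] <- zm[resid[known], , drop = FALSE]
  out <- as.numeric(t(v))
  names(out) <- as.vector(t(outer(cols, 1:3, function(c, k) sprintf("Z%04d_%d", c, k))))
  out
}

# ---- assembly --------------------------------------------------------------

#' Assemble a PCM (or QSAR) feature matrix
#'
#' Builds one row per activity record: the compound's circular fingerprint
#' and physicochemical block, concatenated with the target's z-scale block.
#' With `panel = NULL` a ligand-only (QSAR) matrix is produced. With a
#' [LabelingScheme], rows are labeled active/inactive via [binarize()].
#'
#' @param compounds a [CompoundSet] resolving every `compound_id`.
#' @param activities an [ActivitySet]; one row is produced per record.
#' @param panel a [ProteinPanel] or `NULL` for QSAR mode.
#' @param scheme a [LabelingScheme] or `NULL` for unlabeled output.
#' @param nBits fingerprint length.
#' @param zmode protein descriptor mode, see [zscaleDescriptor()].
#' @param ligandCache optional environment memoising ligand descriptors by
#'   SMILES across calls.
#' @return a [PCMFeatureMatrix].
#' @export
assembleMatrix <- function(compounds, activities, panel = NULL, scheme = NULL,
                           nBits = 512L, zmode = "per_position_variable",
                           ligandCache = NULL) {
  cd <- compoundData(compounds)
  ad <- activityData(activities)
  missingC <- setdiff(ad$compound_id, cd$compound_id)
  missingT <- if (is.null(panel)) character(0) else setdiff(ad$target_id, targetIds(panel))
  if (length(missingC) || length(missingT))
    stop("unresolvable references: ",
         paste(c(head(missingC, 5), head(missingT, 5)), collapse = ", "))
  ligand <- .ligandBlock(cd, nBits = nBits, cache = ligandCache)
  feat <- ligand[match(ad$compound_id, rownames(ligand)), , drop = FALSE]
  ligandCols <- seq_len(ncol(feat))
  proteinCols <- integer(0)
  if (!is.null(panel)) {
    zb <- t(vapply(targetIds(panel),
                   function(t) zscaleDescriptor(panel, t, mode = zmode),
                   zscaleDescriptor(panel, targetIds(panel)[1], mode = zmode)))
    if (is.null(dim(zb)) || ncol(zb) == 0) {
      zb <- matrix(0, length(targetIds(panel)), 0,
                   dimnames = list(targetIds(panel), NULL))
    }
    pb <- zb[match(ad$target_id, rownames(zb)), , drop = FALSE]
    proteinCols <- ncol(feat) + seq_len(ncol(pb))
    feat <- cbind(feat, pb)
  }
  rownames(feat) <- NULL
  labels <- factor(character(0), levels = c("inactive", "active"))
  if (!is.null(scheme))
    labels <- binarize(ad$value, ad$dialect, scheme)
  new("PCMFeatureMatrix", features = feat,
      pairs = data.frame(compound_id = ad$compound_id, target_id = ad$target_id,
                         stringsAsFactors = FALSE),
      labels = labels, ligandCols = as.integer(ligandCols),
      proteinCols = as.integer(proteinCols))
}

# fingerprint + physchem in a single parse pass (one SDF conversion, one
# ring perception)
.ligandDescriptors <- function(smi, nBits = 512L, radius = 3L) {
  b <- .parseBatch(smi)
  fp <- matrix(0L, length(smi), nBits,
               dimnames = list(names(smi), sprintf("FP%04d", seq_len(nBits))))
  pc <- matrix(NA_real_, length(smi), 7,
               dimnames = list(names(smi),
                               c("MW", "ALogP", "HBA", "HBD", "RotB", "BridgeB", "AromRings")))
  p <- ChemmineR::propOB(b$sdf)
  pc[, "MW"] <- p$MW
  pc[, "ALogP"] <- p$logP
  pc[, "HBA"] <- p$HBA2
  pc[, "HBD"] <- p$HBD
  pc[, "RotB"] <- ChemmineR::smartsSearchOB(b$sdf, .ROTOR_SMARTS, uniqueMatches = TRUE)
  for (i in seq_along(smi)) {
    g <- .molGraph(b$sdf[[i]], b$ringInfo[[i]])
    f <- .fcfpFeatures(g, radius = radius)
    if (length(f)) fp[i, (f %% nBits) + 1L] <- 1L
    pc[i, "AromRings"] <- sum(vapply(g$sssr, function(r) isTRUE(r$aromatic), TRUE))
    pc[i, "BridgeB"] <- if (length(g$sssr)) {
      bondTab <- table(unlist(lapply(g$sssr, `[[`, "bonds")))
      sum(bondTab >= 2)
    } else 0
  }
  cbind(fp, pc)
}

# per unique compound, optionally memoised across calls
.ligandBlock <- function(cd, nBits = 512L, cache = NULL) {
  smi <- setNames(cd$smiles, cd$compound_id)
  if (!is.null(cache)) {
    keys <- paste0(smi, "#", nBits)
    hit <- vapply(keys, function(k) !is.null(cache[[k]]), TRUE)
    if (any(!hit)) {
      fresh <- .ligandDescriptors(smi[!hit], nBits = nBits)
      for (j in seq_len(sum(!hit))) cache[[keys[!hit][j]]] <- fresh[j, ]
    }
    out <- t(vapply(keys, function(k) cache[[k]], numeric(nBits + 7)))
    rownames(out) <- cd$compound_id
    colnames(out) <- colnames(.EMPTY_LIGAND_COLS(nBits))
    return(out)
  }
  .ligandDescriptors(smi, nBits = nBits)
}

.EMPTY_LIGAND_COLS <- function(nBits) {
  matrix(0, 0, nBits + 7,
         dimnames = list(NULL, c(sprintf("FP%04d", seq_len(nBits)),
                                 c("MW", "ALogP", "HBA", "HBD", "RotB",
                                   "BridgeB", "AromRings"))))
}

#' Round-trip a feature matrix through CSV
#'
#' @param x a [PCMFeatureMatrix].
#' @param path output CSV file.
#' @export
writeFeatureMatrix <- function(x, path) {
  d <- cbind(pairInfo(x),
             label = if (length(rowLabels(x))) as.character(rowLabels(x)) else NA,
             as.data.frame(featureMatrix(x)))
  attrLine <- sprintf("# ligandCols=%d proteinCols=%d",
                      length(x@ligandCols), length(x@proteinCols))
  con <- file(path, "w")
  writeLines(attrLine, con)
  write.csv(d, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param path CSV written by [writeFeatureMatrix()].
#' @export
readFeatureMatrix <- function(path) {
  hdr <- readLines(path, n = 1)
  nums <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  d <- read.csv(path, skip = 1, check.names = FALSE, stringsAsFactors = FALSE)
  feat <- as.matrix(d[, -(1:3), drop = FALSE])
  labels <- if (all(is.na(d$label)))
    factor(character(0), levels = c("inactive", "active"))
  else factor(d$label, levels = c("inactive", "active"))
  new("PCMFeatureMatrix", features = feat,
      pairs = d[, c("compound_id", "target_id")],
      labels = labels,
      ligandCols = seq_len(nums[1]),
      proteinCols = nums[1] + seq_len(nums[2]))
}
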