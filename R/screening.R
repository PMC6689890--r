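#' Score a compound library against one target
#'
#' Assigns the model's active-class probability to every library compound
#' for the given target: ligand descriptors are computed in batches (memory
#' bounded in library size) and concatenated with the target's fixed protein
#' block. Structures that cannot be processed are logged, excluded and
#' counted.
#'
#' @param model a [TrainedEnsemble] trained on a PCM matrix.
#' @param library a [CompoundSet] of standardized library compounds.
#' @param panel the [ProteinPanel] used in training (or `NULL` for a QSAR
#'   model).
#' @param targetId target to score against.
#' @param nBits fingerprint length used in training.
#' @param zmode protein descriptor mode used in training.
#' @param batchSize compounds per scoring batch.
#' @return `data.frame` with `compound_id`, `probability`, `MW`;
#'   failed ids in `attr(, "failures")`.
#' @export
scoreLibrary <- function(model, library, panel = NULL, targetId = NULL,
                         nBits = 512L, zmode = "per_position_variable",
                         batchSize = 1000L) {
  cd <- compoundData(library)
  if (!nrow(cd))
    return(structure(data.frame(compound_id = character(0),
                                probability = numeric(0), MW = numeric(0)),
                     failures = character(0)))
  out <- vector("list", ceiling(nrow(cd) / batchSize))
  failures <- character(0)
  for (b in seq_along(out)) {
    idx <- ((b - 1L) * batchSize + 1L):min(b * batchSize, nrow(cd))
    chunk <- cd[idx, , drop = FALSE]
    res <- tryCatch({
      cs <- methods::initialize(library, data = chunk)
      acts <- ActivitySet(chunk$compound_id,
                          if (is.null(targetId)) "NA" else targetId,
                          "percent_control", "percent", 100)
      fm <- assembleMatrix(cs, acts, panel = panel, scheme = NULL,
                           nBits = nBits, zmode = zmode)
      data.frame(compound_id = chunk$compound_id,
                 probability = predictProba(model, fm),
                 MW = featureMatrix(fm)[, "MW"],
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) {
      # isolate bad records: retry one by one
      res <- NULL
      for (i in idx) {
        row <- cd[i, , drop = FALSE]
        one <- tryCatch({
          cs <- methods::initialize(library, data = row)
          acts <- ActivitySet(row$compound_id,
                              if (is.null(targetId)) "NA" else targetId,
                              "percent_control", "percent", 100)
          fm <- assembleMatrix(cs, acts, panel = panel, scheme = NULL,
                               nBits = nBits, zmode = zmode)
          data.frame(compound_id = row$compound_id,
                     probability = predictProba(model, fm),
                     MW = featureMatrix(fm)[, "MW"],
                     stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (is.null(one)) failures <- c(failures, row$compound_id)
        else res <- rbind(res, one)
      }
    }
    out[[b]] <- res
  }
  scored <- do.call(rbind, out)
  if (length(failures))
    message(sprintf("%d unscorable structure(s) excluded", length(failures)))
  structure(scored, failures = failures)
}

#' Pre-filter scored compounds
#'
#' Keeps compounds with predicted class probability at or above `pCut` and
#' molecular weight strictly above `mwCut` (fragment-like compounds with
#' MW <= `mwCut` are removed).
#'
#' @param scored `data.frame` from [scoreLibrary()] (columns
#'   `compound_id`, `probability`, `MW`).
#' @param pCut probability cutoff (default 0.8, inclusive).
#' @param mwCut molecular-weight cutoff in Da (default 300, exclusive).
#' @return character vector of surviving compound ids.
#' @export
prefilter <- function(scored, pCut = 0.8, mwCut = 300) {
  scored$compound_id[scored$probability >= pCut & scored$MW > mwCut]
}

#' Select a chemically diverse subset by k-medoid clustering
#'
#' Clusters the survivors into `k` groups by PAM on the Tanimoto distance
#' (1 - Tanimoto on the circular fingerprints) and returns the medoid of
#' each cluster - real compounds serving as cluster centers. With `k` at or
#' above the number of survivors, all survivors are returned.
#'
#' @param fps fingerprint 0/1 matrix, rownames = compound ids.
#' @param k number of clusters (default 40).
#' @param seed kept for interface symmetry; PAM as used here is
#'   deterministic.
#' @return character vector of `min(k, n)` medoid compound ids.
#' @export
selectDiverse <- function(fps, k = 40L, seed = 1L) {
  n <- nrow(fps)
  stopifnot(n >= 1)
  if (n <= k) return(rownames(fps))
  d <- stats::as.dist(1 - tanimoto(fps))
  set.seed(seed)
  pm <- cluster::pam(d, k = k, pamonce = 5)
  rownames(fps)[pm$id.med]
}

#' Rank analogs of a reference compound
#'
#' Returns the `n` survivors most similar to the reference by Tanimoto on
#' the circular fingerprints, in descending similarity; ties are broken by
#' lexicographic compound id. If fewer than `n` survivors exist, all are
#' returned with a warning.
#'
#' @param referenceFp fingerprint vector of the reference compound.
#' @param fps survivor fingerprint matrix, rownames = compound ids.
#' @param n number of analogs requested.
#' @return named numeric vector: similarities named by compound id, ranked.
#' @export
selectAnalogs <- function(referenceFp, fps, n = 10L) {
  sims <- drop(tanimoto(matrix(referenceFp, 1), fps))
  names(sims) <- rownames(fps)
  if (n > length(sims)) {
    warning(sprintf("only %d survivors for %d requested analogs", length(sims), n),
            call. = FALSE)
    n <- length(sims)
  }
  o <- order(-sims, names(sims))
  sims[o[seq_len(n)]]
}

#' Run the full prospective selection procedure
#'
#' Scores the library, applies the probability and molecular-weight
#' pre-filter, picks `kDiverse` cluster medoids (the Diverse set), then for
#' each reference compound picks its top analogs among the survivors (the
#' Cluster set). Analog picks exclude compounds already chosen in the
#' Diverse set and by earlier references, so the combined pick list is
#' duplicate-free.
#'
#' @param model a [TrainedEnsemble].
#' @param library a [CompoundSet].
#' @param panel,targetId scoring context, see [scoreLibrary()].
#' @param references a [CompoundSet] of reference inhibitors, or `NULL`.
#' @param nAnalogs analogs per reference (recycled over references).
#' @param pCut,mwCut pre-filter cutoffs.
#' @param kDiverse size of the Diverse set.
#' @param nBits,zmode descriptor settings matching the model.
#' @param seed integer seed.
#' @return a [SelectionReport].
#' @export
selectCompounds <- function(model, library, panel = NULL, targetId = NULL,
                            references = NULL, nAnalogs = 10L,
                            pCut = 0.8, mwCut = 300, kDiverse = 40L,
                            nBits = 512L, zmode = "per_position_variable",
                            seed = 1L) {
  scored <- scoreLibrary(model, library, panel = panel, targetId = targetId,
                         nBits = nBits, zmode = zmode)
  survivors <- prefilter(scored, pCut = pCut, mwCut = mwCut)
  tab <- data.frame(scored,
                    passed_p50 = scored$probability >= 0.5,
                    passed_p80 = scored$probability >= pCut,
                    passed_mw = scored$MW > mwCut)
  diverse <- character(0)
  analogs <- list()
  if (length(survivors)) {
    cd <- compoundData(library)
    smi <- setNames(cd$smiles[match(survivors, cd$compound_id)], survivors)
    fps <- circularFingerprint(smi, nBits = nBits)
    diverse <- selectDiverse(fps, k = kDiverse, seed = seed)
    if (!is.null(references) && length(references)) {
      rd <- compoundData(references)
      refFps <- circularFingerprint(setNames(rd$smiles, rd$compound_id),
                                    nBits = nBits)
      nAnalogs <- rep_len(nAnalogs, nrow(rd))
      taken <- diverse
      for (j in seq_len(nrow(rd))) {
        pool <- setdiff(rownames(fps), taken)
        if (!length(pool)) { analogs[[rd$compound_id[j]]] <- character(0); next }
        picks <- selectAnalogs(refFps[j, ], fps[pool, , drop = FALSE],
                               n = nAnalogs[j])
        analogs[[rd$compound_id[j]]] <- names(picks)
        taken <- c(taken, names(picks))
      }
    }
  }
  new("SelectionReport", table = tab, diversePicks = diverse,
      analogPicks = analogs)
}

#' Write a selection report
#'
#' The per-compound table goes to CSV; the Diverse and analog pick lists to
#' plain-text id files next to it.
#'
#' @param report a [SelectionReport].
#' @param dir output directory.
#' @export
writeSelectionReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(selectionTable(report), file.path(dir, "selection_table.csv"),
            row.names = FALSE)
  writeLines(diversePicks(report), file.path(dir, "diverse_picks.txt"))
  ap <- analogPicks(report)
  for (ref in names(ap))
    writeLines(ap[[ref]], file.path(dir, sprintf("analogs_%s.txt", ref)))
  invisible(dir)
}
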