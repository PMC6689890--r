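#' Train a random-forest ensemble on a labeled feature matrix
#'
#' Fits a classification forest with `nTrees` trees; the number of variables
#' tried at each split defaults to the floor of the square root of the
#' number of feature columns (overridable). The returned ensemble predicts
#' class probability as the fraction of trees voting `active` and carries a
#' training manifest (data hash, hyperparameters, seed).
#'
#' @param matrix a labeled [PCMFeatureMatrix] with both classes present.
#' @param nTrees number of trees (default 500).
#' @param mtry variables tried per split; `NULL` for `floor(sqrt(p))`.
#' @param seed integer seed making the fit reproducible.
#' @param scheme optional [LabelingScheme] recorded in the manifest.
#' @return a [TrainedEnsemble].
#' @export
trainEnsemble <- function(matrix, nTrees = 500L, mtry = NULL, seed = 1L,
                          scheme = NULL) {
  y <- rowLabels(matrix)
  if (!length(y)) stop("feature matrix is unlabeled")
  if (length(unique(y)) < 2) stop("training data contains a single class")
  x <- featureMatrix(matrix)
  if (is.null(mtry)) mtry <- floor(sqrt(ncol(x)))
  fit <- ranger::ranger(x = x, y = y, num.trees = nTrees, mtry = mtry,
                        seed = seed, num.threads = 1)
  man <- list(
    n_rows = nrow(x), n_features = ncol(x),
    data_hash = .hashMatrix(x, y),
    n_trees = as.integer(nTrees), mtry = as.integer(mtry), seed = as.integer(seed),
    scheme = if (is.null(scheme)) NULL else
      c(pchembl_cutoff = scheme@pchemblCutoff, percent_cutoff = scheme@percentCutoff),
    ranger_version = as.character(packageVersion("ranger")))
  new("TrainedEnsemble", fit = fit, featureNames = colnames(x),
      nTrees = as.integer(nTrees), mtry = as.integer(mtry), manifest = man)
}

# lightweight content fingerprint of the training data for the manifest
.hashMatrix <- function(x, y) {
  s <- c(dim(x), round(colSums(x), 6), round(sum(x * seq_len(nrow(x))), 4),
         as.integer(y))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(s, collapse = ","), f)
  unname(tools::md5sum(f))
}

#' Predict active-class probabilities
#'
#' One probability per row, equal to the fraction of trees in the ensemble
#' voting for the active class.
#'
#' @param model a [TrainedEnsemble].
#' @param matrix a [PCMFeatureMatrix] whose columns match the training
#'   manifest (a mismatch raises an error naming the offending columns).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predictProba <- function(model, matrix) {
  x <- featureMatrix(matrix)
  if (nrow(x) == 0) return(numeric(0))
  if (!identical(colnames(x), model@featureNames)) {
    missing <- setdiff(model@featureNames, colnames(x))
    extra <- setdiff(colnames(x), model@featureNames)
    stop("feature columns do not match training manifest",
         if (length(missing)) paste0("; missing: ", paste(head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(head(extra, 5), collapse = ", ")))
  }
  pr <- predict(model@fit, data = x, predict.all = TRUE, num.threads = 1)$predictions
  activeIdx <- match("active", model@fit$forest$levels)
  rowMeans(pr == activeIdx)
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, PPV, NPV and MCC with the zero convention:
#' any ratio with a zero denominator is reported as 0, and the MCC of a
#' confusion matrix with any zero marginal is 0.
#'
#' @param truth,pred factors with levels `inactive`, `active`.
#' @return one-row `data.frame`: `TP, FP, TN, FN, sensitivity, specificity,
#'   ppv, npv, mcc`.
#' @export
confusionMetrics <- function(truth, pred) {
  truth <- factor(truth, levels = c("inactive", "active"))
  pred <- factor(pred, levels = c("inactive", "active"))
  tp <- sum(truth == "active" & pred == "active")
  fp <- sum(truth == "inactive" & pred == "active")
  tn <- sum(truth == "inactive" & pred == "inactive")
  fn <- sum(truth == "active" & pred == "inactive")
  safe <- function(num, den) if (den > 0) num / den else 0
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
             sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
             ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn), mcc = mcc)
}

#' MCC from the four classification rates
#'
#' The Matthews correlation coefficient expressed in terms of sensitivity,
#' specificity, PPV and NPV:
#' \deqn{MCC = \sqrt{sens \cdot spec \cdot PPV \cdot NPV} -
#'       \sqrt{(1-sens)(1-spec)(1-PPV)(1-NPV)}}
#' Used to cross-check reported per-fold mean rates against reported MCCs.
#'
#' @param sensitivity,specificity,ppv,npv rates in \[0, 1\].
#' @return the MCC.
#' @export
mccFromRates <- function(sensitivity, specificity, ppv, npv) {
  stopifnot(all(c(sensitivity, specificity, ppv, npv) >= 0),
            all(c(sensitivity, specificity, ppv, npv) <= 1))
  sqrt(sensitivity * specificity * ppv * npv) -
    sqrt((1 - sensitivity) * (1 - specificity) * (1 - ppv) * (1 - npv))
}

#' Stratified cross-validation folds over compounds
#'
#' Partitions compound ids into `k` folds, stratified by a per-compound
#' label so each fold sees both classes where possible. Folds partition the
#' id set exactly: union = all ids, pairwise disjoint.
#'
#' @param ids character compound ids (unique).
#' @param labels per-compound factor used for stratification.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` character vectors.
#' @export
makeFolds <- function(ids, labels, k = 5L, seed = 1L) {
  stopifnot(!anyDuplicated(ids), length(labels) == length(ids))
  set.seed(seed)
  fold <- integer(length(ids))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) ids[fold == f])
}

#' Run a cross-validation design
#'
#' Implements the three PCM validation designs plus the QSAR holdout
#' benchmark. Folds are always computed over the in-house primary-target
#' compounds (stratified by their label under `scheme`), and each fold's
#' report is computed on that fold's in-house primary-target records only,
#' so the identical test sets can be reused across designs:
#' \describe{
#'   \item{public_only_cv}{train on public-dialect records only;}
#'   \item{inhouse_only_cv}{train on in-house records minus the test fold;}
#'   \item{combined_cv}{train on public plus in-house minus the test fold;}
#'   \item{qsar_holdout}{ligand-only model, public primary-target records
#'     plus 70 percent of in-house primary-target records in training,
#'     evaluated on the held-out 30 percent.}
#' }
#' In every design, all records of a test-fold compound (any target, any
#' dialect) are excluded from training, so a test compound is never seen in
#' training.
#'
#' @param mode one of `public_only_cv`, `inhouse_only_cv`, `combined_cv`,
#'   `qsar_holdout`.
#' @param compounds a [CompoundSet].
#' @param activities an [ActivitySet].
#' @param panel a [ProteinPanel] (ignored in `qsar_holdout` mode).
#' @param scheme a [LabelingScheme].
#' @param primaryTarget the target whose in-house compounds are rotated.
#' @param nFolds folds (default 5).
#' @param nTrees,seed forest size and seed.
#' @param nBits fingerprint length.
#' @param zmode protein descriptor mode.
#' @param ligandCache optional descriptor cache environment.
#' @return list with `perFold` (one metrics row per fold), `summary`
#'   (mean and sd of each metric) and `folds` (the compound partitions).
#' @export
runValidation <- function(mode = c("combined_cv", "inhouse_only_cv",
                                   "public_only_cv", "qsar_holdout"),
                          compounds, activities, panel, scheme, primaryTarget,
                          nFolds = 5L, nTrees = 500L, seed = 1L, nBits = 512L,
                          zmode = "per_position_variable", ligandCache = NULL) {
  mode <- match.arg(mode)
  ad <- activityData(activities)
  inhPrim <- ad$dialect == "percent_control" & ad$target_id == primaryTarget
  if (!any(inhPrim)) stop("no in-house records for the primary target")
  inhIds <- unique(ad$compound_id[inhPrim])
  firstVal <- vapply(split(ad$value[inhPrim], ad$compound_id[inhPrim]), `[`, 0, 1)
  idLab <- as.character(binarize(firstVal[inhIds], "percent_control", scheme))
  names(idLab) <- inhIds

  usePanel <- if (mode == "qsar_holdout") NULL else panel
  fmAll <- assembleMatrix(compounds, activities, panel = usePanel,
                          scheme = scheme, nBits = nBits, zmode = zmode,
                          ligandCache = ligandCache)
  lab <- rowLabels(fmAll)
  rowsPub <- which(ad$dialect == "pchembl")
  rowsInh <- which(ad$dialect == "percent_control")
  if (mode == "qsar_holdout") {
    rowsPub <- which(ad$dialect == "pchembl" & ad$target_id == primaryTarget)
    rowsInh <- which(inhPrim)
  }

  if (mode == "qsar_holdout") {
    set.seed(seed)
    testIds <- unlist(lapply(split(inhIds, idLab), function(g)
      sample(g, round(length(g) * 0.3))))
    folds <- list(testIds)
  } else {
    folds <- makeFolds(inhIds, factor(idLab), k = nFolds, seed = seed)
  }

  perFold <- NULL
  for (f in seq_along(folds)) {
    testIds <- folds[[f]]
    testRows <- which(inhPrim & ad$compound_id %in% testIds)
    trainRows <- switch(mode,
      public_only_cv = rowsPub,
      inhouse_only_cv = rowsInh,
      combined_cv = c(rowsPub, rowsInh),
      qsar_holdout = c(rowsPub, rowsInh))
    trainRows <- setdiff(trainRows[!(ad$compound_id[trainRows] %in% testIds)],
                         integer(0))
    fmTrain <- fmAll[trainRows]
    if (length(unique(rowLabels(fmTrain))) < 2)
      stop("single-class training data in fold ", f)
    model <- trainEnsemble(fmTrain, nTrees = nTrees, seed = seed + f - 1L,
                           scheme = scheme)
    p <- predictProba(model, fmAll[testRows])
    pred <- factor(ifelse(p >= 0.5, "active", "inactive"),
                   levels = c("inactive", "active"))
    m <- confusionMetrics(lab[testRows], pred)
    m$fold <- f
    m$degenerate <- length(unique(lab[testRows])) < 2
    if (m$degenerate)
      warning("fold ", f, " has single-class truth; zero-convention metrics",
              call. = FALSE)
    perFold <- rbind(perFold, m)
  }
  metricCols <- c("sensitivity", "specificity", "ppv", "npv", "mcc")
  summary <- data.frame(metric = metricCols,
                        mean = vapply(metricCols, function(c) mean(perFold[[c]]), 0),
                        sd = vapply(metricCols, function(c) sd(perFold[[c]]), 0))
  list(perFold = perFold, summary = summary, folds = folds, mode = mode)
}

#' Persist / restore a trained ensemble
#'
#' The model is written as a versioned RDS artifact next to a JSON manifest
#' describing the training data and hyperparameters.
#'
#' @param model a [TrainedEnsemble].
#' @param path output `.rds` path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @export
saveEnsemble <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model@manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) readRDS(path)
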