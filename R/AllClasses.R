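#' @import methods
#' @importFrom stats predict rnorm runif sd setNames quantile plogis aggregate
#' @importFrom utils read.csv write.csv head packageVersion
NULL

.SOURCES <- c("public", "in_house", "library")
.DIALECTS <- c("pchembl", "percent_control")
.ACTIVITY_TYPES <- c("Ki", "IC50", "EC50", "Kd", "percent")

#' Set of standardized compounds
#'
#' Holds compound identifiers, standardized (canonical) SMILES and the data
#' source each compound came from. Construct with [CompoundSet()].
#'
#' @slot data a `data.frame` with columns `compound_id`, `smiles`, `source`.
#' @export
setClass("CompoundSet", representation(data = "data.frame"))

setValidity("CompoundSet", function(object) {
  d <- object@data
  msgs <- character()
  need <- c("compound_id", "smiles", "source")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$compound_id))
    msgs <- c(msgs, "compound_id values must be unique")
  if (!all(d$source %in% .SOURCES))
    msgs <- c(msgs, sprintf("source must be one of %s", paste(.SOURCES, collapse = "/")))
  if (any(is.na(d$smiles) | !nzchar(d$smiles)))
    msgs <- c(msgs, "empty SMILES not allowed")
  if (length(msgs)) msgs else TRUE
})

#' @param compound_id character vector of unique identifiers.
#' @param smiles character vector of standardized SMILES.
#' @param source one of `"public"`, `"in_house"`, `"library"` (recycled).
#' @rdname CompoundSet-class
#' @export
CompoundSet <- function(compound_id, smiles, source = "public") {
  new("CompoundSet", data = data.frame(
    compound_id = as.character(compound_id),
    smiles = as.character(smiles),
    source = rep_len(as.character(source), length(compound_id)),
    stringsAsFactors = FALSE))
}

#' Set of activity measurements
#'
#' One row per (compound, target) measurement. Two unit dialects coexist:
#' `pchembl` (-log10 molar potency; higher = more potent) and
#' `percent_control` (single-concentration readout where 100 = no inhibition;
#' lower = more potent).
#'
#' @slot data a `data.frame` with columns `compound_id`, `target_id`,
#'   `dialect`, `activity_type`, `value`, `confidence`.
#' @export
setClass("ActivitySet", representation(data = "data.frame"))

setValidity("ActivitySet", function(object) {
  d <- object@data
  need <- c("compound_id", "target_id", "dialect", "activity_type", "value", "confidence")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  msgs <- character()
  if (!all(d$dialect %in% .DIALECTS))
    msgs <- c(msgs, "dialect must be pchembl or percent_control")
  if (!all(d$activity_type %in% .ACTIVITY_TYPES))
    msgs <- c(msgs, "unknown activity_type")
  pc <- d$dialect == "pchembl"
  if (any(pc & (d$value <= 0 | d$value >= 14), na.rm = TRUE))
    msgs <- c(msgs, "pchembl values must lie in (0, 14)")
  if (any(!pc & d$value < 0, na.rm = TRUE))
    msgs <- c(msgs, "percent_control values must be >= 0")
  if (any(xor(d$activity_type == "percent", d$dialect == "percent_control")))
    msgs <- c(msgs, "activity_type 'percent' iff dialect 'percent_control'")
  if (length(msgs)) msgs else TRUE
})

#' @param compound_id,target_id character vectors.
#' @param dialect `"pchembl"` or `"percent_control"` (recycled).
#' @param activity_type one of Ki/IC50/EC50/Kd/percent (recycled).
#' @param value numeric measurement in the dialect's units.
#' @param confidence integer assay confidence (public dialect) or `NA`.
#' @rdname ActivitySet-class
#' @export
ActivitySet <- function(compound_id, target_id, dialect, activity_type, value,
                        confidence = NA_integer_) {
  n <- length(compound_id)
  new("ActivitySet", data = data.frame(
    compound_id = as.character(compound_id),
    target_id = rep_len(as.character(target_id), n),
    dialect = rep_len(as.character(dialect), n),
    activity_type = rep_len(as.character(activity_type), n),
    value = as.numeric(value),
    confidence = rep_len(as.integer(confidence), n),
    stringsAsFactors = FALSE))
}

#' Aligned protein panel
#'
#' The set of related targets the PCM model spans, as a gapped multiple
#' sequence alignment with one entry per target.
#'
#' @slot targets character, one id per entry.
#' @slot species character species tags, parallel to `targets`.
#' @slot alignment an [Biostrings::AAStringSet] of equal-width aligned sequences.
#' @export
setClass("ProteinPanel", representation(
  targets = "character", species = "character", alignment = "ANY"))

setValidity("ProteinPanel", function(object) {
  aln <- object@alignment
  if (!methods::is(aln, "AAStringSet")) return("alignment must be an AAStringSet")
  if (length(aln) != length(object@targets)) return("one aligned sequence per target")
  if (length(object@species) != length(object@targets)) return("one species tag per target")
  w <- Biostrings::width(aln)
  if (length(unique(w)) > 1) return("aligned sequences must have identical length")
  if (anyDuplicated(object@targets)) return("target ids must be unique")
  TRUE
})

#' @param targets,species character vectors.
#' @param alignment `AAStringSet` (or named character) of aligned sequences.
#' @rdname ProteinPanel-class
#' @export
ProteinPanel <- function(targets, alignment, species = rep("unknown", length(targets))) {
  if (is.character(alignment)) alignment <- Biostrings::AAStringSet(alignment)
  names(alignment) <- targets
  new("ProteinPanel", targets = as.character(targets),
      species = as.character(species), alignment = alignment)
}

#' Dual-dialect activity labeling scheme
#'
#' @slot pchemblCutoff active iff pChEMBL value strictly exceeds this.
#' @slot percentCutoff active iff percent-of-control is strictly below this.
#' @export
setClass("LabelingScheme",
         representation(pchemblCutoff = "numeric", percentCutoff = "numeric"))

setValidity("LabelingScheme", function(object) {
  msgs <- character()
  if (object@pchemblCutoff < 4 || object@pchemblCutoff > 10)
    msgs <- c(msgs, "pchemblCutoff must lie in [4, 10]")
  if (object@percentCutoff <= 0 || object@percentCutoff >= 100)
    msgs <- c(msgs, "percentCutoff must lie in (0, 100)")
  if (length(msgs)) msgs else TRUE
})

#' @param pchemblCutoff,percentCutoff numeric cutoffs.
#' @rdname LabelingScheme-class
#' @export
LabelingScheme <- function(pchemblCutoff = 8.5, percentCutoff = 70) {
  new("LabelingScheme", pchemblCutoff = pchemblCutoff, percentCutoff = percentCutoff)
}

#' PCM feature matrix
#'
#' Row-aligned ligand and protein descriptor blocks for (compound, target)
#' pairs, with optional binary labels. The ligand block is identical for the
#' same compound across targets and the protein block identical for the same
#' target across compounds.
#'
#' @slot features numeric matrix, rows = pairs, columns = descriptors.
#' @slot pairs `data.frame` with `compound_id`, `target_id` per row.
#' @slot labels factor with levels `inactive`, `active`; length 0 when unlabeled.
#' @slot ligandCols,proteinCols integer column indices of the two blocks.
#' @export
setClass("PCMFeatureMatrix", representation(
  features = "matrix", pairs = "data.frame", labels = "factor",
  ligandCols = "integer", proteinCols = "integer"))

setValidity("PCMFeatureMatrix", function(object) {
  msgs <- character()
  if (nrow(object@features) != nrow(object@pairs))
    msgs <- c(msgs, "features and pairs must have the same number of rows")
  if (length(object@labels) && length(object@labels) != nrow(object@features))
    msgs <- c(msgs, "labels must be empty or one per row")
  if (anyNA(object@features))
    msgs <- c(msgs, "feature matrix must not contain missing values")
  if (length(object@labels) && !identical(levels(object@labels), c("inactive", "active")))
    msgs <- c(msgs, "labels must have levels inactive, active")
  if (length(msgs)) msgs else TRUE
})

#' Trained random-forest ensemble
#'
#' Wraps a fitted classification forest whose class probability is the
#' fraction of trees voting `active`, plus a training manifest for
#' reproducibility.
#'
#' @slot fit the fitted [ranger::ranger] forest.
#' @slot featureNames training column names, in order.
#' @slot nTrees,mtry integers.
#' @slot manifest list: data hash, seed, labeling scheme, hyperparameters.
#' @export
setClass("TrainedEnsemble", representation(
  fit = "ANY", featureNames = "character", nTrees = "integer",
  mtry = "integer", manifest = "list"))

#' Grid-search result over labeling schemes
#'
#' @slot cells `data.frame`: one row per (pchembl_cutoff, percent_cutoff)
#'   cell with its benchmark confusion counts and metrics.
#' @slot selected the [LabelingScheme] maximizing MCC.
#' @export
setClass("GridResult", representation(cells = "data.frame", selected = "LabelingScheme"))

#' Prospective selection report
#'
#' @slot table per-library-compound `data.frame`: probability, molecular
#'   weight and filter flags.
#' @slot diversePicks compound ids of the diversity (cluster-medoid) picks.
#' @slot analogPicks named list: reference id -> ranked analog ids.
#' @export
setClass("SelectionReport", representation(
  table = "data.frame", diversePicks = "character", analogPicks = "list"))

setValidity("SelectionReport", function(object) {
  msgs <- character()
  if (anyDuplicated(object@diversePicks)) msgs <- c(msgs, "diverse picks must be unique")
  for (p in object@analogPicks)
    if (anyDuplicated(p)) msgs <- c(msgs, "analog pick lists must be duplicate-free")
  if (length(msgs)) msgs else TRUE
})

#' 2-D chemical-space embedding
#'
#' @slot coords n x 2 matrix with columns `CSNE1`, `CSNE2`, rownames = ids.
#' @slot perplexity,seed the embedding parameters.
#' @export
setClass("EmbeddingResult", representation(
  coords = "matrix", perplexity = "numeric", seed = "integer"))

setValidity("EmbeddingResult", function(object) {
  if (ncol(object@coords) != 2) return("coords must have two columns")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  TRUE
})
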