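#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname accessors
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))
#' @rdname accessors
#' @export
setGeneric("activityData", function(x) standardGeneric("activityData"))
#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))
#' @rdname accessors
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))
#' @rdname accessors
#' @export
setGeneric("rowLabels", function(x) standardGeneric("rowLabels"))
#' @rdname accessors
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))
#' @rdname accessors
#' @export
setGeneric("mtry", function(x) standardGeneric("mtry"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("gridCells", function(x) standardGeneric("gridCells"))
#' @rdname accessors
#' @export
setGeneric("selectedScheme", function(x) standardGeneric("selectedScheme"))
#' @rdname accessors
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))
#' @rdname accessors
#' @export
setGeneric("diversePicks", function(x) standardGeneric("diversePicks"))
#' @rdname accessors
#' @export
setGeneric("analogPicks", function(x) standardGeneric("analogPicks"))
#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

setMethod("compoundIds", "CompoundSet", function(x) x@data$compound_id)
setMethod("compoundData", "CompoundSet", function(x) x@data)
setMethod("activityData", "ActivitySet", function(x) x@data)
setMethod("targetIds", "ProteinPanel", function(x) x@targets)
setMethod("alignment", "ProteinPanel", function(x) x@alignment)
setMethod("featureMatrix", "PCMFeatureMatrix", function(x) x@features)
setMethod("pairInfo", "PCMFeatureMatrix", function(x) x@pairs)
setMethod("rowLabels", "PCMFeatureMatrix", function(x) x@labels)
setMethod("nTrees", "TrainedEnsemble", function(x) x@nTrees)
setMethod("mtry", "TrainedEnsemble", function(x) x@mtry)
setMethod("manifest", "TrainedEnsemble", function(x) x@manifest)
setMethod("gridCells", "GridResult", function(x) x@cells)
setMethod("selectedScheme", "GridResult", function(x) x@selected)
setMethod("selectionTable", "SelectionReport", function(x) x@table)
setMethod("diversePicks", "SelectionReport", function(x) x@diversePicks)
setMethod("analogPicks", "SelectionReport", function(x) x@analogPicks)
setMethod("embeddingCoords", "EmbeddingResult", function(x) x@coords)

#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@data))
#' @export
setMethod("length", "ActivitySet", function(x) nrow(x@data))
#' @export
setMethod("length", "ProteinPanel", function(x) length(x@targets))

#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@data$compound_id)
  methods::initialize(x, data = x@data[i, , drop = FALSE])
})

#' @export
setMethod("[", "ActivitySet", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, data = x@data[i, , drop = FALSE])
})

#' @export
setMethod("[", "PCMFeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  new("PCMFeatureMatrix",
      features = x@features[i, , drop = FALSE],
      pairs = x@pairs[i, , drop = FALSE],
      labels = if (length(x@labels)) x@labels[i] else x@labels,
      ligandCols = x@ligandCols, proteinCols = x@proteinCols)
})

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet with", nrow(object@data), "compounds\n")
  cat("  sources:", paste(sprintf("%s=%d", names(table(object@data$source)),
                                  table(object@data$source)), collapse = ", "), "\n")
})

setMethod("show", "ActivitySet", function(object) {
  d <- object@data
  cat("ActivitySet with", nrow(d), "records over", length(unique(d$target_id)),
      "targets\n")
  cat("  dialects:", paste(sprintf("%s=%d", names(table(d$dialect)),
                                   table(d$dialect)), collapse = ", "), "\n")
})

setMethod("show", "ProteinPanel", function(object) {
  cat("ProteinPanel with", length(object@targets), "aligned sequences (width",
      if (length(object@targets)) Biostrings::width(object@alignment)[1] else 0, ")\n")
  cat("  targets:", paste(object@targets, collapse = ", "), "\n")
})

setMethod("show", "LabelingScheme", function(object) {
  cat(sprintf("LabelingScheme: active iff pChEMBL > %.2f (public) or %%control < %.1f (in-house)\n",
              object@pchemblCutoff, object@percentCutoff))
})

setMethod("show", "PCMFeatureMatrix", function(object) {
  cat("PCMFeatureMatrix:", nrow(object@features), "pairs x",
      ncol(object@features), "features\n")
  cat("  ligand block:", length(object@ligandCols), "columns; protein block:",
      length(object@proteinCols), "columns\n")
  if (length(object@labels))
    cat("  labels:", sum(object@labels == "active"), "active /",
        sum(object@labels == "inactive"), "inactive\n")
  else cat("  unlabeled (screening mode)\n")
})

setMethod("show", "TrainedEnsemble", function(object) {
  cat("TrainedEnsemble:", object@nTrees, "trees, mtry", object@mtry, ",",
      length(object@featureNames), "features\n")
})

setMethod("show", "GridResult", function(object) {
  cat("GridResult over", nrow(object@cells), "threshold cells\n")
  show(object@selected)
  cat(sprintf("  benchmark MCC at selected cell: %.3f\n",
              max(object@cells$mcc)))
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport:", nrow(object@table), "library compounds;",
      sum(object@table$passed_p80 & object@table$passed_mw), "pass the pre-filter\n")
  cat("  diverse picks:", length(object@diversePicks),
      "; analog references:", length(object@analogPicks), "\n")
})

setMethod("show", "EmbeddingResult", function(object) {
  cat("EmbeddingResult:", nrow(object@coords), "compounds, perplexity",
      object@perplexity, "\n")
})
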