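#' Standardize chemical structures to a neutral canonical parent
#'
#' Applies the curation cascade used before any descriptor calculation:
#' keep the largest organic fragment (salt/counter-ion stripping), neutralize
#' charges (protonate acids, deprotonate bases to the neutral parent), and
#' emit a canonical SMILES. Stereo annotations present in the input are kept
#' as given; the function is idempotent on its own output.
#'
#' @param x character vector of SMILES (multi-fragment allowed).
#' @param ids record identifiers used in error reports; defaults to
#'   `names(x)` or positional ids.
#' @param onError `"stop"` raises a structured parse error (condition class
#'   `pcm_parse_error` carrying `record_id`) on the first unparseable record;
#'   `"drop"` removes offending records and attaches their ids as
#'   `attr(result, "failures")`.
#' @return character vector of canonical SMILES named by `ids`.
#' @export
standardizeStructure <- function(x, ids = NULL, onError = c("stop", "drop")) {
  onError <- match.arg(onError)
  if (is.null(ids)) ids <- if (!is.null(names(x))) names(x) else paste0("record", seq_along(x))
  if (!length(x)) return(setNames(character(0), character(0)))
  frag <- vapply(as.character(x), .largestFragment, "", USE.NAMES = FALSE)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(frag) & nzchar(frag)
  if (any(ok)) {
    res <- .obCanonicalNeutral(frag[ok])
    out[ok] <- res
  }
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    if (onError == "stop") {
      cond <- structure(class = c("pcm_parse_error", "error", "condition"),
                        list(message = sprintf("unparseable structure for record '%s'",
                                               ids[which(bad)[1]]),
                             call = sys.call(-1), record_id = ids[bad]))
      stop(cond)
    }
    out <- out[!bad]
    ids_ok <- ids[!bad]
    names(out) <- ids_ok
    attr(out, "failures") <- ids[bad]
    return(out)
  }
  setNames(out, ids)
}

# Largest fragment by heavy-atom count; carbon-containing fragments are
# preferred over purely inorganic ones (the "largest organic fragment" rule).
.largestFragment <- function(smi) {
  parts <- strsplit(smi, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(NA_character_)
  if (length(parts) == 1L) return(parts)
  nheavy <- vapply(parts, .heavyAtomCount, 0L)
  organic <- grepl("C|c", vapply(parts, function(p) gsub("Cl|Ca|Cu|Cd|Co|Cr|Cs", "", p), ""))
  score <- nheavy + ifelse(organic, 1000L, 0L)
  parts[which.max(score)]
}

# Token-level heavy atom counter (H and ring/bond symbols ignored).
.heavyAtomCount <- function(smi) {
  # bracket atoms count as one heavy atom unless they are [H] variants
  brackets <- gregexpr("\\[[^]]*\\]", smi)[[1]]
  nb <- 0L
  if (brackets[1] != -1) {
    toks <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
    nb <- sum(!grepl("^\\[[0-9]*H[0-9]*[+-]?\\]$", toks))
    smi <- gsub("\\[[^]]*\\]", "", smi)
  }
  organics <- gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", smi)[[1]]
  nb + if (organics[1] == -1) 0L else length(organics)
}

# Neutralize + canonicalize a batch of single-fragment SMILES through
# Open Babel; returns NA for records the toolkit cannot parse.
.obCanonicalNeutral <- function(smi) {
  n <- length(smi)
  input <- paste(paste(smi, seq_len(n), sep = "\t"), collapse = "\n")
  ops <- data.frame(names = "neutralize", args = "")
  lines <- tryCatch({
    raw <- ChemmineOB::convertFormat("SMI", "CAN", input, options = ops)
    strsplit(raw, "\n", fixed = TRUE)[[1]]
  }, error = function(e) character(0))
  out <- rep(NA_character_, n)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2) {
        idx <- suppressWarnings(as.integer(trimws(p[2])))
        if (!is.na(idx) && idx >= 1 && idx <= n) out[idx] <- trimws(p[1])
      }
    }
  }
  # fall back record-by-record for anything the batch call lost
  missing <- which(is.na(out) | !nzchar(out))
  for (i in missing) {
    out[i] <- tryCatch({
      r <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smi[i], "\tx"), options = ops)
      v <- trimws(strsplit(strsplit(r, "\n")[[1]][1], "\t")[[1]][1])
      if (nzchar(v)) v else NA_character_
    }, error = function(e) NA_character_)
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Read a compound file into a CompoundSet
#'
#' Reads SMILES (`.smi`, one record per line, `id<TAB>smiles`; a single
#' column is treated as bare SMILES with positional ids) or SDF. Every
#' structure is passed through [standardizeStructure()]; records that fail to
#' parse are dropped, reported with a warning, and listed in
#' `attr(x, "failures")`.
#'
#' @param path file path.
#' @param source provenance tag (`public`, `in_house`, `library`).
#' @param format `"auto"` (by extension), `"smi"` or `"sdf"`.
#' @return a [CompoundSet]; failed record ids in `attr(, "failures")`.
#' @export
readCompounds <- function(path, source = "public", format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][1] else paste0("cmp", i), "")
    smis <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    ids[!nzchar(ids)] <- paste0("cmp", which(!nzchar(ids)))
    smis <- as.character(ChemmineR::sdf2smiles(sdf))
  }
  std <- standardizeStructure(smis, ids = ids, onError = "drop")
  fails <- attr(std, "failures")
  if (length(fails))
    warning(sprintf("%d record(s) failed standardization: %s", length(fails),
                    paste(head(fails, 5), collapse = ", ")), call. = FALSE)
  cs <- CompoundSet(names(std), as.character(std), source = source)
  attr(cs, "failures") <- fails
  cs
}

#' Read an activity CSV into an ActivitySet
#'
#' Expects the header `compound_id,target_id,dialect,activity_type,value,
#' confidence`. Rows violating the record contract (unknown dialect or type,
#' non-numeric or out-of-range value) are dropped with a warning rather than
#' aborting the read.
#'
#' @param path CSV file path.
#' @return an [ActivitySet]; dropped row numbers in `attr(, "failures")`.
#' @export
readActivities <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_id", "dialect", "activity_type", "value")
  if (!all(need %in% names(d)))
    stop("activity CSV must have columns: ", paste(need, collapse = ", "))
  if (!"confidence" %in% names(d)) d$confidence <- NA_integer_
  d$value <- suppressWarnings(as.numeric(d$value))
  ok <- d$dialect %in% .DIALECTS & d$activity_type %in% .ACTIVITY_TYPES &
    !is.na(d$value) &
    ifelse(d$dialect == "pchembl", d$value > 0 & d$value < 14, d$value >= 0) &
    !xor(d$activity_type == "percent", d$dialect == "percent_control")
  if (any(!ok))
    warning(sprintf("%d activity row(s) dropped as malformed", sum(!ok)), call. = FALSE)
  a <- ActivitySet(d$compound_id[ok], d$target_id[ok], d$dialect[ok],
                   d$activity_type[ok], d$value[ok], d$confidence[ok])
  attr(a, "failures") <- which(!ok)
  a
}

#' Read an aligned protein panel
#'
#' Consumes a precomputed whole-sequence alignment in aligned FASTA or
#' Clustal format. Sequence names of the form `target|species` populate the
#' species tag; otherwise the species is `unknown`.
#'
#' @param path alignment file.
#' @param format `"auto"` (by extension: `.aln`/`.clustal` is Clustal,
#'   anything else FASTA), `"fasta"` or `"clustal"`.
#' @return a [ProteinPanel].
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(aln|clustal)$", path, ignore.case = TRUE)) "clustal" else "fasta"
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  aln <- methods::as(msa, "AAStringSet")
  nm <- sub("\\s.*$", "", names(aln))
  species <- ifelse(grepl("|", nm, fixed = TRUE), sub("^[^|]*\\|", "", nm), "unknown")
  targets <- sub("\\|.*$", "", nm)
  ProteinPanel(targets, aln, species = species)
}

#' Keep activity records at the accepted assay-confidence scores
#'
#' Public pChEMBL-dialect records carry an assay confidence score; only
#' scores 7 and 9 (direct single-protein assignment) are retained. Records
#' without a confidence score are dropped and logged. Input order is
#' preserved.
#'
#' @param activities an [ActivitySet], pchembl dialect only.
#' @param keep integer scores to retain.
#' @return filtered [ActivitySet].
#' @export
filterConfidence <- function(activities, keep = c(7L, 9L)) {
  d <- activityData(activities)
  if (any(d$dialect != "pchembl"))
    stop("filterConfidence applies to the pchembl dialect only")
  nNA <- sum(is.na(d$confidence))
  if (nNA) message(sprintf("dropping %d record(s) without confidence score", nNA))
  methods::initialize(activities, data = d[!is.na(d$confidence) & d$confidence %in% keep, ,
                                           drop = FALSE])
}

.ACTIVITY_RANK <- c(Ki = 1L, IC50 = 2L, EC50 = 3L, Kd = 4L)

#' Resolve duplicate activity measurements
#'
#' For each (compound, target) pair, only records of the highest-ranked
#' available activity type are kept, with the ranking Ki > IC50 > EC50 > Kd;
#' remaining same-type duplicates are collapsed to their arithmetic mean
#' pChEMBL value. Pair order follows first occurrence in the input.
#'
#' @param activities an [ActivitySet], pchembl dialect only.
#' @return deduplicated [ActivitySet], one record per (compound, target).
#' @export
deduplicateActivities <- function(activities) {
  d <- activityData(activities)
  if (!nrow(d)) return(activities)
  if (any(d$dialect != "pchembl"))
    stop("deduplicateActivities applies to the pchembl dialect only")
  key <- paste(d$compound_id, d$target_id, sep = "\r")
  first <- !duplicated(key)
  out <- do.call(rbind, lapply(key[first], function(k) {
    g <- d[key == k, , drop = FALSE]
    rank <- .ACTIVITY_RANK[g$activity_type]
    g <- g[rank == min(rank), , drop = FALSE]
    data.frame(compound_id = g$compound_id[1], target_id = g$target_id[1],
               dialect = "pchembl", activity_type = g$activity_type[1],
               value = mean(g$value),
               confidence = g$confidence[1], stringsAsFactors = FALSE)
  }))
  methods::initialize(activities, data = out)
}

#' Merge the public and in-house datasets
#'
#' Compounds are identified by their standardized canonical SMILES: a
#' structure present in both sources keeps a single record (under the
#' lexicographically smallest of its ids, tagged `in_house` since the
#' in-house chemical space is the modelling target). When the same
#' (compound, target) pair carries records in both unit dialects, the
#' in-house percent-of-control record wins. Unique compound and activity
#' counts are logged.
#'
#' @param public list with elements `compounds` ([CompoundSet]) and
#'   `activities` ([ActivitySet]), standardized and deduplicated.
#' @param inhouse same, for the in-house source.
#' @return list with merged `compounds` and `activities`.
#' @export
mergeDatasets <- function(public, inhouse) {
  pc <- compoundData(public$compounds)
  ic <- compoundData(inhouse$compounds)
  all <- rbind(pc, ic)
  # canonical id per structure: lexicographically smallest id
  canon <- vapply(split(all$compound_id, all$smiles), function(ids) min(ids), "")
  src <- vapply(split(all$source, all$smiles), function(s)
    if ("in_house" %in% s) "in_house" else s[1], "")
  smiles <- names(canon)
  o <- order(canon)
  compounds <- CompoundSet(canon[o], smiles[o], source = src[o])

  idmap <- setNames(canon[match(all$smiles, names(canon))], all$compound_id)
  pa <- activityData(public$activities)
  ia <- activityData(inhouse$activities)
  pa$compound_id <- unname(idmap[pa$compound_id])
  ia$compound_id <- unname(idmap[ia$compound_id])
  keyI <- paste(ia$compound_id, ia$target_id, sep = "\r")
  keyP <- paste(pa$compound_id, pa$target_id, sep = "\r")
  clash <- keyP %in% keyI
  if (any(clash))
    message(sprintf("%d cross-dialect duplicate pair(s): in-house record kept", sum(clash)))
  act <- rbind(pa[!clash, , drop = FALSE], ia)
  act <- act[order(act$compound_id, act$target_id, act$dialect), , drop = FALSE]
  rownames(act) <- NULL
  message(sprintf("merged dataset: %d unique compounds, %d activities",
                  length(compounds), nrow(act)))
  list(compounds = compounds,
       activities = methods::initialize(public$activities, data = act))
}
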