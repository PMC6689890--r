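# Shared fixtures, memoised across test files (test_check runs everything in
# one process). All compound structures are generated in code; nothing is
# read from disk except files the tests themselves write.

.fixtureEnv <- new.env(parent = emptyenv())

# descriptor memo shared by every test that assembles feature matrices
ligandCache <- function() {
  if (is.null(.fixtureEnv$cache)) .fixtureEnv$cache <- new.env(parent = emptyenv())
  .fixtureEnv$cache
}

memo <- function(key, expr) {
  if (is.null(.fixtureEnv[[key]])) .fixtureEnv[[key]] <- force(expr)
  .fixtureEnv[[key]]
}

# a small but complete synthetic study (panel, public, in-house, library)
smallDataset <- function() {
  memo("small", generateDataset(generatorConfig(
    seed = 11L, n_public_compounds = 60L, n_inhouse_compounds = 150L,
    n_library = 100L)))
}

smallMerged <- function() {
  memo("small_merged", {
    ds <- smallDataset()
    pubA <- deduplicateActivities(filterConfidence(ds$public$activities))
    suppressMessages(mergeDatasets(
      list(compounds = ds$public$compounds, activities = pubA), ds$inhouse))
  })
}

# a handful of named drug-like structures for descriptor unit tests
toySmiles <- c(
  ethanol = "CCO",
  benzene = "c1ccccc1",
  naphthalene = "c1ccc2ccccc2c1",
  aceticAcid = "CC(=O)O",
  aniline = "Nc1ccccc1",
  pyridine = "c1ccncc1",
  triethylamine = "CCN(CC)CC",
  chlorobenzene = "Clc1ccccc1",
  phenol = "Oc1ccccc1",
  benzamide = "NC(=O)c1ccccc1",
  ibuprofenLike = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
  piperidinol = "OC1CCN(CC)CC1")

toyFingerprints <- function(nBits = 512L) {
  memo(paste0("toyfp", nBits), circularFingerprint(toySmiles, nBits = nBits))
}

# small labeled PCM matrix on the small dataset
smallMatrix <- function() {
  memo("small_fm", {
    ds <- smallDataset()
    m <- smallMerged()
    assembleMatrix(m$compounds, m$activities, ds$panel,
                   scheme = LabelingScheme(8.5, 70), ligandCache = ligandCache())
  })
}

smallModel <- function() {
  memo("small_model", trainEnsemble(smallMatrix(), nTrees = 150L, seed = 1L))
}

# brute-force medoid: the element minimizing summed distance to all others
bruteMedoid <- function(fps) {
  d <- 1 - tanimoto(fps)
  rownames(fps)[which.min(rowSums(d))]
}
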