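test_that("circular fingerprints are deterministic, sparse and class-driven", {
  fp <- toyFingerprints()
  expect_equal(dim(fp), c(length(toySmiles), 512L))
  expect_true(all(fp %in% c(0L, 1L)))
  # determinism
  expect_identical(circularFingerprint(toySmiles["benzene"]),
                   fp["benzene", , drop = FALSE])
  # methane and benzene share no hashed features at 512 bits
  mb <- circularFingerprint(c(methane = "C", benzene = "c1ccccc1"))
  expect_equal(tanimoto(mb)[1, 2], 0)
  # popcount cannot exceed the number of distinct features: a molecule with
  # k atoms over r+1 iterations has at most k*(r+1) features
  natoms <- c(3, 6, 10)
  expect_true(all(rowSums(fp[c("ethanol", "benzene", "naphthalene"), ]) <=
                    natoms * 4))
})

test_that("folding to 512 bits is the mod-512 image of the 2048-bit fingerprint", {
  fp512 <- toyFingerprints(512L)
  fp2048 <- toyFingerprints(2048L)
  for (i in seq_len(nrow(fp512))) {
    folded <- rep(0L, 512)
    folded[unique((which(fp2048[i, ] == 1) - 1L) %% 512L) + 1L] <- 1L
    expect_equal(unname(fp512[i, ]), folded)
  }
})

test_that("physchem block matches elementary counting oracles", {
  pc <- physchemBlock(toySmiles)
  # benzene MW from standard atomic masses: 6*12.011 + 6*1.008
  expect_equal(pc["benzene", "MW"], 6 * 12.011 + 6 * 1.008, tolerance = 0.01)
  expect_equal(unname(pc["ethanol", c("HBD", "HBA", "AromRings", "BridgeB")]),
               c(1, 1, 0, 0))
  expect_equal(unname(pc["naphthalene", c("AromRings", "BridgeB")]), c(2, 1))
  expect_equal(unname(pc["benzene", c("AromRings", "BridgeB", "RotB")]), c(1, 0, 0))
  expect_true(all(pc[, "MW"] > 0))
  counts <- pc[, c("HBA", "HBD", "RotB", "BridgeB", "AromRings")]
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("z-scale descriptors cover both modes and respect conservation", {
  # identical sequences: no variable columns
  p0 <- ProteinPanel(c("A", "B"), c("ACDEF", "ACDEF"))
  expect_length(zscaleDescriptor(p0, "A"), 0)
  # homopolymer mean equals the residue's own z-scales
  zt <- zscaleTable()
  pA <- ProteinPanel("X", paste(rep("W", 10), collapse = ""))
  expect_equal(unname(zscaleDescriptor(pA, "X", mode = "sequence_mean")),
               unlist(zt[zt$aa == "W", c("z1", "z2", "z3")], use.names = FALSE))
  # one differing column: per-position descriptors differ in exactly 3 entries
  p1 <- ProteinPanel(c("A", "B"), c("ACDEFGHIK", "ACDEYGHIK"))
  zA <- zscaleDescriptor(p1, "A")
  zB <- zscaleDescriptor(p1, "B")
  expect_length(zA, 3)
  expect_equal(sum(zA != zB), 3)
  # gaps ignored in sequence_mean: inserting a gap leaves the mean unchanged
  p2 <- ProteinPanel(c("A", "B"), c("ACD-EF", "ACDWEF"))
  p3 <- ProteinPanel(c("A", "B"), c("ACDEF", "ACDEF"))
  expect_equal(unname(zscaleDescriptor(p2, "A", mode = "sequence_mean")),
               unname(zscaleDescriptor(p3, "A", mode = "sequence_mean")))
  # gap in a variable column encodes as zeros
  expect_equal(unname(zscaleDescriptor(p2, "A"))[1:3], c(0, 0, 0))
  # unknown residue symbols are flagged with their position
  pBad <- ProteinPanel("A", "ACXEF")
  expect_error(zscaleDescriptor(pBad, "A"), "column 3")
})

test_that("assembled matrices respect block structure and row order", {
  comps <- CompoundSet(c("c1", "c2"), c("CCO", "c1ccccc1"))
  panel <- ProteinPanel(c("T1", "T2"), c("ACDEF", "ACDYF"))
  acts <- ActivitySet(c("c1", "c1", "c2", "c2"), c("T1", "T2", "T1", "T2"),
                      "pchembl", "Ki", c(9, 5, 9, 5), 9L)
  fm <- assembleMatrix(comps, acts, panel, scheme = LabelingScheme(8.5, 70))
  expect_equal(nrow(featureMatrix(fm)), 4)
  # ligand block identical for the same compound across targets
  lig <- featureMatrix(fm)[, fm@ligandCols]
  expect_equal(unname(lig[1, ]), unname(lig[2, ]))
  # protein block identical for the same target across compounds
  prot <- featureMatrix(fm)[, fm@proteinCols, drop = FALSE]
  expect_equal(unname(prot[1, ]), unname(prot[3, ]))
  expect_false(isTRUE(all.equal(unname(prot[1, ]), unname(prot[2, ]))))
  expect_equal(as.character(rowLabels(fm)), c("active", "inactive") [c(1, 2, 1, 2)])
  # QSAR mode: no protein block, 512 + 7 columns
  fq <- assembleMatrix(comps, acts, panel = NULL)
  expect_equal(ncol(featureMatrix(fq)), 519)
  expect_length(fq@proteinCols, 0)
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  fmP <- assembleMatrix(comps, acts[perm], panel,
                        scheme = LabelingScheme(8.5, 70))
  expect_equal(featureMatrix(fmP), featureMatrix(fm)[perm, ])
  expect_equal(pairInfo(fmP)$compound_id, pairInfo(fm)$compound_id[perm])
  # unresolvable references are reported
  actsBad <- ActivitySet("ghost", "T1", "pchembl", "Ki", 7, 9L)
  expect_error(assembleMatrix(comps, actsBad, panel), "ghost")
})

test_that("feature matrices round-trip through CSV", {
  fm <- assembleMatrix(CompoundSet(c("c1", "c2"), c("CCO", "CCN")),
                       ActivitySet(c("c1", "c2"), "T1", "percent_control",
                                   "percent", c(40, 90)),
                       panel = NULL, scheme = LabelingScheme(8.5, 70))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureMatrix(fm, f)
  fm2 <- readFeatureMatrix(f)
  expect_equal(featureMatrix(fm2), featureMatrix(fm), tolerance = 1e-9)
  expect_equal(pairInfo(fm2), pairInfo(fm))
  expect_equal(rowLabels(fm2), rowLabels(fm))
})
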