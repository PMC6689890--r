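test_that("library scoring returns bounded probabilities and handles edge cases", {
  ds <- smallDataset()
  model <- smallModel()
  scored <- scoreLibrary(model, ds$library, ds$panel, "SGLT1_hs")
  expect_equal(nrow(scored), length(ds$library))
  expect_true(all(scored$probability >= 0 & scored$probability <= 1))
  expect_true(all(scored$MW > 0))
  # an empty library scores to an empty frame
  empty <- CompoundSet(character(0), character(0), "library")
  expect_equal(nrow(scoreLibrary(model, empty, ds$panel, "SGLT1_hs")), 0)
  # a training active scores >= 0.5 (overfit-forest property)
  fm <- smallMatrix()
  lab <- rowLabels(fm)
  ad <- pairInfo(fm)
  actRow <- which(lab == "active" & ad$target_id == "SGLT1_hs")[1]
  cd <- compoundData(smallMerged()$compounds)
  one <- CompoundSet(ad$compound_id[actRow],
                     cd$smiles[match(ad$compound_id[actRow], cd$compound_id)],
                     "library")
  s1 <- scoreLibrary(model, one, ds$panel, "SGLT1_hs")
  expect_gte(s1$probability, 0.5)
})

test_that("the pre-filter applies exact boundary semantics", {
  toy <- data.frame(
    compound_id = sprintf("t%02d", 1:6),
    probability = c(0.85, 0.85, 0.79, 0.80, 1.00, 0.50),
    MW = c(310, 300, 400, 300.1, 299.9, 500))
  surv <- prefilter(toy, pCut = 0.8, mwCut = 300)
  # p >= 0.8 AND MW > 300 (MW exactly 300 removed; p exactly 0.8 kept)
  expect_setequal(surv, c("t01", "t04"))
  # monotone in the probability cutoff
  expect_true(all(prefilter(toy, pCut = 0.8) %in% prefilter(toy, pCut = 0.5)))
})

test_that("diverse selection picks medoids, k=1 matching brute force", {
  fp <- toyFingerprints()
  # k >= n returns everything
  expect_setequal(selectDiverse(fp[1:5, ], k = 40), rownames(fp)[1:5])
  # k = 1 equals the brute-force medoid on up to 12 compounds
  expect_equal(selectDiverse(fp, k = 1, seed = 3), bruteMedoid(fp))
  for (sub in list(1:5, 3:10, c(1, 4, 6, 9, 11, 12))) {
    expect_equal(selectDiverse(fp[sub, , drop = FALSE], k = 1),
                 bruteMedoid(fp[sub, , drop = FALSE]))
  }
  # two tight chemotype islands, k = 2: one medoid per island
  island1 <- c("CCCCCCCC", "CCCCCCC", "CCCCCCCCC", "CCCCCCCCCC")
  island2 <- c("Oc1ccc(O)cc1O", "Oc1ccc(O)cc1", "Oc1cc(O)cc(O)c1", "Oc1ccccc1O")
  fps <- circularFingerprint(setNames(c(island1, island2), paste0("m", 1:8)))
  med <- selectDiverse(fps, k = 2, seed = 1)
  expect_length(med, 2)
  expect_length(intersect(med, paste0("m", 1:4)), 1)
  expect_length(intersect(med, paste0("m", 5:8)), 1)
})

test_that("diverse picks are deterministic and more spread than random picks", {
  ds <- smallDataset()
  cd <- compoundData(ds$library)
  fps <- circularFingerprint(setNames(cd$smiles, cd$compound_id))
  p1 <- selectDiverse(fps, k = 8, seed = 4)
  p2 <- selectDiverse(fps, k = 8, seed = 4)
  expect_identical(p1, p2)
  meanSim <- function(ids) {
    s <- tanimoto(fps[ids, ])
    mean(s[upper.tri(s)])
  }
  divSim <- meanSim(p1)
  randSim <- vapply(1:10, function(s) {
    set.seed(s)
    meanSim(sample(rownames(fps), 8))
  }, 0)
  expect_lte(divSim, mean(randSim))
})

test_that("analog ranking is by descending similarity with lexicographic ties", {
  fp <- toyFingerprints()
  # a reference present among survivors ranks itself first at similarity 1
  ranked <- selectAnalogs(fp["phenol", ], fp, n = 4)
  expect_equal(names(ranked)[1], "phenol")
  expect_equal(unname(ranked[1]), 1)
  expect_true(all(diff(ranked) <= 0))
  # requesting more analogs than survivors returns all with a warning
  expect_warning(all9 <- selectAnalogs(fp["phenol", ], fp[1:3, ], n = 99),
                 "survivors")
  expect_length(all9, 3)
  # dissimilar survivors still yield a full ranking
  far <- circularFingerprint(c(a = "CCCCCCCCCC", b = "CCCCCCCCC"))
  rankedFar <- selectAnalogs(fp["phenol", ], far, n = 2)
  expect_length(rankedFar, 2)
})

test_that("the combined selection keeps pick lists disjoint", {
  ds <- smallDataset()
  model <- smallModel()
  cd <- compoundData(ds$library)
  refs <- CompoundSet(c("ref1", "ref2"), cd$smiles[1:2])
  rep <- selectCompounds(model, ds$library, ds$panel, "SGLT1_hs",
                         references = refs, nAnalogs = 3L,
                         pCut = 0.2, mwCut = 150, kDiverse = 6L, seed = 2L)
  expect_s4_class(rep, "SelectionReport")
  allPicks <- c(diversePicks(rep), unlist(analogPicks(rep)))
  expect_equal(anyDuplicated(allPicks), 0)
  tab <- selectionTable(rep)
  surv <- tab$compound_id[tab$passed_p80 & tab$passed_mw]
  expect_true(all(diversePicks(rep) %in% surv))
  expect_true(all(unlist(analogPicks(rep)) %in% surv))
})
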