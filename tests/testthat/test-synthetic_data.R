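test_that("panel generation respects the mutation model", {
  cfg <- generatorConfig(seed = 31L, panel_size = 6L, sequence_length = 600L,
                         mutation_rate = 0.05)
  p1 <- generatePanel(cfg)
  p2 <- generatePanel(cfg)
  expect_identical(as.character(alignment(p1)), as.character(alignment(p2)))
  expect_equal(length(p1), 6)
  expect_equal(unique(Biostrings::width(alignment(p1))), 600)
  # zero mutation rate: all sequences identical
  p0 <- generatePanel(generatorConfig(seed = 31L, mutation_rate = 0))
  expect_equal(length(unique(as.character(alignment(p0)))), 1)
  # binomial oracle: observed root-to-member differences within 3 sd of
  # n * mu * (1 - 1/20)  (a drawn substitution is silent with prob 1/20)
  seqs <- as.matrix(alignment(p1))
  root <- seqs[1, ]
  diffs <- vapply(2:6, function(i) sum(seqs[i, ] != root), 0L)
  pEff <- 0.05 * (1 - 1 / 20)
  expected <- 600 * pEff
  sdBin <- sqrt(600 * pEff * (1 - pEff))
  expect_true(all(abs(diffs - expected) <= 3 * sdBin))
})

test_that("generated compounds are valid, standardized, and style-separated", {
  ds <- smallDataset()
  for (cs in list(ds$public$compounds, ds$inhouse$compounds, ds$library)) {
    smi <- compoundData(cs)$smiles
    # emitted SMILES survive standardization unchanged
    expect_equal(unname(standardizeStructure(smi)), smi)
  }
  # reproducibility
  cfg <- generatorConfig(seed = 11L, n_public_compounds = 60L,
                         n_inhouse_compounds = 150L, n_library = 100L)
  again <- generateCompounds(cfg, "glycoside_like", idPrefix = "PUB",
                             source = "public", seedOffset = 0L)
  expect_identical(compoundData(again), compoundData(ds$public$compounds))
})

test_that("glycoside-like compounds are HBD-richer than diverse ones", {
  for (s in c(41L, 42L)) {
    cfg <- generatorConfig(seed = s, n_public_compounds = 60L,
                           n_inhouse_compounds = 60L)
    gly <- generateCompounds(cfg, "glycoside_like", n = 60L)
    div <- generateCompounds(cfg, "diverse", n = 60L, seedOffset = 3L)
    hbd <- function(cs) mean(physchemBlock(compoundData(cs)$smiles)[, "HBD"])
    expect_gt(hbd(gly), hbd(div))
  }
})

test_that("activity assignment is deterministic and plants the rule signal", {
  ds <- smallDataset()
  cfg <- ds$config
  a2 <- assignActivities(ds$inhouse$compounds, ds$panel, cfg,
                         "percent_control", "primary_pair", seedOffset = 7L)
  expect_equal(activityData(a2), activityData(ds$inhouse$activities))
  ad <- activityData(ds$inhouse$activities)
  expect_true(all(ad$value >= cfg$percent_floor & ad$value <= cfg$percent_ceiling))
  # matchers of the dominant rule are strongly enriched among label-actives
  m <- attr(ds$inhouse$activities, "matches")
  mi <- m[match(ad$compound_id, compoundIds(ds$inhouse$compounds)), "diverse"]
  lab <- binarize(ad$value, "percent_control", LabelingScheme(8.5, 70))
  enrichment <- mean(mi[lab == "active"]) / mean(mi)
  expect_gte(enrichment, 5)
  # noise-free assignment is a deterministic map of the rule matches
  cfg0 <- generatorConfig(seed = 11L, noise_sd = 0)
  a0 <- assignActivities(ds$inhouse$compounds, ds$panel, cfg0,
                         "percent_control", "primary_pair")
  d0 <- activityData(a0)
  m0 <- attr(a0, "matches")
  none <- !m0[match(d0$compound_id, compoundIds(ds$inhouse$compounds)), "diverse"] &
    !m0[match(d0$compound_id, compoundIds(ds$inhouse$compounds)), "glycoside"]
  baselinePct <- pmin(pmax(100 - 100 * plogis((cfg0$baseline +
    pcmscreen:::.targetModifiers(ds$panel, cfg0)[d0$target_id] -
    cfg0$percent_g_mid) / cfg0$percent_g_scale), cfg0$percent_floor),
    cfg0$percent_ceiling)
  expect_equal(d0$value[none], unname(baselinePct[none]), tolerance = 1e-9)
})

test_that("public records carry the pchembl dialect contract", {
  ds <- smallDataset()
  pd <- activityData(ds$public$activities)
  expect_true(all(pd$dialect == "pchembl"))
  expect_true(all(pd$value >= 4 & pd$value <= 10))
  expect_true(all(pd$confidence %in% c(7L, 9L)))
  expect_true(all(pd$activity_type %in% c("Ki", "IC50")))
  # two records per compound on distinct targets
  byC <- split(pd$target_id, pd$compound_id)
  expect_true(all(lengths(byC) == 2))
  expect_true(all(vapply(byC, function(t) length(unique(t)) == 2, TRUE)))
})

test_that("the planted percent threshold is where class densities cross", {
  cfg <- generatorConfig(seed = 1L)
  t0 <- plantedPercentThreshold(cfg, matchedFraction = 0.5)
  # with equal priors the crossing is midway between the class means
  lmid <- cfg$baseline + cfg$pharmacophore_rules$diverse$contribution / 2
  expect_equal(t0, 100 - 100 * plogis((lmid - cfg$percent_g_mid) /
                                        cfg$percent_g_scale))
  # rarer actives push the boundary toward the active (low-percent) side
  expect_lt(plantedPercentThreshold(cfg, matchedFraction = 0.1), t0)
})
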