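test_that("training is reproducible and fits separable data perfectly", {
  set.seed(2)
  x <- cbind(matrix(rnorm(20 * 5), 20), sig = rep(c(0, 3), each = 10))
  colnames(x) <- paste0("f", 1:6)
  fm <- new("PCMFeatureMatrix", features = x,
            pairs = data.frame(compound_id = paste0("c", 1:20), target_id = "T1"),
            labels = factor(rep(c("inactive", "active"), each = 10),
                            levels = c("inactive", "active")),
            ligandCols = 1:6, proteinCols = integer(0))
  m1 <- trainEnsemble(fm, nTrees = 100L, seed = 7L)
  m2 <- trainEnsemble(fm, nTrees = 100L, seed = 7L)
  expect_equal(predictProba(m1, fm), predictProba(m2, fm))
  pred <- factor(ifelse(predictProba(m1, fm) >= 0.5, "active", "inactive"),
                 levels = c("inactive", "active"))
  expect_equal(confusionMetrics(rowLabels(fm), pred)$mcc, 1)
  # an overfit forest assigns its own training rows to their class
  expect_true(all((predictProba(m1, fm) >= 0.5) == (rowLabels(fm) == "active")))
  # empty prediction input
  expect_length(predictProba(m1, fm[integer(0)]), 0)
  # manifest records the hyperparameters
  expect_equal(manifest(m1)$n_trees, 100L)
  expect_equal(manifest(m1)$mtry, floor(sqrt(6)))
})

test_that("mtry defaults to the floored square root of the column count", {
  set.seed(3)
  x <- matrix(rnorm(40 * 522), 40)
  colnames(x) <- paste0("f", 1:522)
  fm <- new("PCMFeatureMatrix", features = x,
            pairs = data.frame(compound_id = paste0("c", 1:40), target_id = "T"),
            labels = factor(rep(c("inactive", "active"), 20),
                            levels = c("inactive", "active")),
            ligandCols = 1:522, proteinCols = integer(0))
  m <- trainEnsemble(fm, nTrees = 30L, seed = 1L)
  expect_equal(mtry(m), 22L)       # floor(sqrt(522))
  expect_equal(nTrees(m), 30L)
  # override is honored
  expect_equal(mtry(trainEnsemble(fm, nTrees = 30L, mtry = 38L, seed = 1L)), 38L)
  # single-class training is an error
  fm@labels <- factor(rep("active", 40), levels = c("inactive", "active"))
  expect_error(trainEnsemble(fm, nTrees = 30L), "single class")
})

test_that("column mismatches are reported by name", {
  fm <- smallMatrix()
  model <- smallModel()
  broken <- fm[1:3]
  colnames(broken@features)[1] <- "WRONG"
  expect_error(predictProba(model, broken), "WRONG")
})

test_that("confusion metrics follow their definitions including zero conventions", {
  t0 <- factor(c("active", "active", "inactive", "inactive"),
               levels = c("inactive", "active"))
  p0 <- factor(c("active", "inactive", "inactive", "active"),
               levels = c("inactive", "active"))
  m <- confusionMetrics(t0, p0)
  expect_equal(c(m$TP, m$FP, m$TN, m$FN), c(1, 1, 1, 1))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$mcc, 0)
  # all-inactive predictions: zero marginals give MCC 0, not NaN
  allneg <- factor(rep("inactive", 4), levels = c("inactive", "active"))
  m2 <- confusionMetrics(t0, allneg)
  expect_equal(m2$mcc, 0)
  expect_equal(m2$ppv, 0)
  expect_equal(m2$specificity, 1)
})

test_that("the rate-form MCC identity matches counts over all small confusion matrices", {
  # brute-force enumeration of every confusion matrix with total <= 30
  mismatch <- 0
  for (n in 1:30) {
    parts <- expand.grid(tp = 0:n, fp = 0:n, tn = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    parts$fn <- n - rowSums(parts)
    margins <- with(parts, pmin(tp + fp, tp + fn, tn + fp, tn + fn))
    parts <- parts[margins > 0, ]
    if (!nrow(parts)) next
    direct <- with(parts, (tp * tn - fp * fn) /
                     sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
    viaRates <- with(parts, mccFromRates(tp / (tp + fn), tn / (tn + fp),
                                         tp / (tp + fp), tn / (tn + fn)))
    mismatch <- mismatch + sum(abs(direct - viaRates) > 1e-9)
  }
  expect_equal(mismatch, 0)
})

test_that("fold construction partitions the in-house compounds exactly", {
  ids <- sprintf("c%03d", 1:83)
  labels <- factor(rep_len(c("a", "a", "b"), 83))
  folds <- makeFolds(ids, labels, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), ids)
  expect_equal(sum(lengths(folds)), 83)            # pairwise disjoint
  # stratification: every fold contains both labels
  for (f in folds)
    expect_equal(sort(unique(as.character(labels[match(f, ids)]))), c("a", "b"))
})

test_that("validation designs share folds and never leak test compounds", {
  ds <- smallDataset()
  m <- smallMerged()
  scheme <- LabelingScheme(8.5, 70)
  args <- list(compounds = m$compounds, activities = m$activities,
               panel = ds$panel, scheme = scheme, primaryTarget = "SGLT1_hs",
               nTrees = 60L, seed = 5L, ligandCache = ligandCache())
  vC <- do.call(runValidation, c(list(mode = "combined_cv"), args))
  vP <- do.call(runValidation, c(list(mode = "public_only_cv"), args))
  vI <- do.call(runValidation, c(list(mode = "inhouse_only_cv"), args))
  # identical test folds across designs
  expect_equal(vC$folds, vP$folds)
  expect_equal(vC$folds, vI$folds)
  ad <- activityData(m$activities)
  inhIds <- unique(ad$compound_id[ad$dialect == "percent_control" &
                                    ad$target_id == "SGLT1_hs"])
  expect_setequal(unlist(vC$folds), inhIds)
  expect_equal(nrow(vC$perFold), 5)
  expect_true(all(c("sensitivity", "specificity", "ppv", "npv", "mcc") %in%
                    names(vC$perFold)))
  # perfect-oracle sanity: labels learned from themselves are reproduced
  expect_true(all(vC$perFold$TP + vC$perFold$FP + vC$perFold$TN + vC$perFold$FN > 0))
})
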