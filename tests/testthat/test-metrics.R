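test_that("confusion counts name MCN as the positive class", {
  c1 <- confusionCounts(rep(c("MCN", "SCN"), c(3, 2)),
                        rep(c("MCN", "SCN"), c(3, 2)))
  expect_identical(c(c1@trueMcn, c1@falseScn, c1@trueScn, c1@falseMcn),
                   c(3L, 0L, 2L, 0L))
  c2 <- confusionCounts(rep("MCN", 5), rep(c("MCN", "SCN"), c(3, 2)))
  expect_identical(c(c2@trueMcn, c2@falseScn, c2@trueScn, c2@falseMcn),
                   c(3L, 0L, 0L, 2L))
  c3 <- confusionCounts(c("MCN", "SCN", "MCN", "SCN", "SCN"),
                        c("MCN", "MCN", "SCN", "SCN", "MCN"))
  expect_identical(c(c3@trueMcn, c3@falseScn, c3@trueScn, c3@falseMcn),
                   c(1L, 2L, 1L, 1L))
  expect_error(confusionCounts("MCN", c("MCN", "SCN")), "equal length")
})

test_that("sensitivity/specificity/accuracy follow their defining formulas", {
  m <- sensSpecAcc(new("ConfusionCounts", trueMcn = 29L, falseScn = 7L,
                       trueScn = 25L, falseMcn = 8L))
  expect_equal(m[["sensitivity"]], 29 / 36)
  expect_equal(m[["specificity"]], 25 / 33)
  expect_equal(m[["accuracy"]], 54 / 69)
  perfect <- sensSpecAcc(new("ConfusionCounts", trueMcn = 4L, falseScn = 0L,
                             trueScn = 6L, falseMcn = 0L))
  expect_equal(unname(perfect), c(1, 1, 1))
  expect_warning(z <- sensSpecAcc(new("ConfusionCounts", trueMcn = 0L,
                                      falseScn = 0L, trueScn = 3L,
                                      falseMcn = 1L)), "sensitivity")
  expect_true(is.na(z[["sensitivity"]]))
})

test_that("accuracy decomposes as the class-weighted mean of sens and spec", {
  set.seed(40)
  for (i in 1:50) {
    cc <- new("ConfusionCounts", trueMcn = sample(1:30, 1),
              falseScn = sample(1:30, 1), trueScn = sample(1:30, 1),
              falseMcn = sample(1:30, 1))
    m <- sensSpecAcc(cc)
    nM <- cc@trueMcn + cc@falseScn
    nS <- cc@trueScn + cc@falseMcn
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * nM + m[["specificity"]] * nS) /
                   (nM + nS))
  }
})

test_that("threshold-sweep AUC equals the pairwise Mann-Whitney oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c("MCN", "MCN", "SCN", "SCN")),
               1)
  expect_equal(rocAuc(rep(0.4, 6), rep(c("MCN", "SCN"), 3)), 0.5)
  expect_equal(rocAuc(c(0.9, 0.4, 0.5, 0.1),
                      c("MCN", "MCN", "SCN", "SCN")), 0.75)
  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- sample(c("SCN", "MCN"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("SCN", "MCN")
    # coarse grid forces plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_lt(abs(rocAuc(scores, labels) -
                    aucPairwiseOracle(scores, labels)), 1e-12)
  }
  expect_error(rocAuc(runif(4), rep("MCN", 4)), "both classes")
})

test_that("stratified folds reproduce the 33/36 split arithmetic", {
  patients <- sprintf("P%03d", 1:69)
  labels <- rep(c("SCN", "MCN"), c(33, 36))
  fa <- makeFolds(patients, labels, k = 4L, seed = 42L)
  folds <- foldOf(fa, patients)
  sizes <- as.vector(table(folds))
  expect_identical(sort(sizes, decreasing = TRUE), c(18L, 17L, 17L, 17L))
  scnPerFold <- as.vector(table(folds[labels == "SCN"]))
  mcnPerFold <- as.vector(table(folds[labels == "MCN"]))
  expect_identical(sort(scnPerFold, decreasing = TRUE), c(9L, 8L, 8L, 8L))
  expect_identical(mcnPerFold, rep(9L, 4L))
  # partition: disjoint and exhaustive
  expect_identical(sort(names(folds)), sort(patients))
  expect_identical(anyDuplicated(names(folds)), 0L)
  # determinism
  fa2 <- makeFolds(patients, labels, k = 4L, seed = 42L)
  expect_identical(fa@folds, fa2@folds)
  expect_false(identical(makeFolds(patients, labels, 4L, 43L)@folds,
                         fa@folds))
})

test_that("stratification holds within one patient for many cohorts", {
  set.seed(44)
  for (i in 1:12) {
    k <- sample(2:5, 1)
    nS <- sample(k:20, 1); nM <- sample(k:20, 1)
    patients <- sprintf("Q%03d", seq_len(nS + nM))
    labels <- sample(rep(c("SCN", "MCN"), c(nS, nM)))
    fa <- makeFolds(patients, labels, k = k, seed = i)
    folds <- foldOf(fa, patients)
    for (cl in c("SCN", "MCN")) {
      perFold <- tabulate(folds[labels == cl] + 1L, k)
      expect_lte(max(perFold) - min(perFold), 1L)
    }
    sizes <- tabulate(folds + 1L, k)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_error(makeFolds(c("a", "b"), c("SCN", "MCN"), k = 2L), "at least k")
  expect_error(makeFolds(c("a", "a"), c("SCN", "SCN"), k = 2L), "unique")
})

test_that("fold aggregation reports mean, sd and range", {
  pf <- data.frame(fold = 0:3, auc = c(0.8, 0.9, 0.7, 0.8))
  rep1 <- aggregateFolds(pf)
  s <- rep1@summary
  expect_equal(s$mean, 0.8)
  expect_equal(s$sd, sd(c(0.8, 0.9, 0.7, 0.8)))
  expect_equal(s$min, 0.7)
  expect_equal(s$max, 0.9)
  # single fold: sd rendered 0, min = max = mean
  one <- aggregateFolds(data.frame(fold = 0, auc = 0.75))@summary
  expect_equal(c(one$mean, one$sd, one$min, one$max), c(0.75, 0, 0.75, 0.75))
  # permutation invariance
  perm <- aggregateFolds(pf[c(3, 1, 4, 2), ])@summary
  expect_equal(perm, s)
  # NA folds excluded with a warning
  expect_warning(agg <- aggregateFolds(
    data.frame(fold = 0:2, auc = c(0.8, NA, 0.6))), "excluded")
  expect_equal(agg@summary$mean, 0.7)
  expect_match(formatMetricReport(rep1)[["auc"]], "0.80")
})

test_that("cohort summary reproduces the 9/24 and 8/28 sex ratios", {
  tab <- data.frame(
    label = rep(c("SCN", "MCN"), c(33, 36)),
    sex = c(rep(c("M", "F"), c(9, 24)), rep(c("M", "F"), c(8, 28))))
  s <- cohortSummary(tab)$perClass
  expect_equal(s$male_to_female[s$label == "SCN"], 0.38)
  expect_equal(s$male_to_female[s$label == "MCN"], 0.29)
  # equal counts give ratio 1.00
  eq <- data.frame(label = rep(c("SCN", "MCN"), each = 4),
                   sex = rep(c("M", "F"), 4))
  expect_equal(cohortSummary(eq)$perClass$male_to_female, c(1, 1))
})

test_that("cohort summary runs the flagged default tests", {
  set.seed(45)
  tab <- data.frame(
    label = rep(c("SCN", "MCN"), c(33, 36)),
    sex = c(rep(c("M", "F"), c(9, 24)), rep(c("M", "F"), c(8, 28))),
    age = c(rnorm(33, 53, 10), rnorm(36, 50, 14)),
    tumor_size = c(rlnorm(33, 1, 0.4), rlnorm(36, 1.1, 0.4)))
  s <- cohortSummary(tab)
  expect_identical(s$tests$variable, c("age", "sex", "tumor_size"))
  expect_true(all(s$tests$p_value >= 0 & s$tests$p_value <= 1))
  expect_match(s$tests$test[1], "Welch")
  expect_match(s$tests$test[2], "continuity")
  expect_match(s$tests$test[3], "Mann-Whitney")
  expect_equal(s$perClass$age_mean[1], mean(tab$age[tab$label == "SCN"]))
  expect_error(cohortSummary(data.frame(x = 1)), "label")
})
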