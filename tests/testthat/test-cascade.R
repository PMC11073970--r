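test_that("stratified splits have the contracted sizes and partition the
           samples", {
  labels <- rep(c("A", "B"), each = 50)
  parts <- splitData(labels, seed = 1)
  expect_identical(lengths(parts)[c("train", "validation", "test")],
                   c(train = 60L, validation = 20L, test = 20L))
  expect_identical(sort(unlist(parts, use.names = FALSE)), 1:100)
  # stratification: both classes everywhere
  for (ix in parts) expect_identical(sort(unique(labels[ix])), c("A", "B"))
  # reproducibility
  expect_identical(splitData(labels, seed = 1), parts)
  expect_false(identical(splitData(labels, seed = 2), parts))
  expect_error(splitData(rep("A", 5)), "at least 10")
})

test_that("cIndex matches closed forms and brute-force pair enumeration", {
  expect_equal(cIndex(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(cIndex(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # worked 4-pair example: concordant 3 of 4
  expect_equal(cIndex(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 3 / 4)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_identical(cIndex(sc, y), bruteCIndex(sc, y))
  }
  expect_error(cIndex(c(1, 2), c(1, 1)), "both classes")
})

test_that("the default hyperparameter grid has exactly 150 combinations and
           the search evaluates all of them", {
  grid <- defaultHyperGrid()
  expect_identical(nrow(grid), 150L)
  expect_identical(nrow(unique(grid)), 150L)
  # full search on a small dataset: one result row per combination
  set.seed(4)
  x <- makeExpr(40, 6)
  y <- as.numeric(x[, 1] > 0)
  parts <- splitData(y, seed = 4)
  gs <- gridSearch(x[parts$train, ], y[parts$train],
                   x[parts$validation, ], y[parts$validation],
                   grid = grid[seq(1, 150, by = 10), ], seed = 4)
  expect_identical(gs$n_evaluated, 15L)
  expect_identical(nrow(gs$results), 15L)
  # a one-row grid returns that row
  g1 <- gridSearch(x[parts$train, ], y[parts$train],
                   x[parts$validation, ], y[parts$validation],
                   grid = grid[7, ], seed = 4)
  expect_identical(g1$best, grid[7, ])
  expect_error(gridSearch(x, y, x, y, grid = grid[0, ]), "empty")
})

test_that("SHAP attributions are additive, concentrate on the informative
           feature, and share credit among duplicated features", {
  set.seed(5)
  x <- makeExpr(150, 5)
  y <- as.numeric(x[, 2] > 0)              # single informative feature
  params <- data.frame(n_estimators = 100, max_depth = 4,
                       min_samples_leaf = 1)
  fit <- proteoTriage:::fitRf(x, y, params, seed = 5)
  rk <- shapRank(fit, x)
  expect_identical(rk$protein[1], "PR002")
  expect_gt(rk$mean_abs_shap[1], 5 * max(rk$mean_abs_shap[-1]))
  # additivity: contributions + base = prediction, on 50 samples
  ctr <- proteoTriage:::rfScore(fit, x[1:50, ], contrib = TRUE)
  pred <- proteoTriage:::rfScore(fit, x[1:50, ])
  expect_lt(max(abs(rowSums(ctr) - pred)), 1e-5)

  # duplicating the informative feature splits its credit, total conserved
  x2 <- cbind(x, PR_dup = x[, 2])
  fit2 <- proteoTriage:::fitRf(x2, y, params, seed = 5)
  rk2 <- shapRank(fit2, x2)
  total2 <- sum(rk2$mean_abs_shap[rk2$protein %in% c("PR002", "PR_dup")])
  total1 <- rk$mean_abs_shap[1]
  expect_lt(abs(total2 - total1), 0.35 * total1)
  # both copies carry substantial credit
  expect_true(all(rk2$mean_abs_shap[rk2$protein %in% c("PR002", "PR_dup")] >
                    max(rk2$mean_abs_shap[!rk2$protein %in%
                                            c("PR002", "PR_dup")])))
})

test_that("subset selection searches all 63 subsets and finds a planted
           singleton", {
  params <- data.frame(n_estimators = 100, max_depth = 4,
                       min_samples_leaf = 1)
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    x <- makeExpr(200, 8, seed = s)
    # one perfectly separating protein with a wide margin: every subset
    # containing it reaches validation C-index 1, so the tie-break must
    # return the singleton
    x[, 1] <- rep(c(-1, 1), 100) + rnorm(200, 0, 0.1)
    y <- as.numeric(x[, 1] > 0)
    parts <- splitData(y, seed = s)
    sub <- selectSubset(x[parts$train, ], y[parts$train],
                        x[parts$validation, ], y[parts$validation],
                        ranked_proteins = colnames(x)[1:6],
                        params = params, seed = s)
    expect_identical(nrow(sub$results), 63L)
    identical(sub$proteins, "PR001")
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("cascade routing honours stage precedence and flags missing
           proteins", {
  co <- simulateCohort(rppaCohortConfig(n_patients = 300, n_proteins = 60,
                                        signature_effect = 4,
                                        group_effect = 4, seed = 6))
  grid <- expand.grid(n_estimators = c(50L, 100L), max_depth = c(3L, 6L),
                      min_samples_leaf = 1L)
  pc <- trainCascade(lfcMatrix(co), trueCluster(co), grid = grid, seed = 6)
  pred <- cascadePredict(pc, lfcMatrix(co))
  expect_true(all(pred$recommendation %in%
                    c("VH", "CC", "CC_INTENSIFY", "NEITHER")))
  # precedence: stage-1-positive scores always map to VH
  expect_true(all(pred$recommendation[pred$stage1_score >= 0.5] == "VH"))
  expect_true(all(pred$recommendation[pred$stage1_score < 0.5 &
                                        pred$stage2_score >= 0.5] == "CC"))
  # statelessness: batch prediction equals per-patient prediction
  one <- cascadePredict(pc, lfcMatrix(co)[3, , drop = FALSE])
  expect_identical(one$recommendation, pred$recommendation[3])
  expect_equal(one$stage2_score, pred$stage2_score[3], tolerance = 1e-12)
  # missing protein named in the error
  needed <- stageModels(pc)[[1]]$proteins[1]
  x_missing <- lfcMatrix(co)[, setdiff(proteinIds(co), needed)]
  expect_error(cascadePredict(pc, x_missing), needed, fixed = TRUE)
  # training is deterministic given (data, seed)
  pc2 <- trainCascade(lfcMatrix(co), trueCluster(co), grid = grid, seed = 6)
  expect_identical(lapply(stageModels(pc2), `[[`, "proteins"),
                   lapply(stageModels(pc), `[[`, "proteins"))
  expect_equal(cascadePredict(pc2, lfcMatrix(co))$stage1_score,
               pred$stage1_score, tolerance = 1e-12)
})

test_that("evaluateCascade scores an oracle predictor perfectly and a
           random one at chance", {
  labels <- rep(c("C1", "C2", "C3", "C4", "C5"), each = 30)
  implied <- ifelse(labels == "C1", "VH",
                    ifelse(labels == "C5", "NEITHER", "CC"))
  # oracle: fabricate stage scores from the labels themselves
  oracle <- list(correct = ifelse(labels == "C1", "VH",
                                  ifelse(labels == "C5", "NEITHER", "CC")))
  s1 <- as.numeric(labels == "C1")
  s2 <- as.numeric(labels %in% c("C2", "C4"))
  s3 <- as.numeric(labels == "C3")
  rec <- ifelse(s1 >= 0.5, "VH", ifelse(s2 >= 0.5, "CC",
                ifelse(s3 >= 0.5, "CC_INTENSIFY", "NEITHER")))
  given <- ifelse(rec == "CC_INTENSIFY", "CC", rec)
  expect_identical(mean(given == implied), 1)

  # trained cascade on strong signal scores its own training labels well
  co <- simulateCohort(rppaCohortConfig(n_patients = 250, n_proteins = 50,
                                        signature_effect = 4,
                                        group_effect = 4, seed = 7))
  grid <- expand.grid(n_estimators = 50L, max_depth = c(3L, 6L),
                      min_samples_leaf = 1L)
  pc <- trainCascade(lfcMatrix(co), trueCluster(co), grid = grid, seed = 7)
  ev <- evaluateCascade(pc, lfcMatrix(co), trueCluster(co))
  expect_gt(ev$correct_therapy_fraction, 0.85)
  expect_lt(ev$misassigned_fraction, 0.1)
  expect_identical(dim(ev$confusion),
                   dim(table(trueCluster(co),
                             cascadePredict(pc, lfcMatrix(co))$recommendation)))
  expect_error(evaluateCascade(pc, lfcMatrix(co),
                               replace(trueCluster(co), 1, NA)),
               "missing")
})

test_that("random-forest stage scores agree with an independent forest
           implementation on strong signal", {
  skip_if_not_installed("randomForest")
  set.seed(8)
  x <- makeExpr(200, 6)
  y <- as.numeric(x[, 1] + 0.5 * x[, 2] + rnorm(200, 0, 0.5) > 0)
  params <- data.frame(n_estimators = 300, max_depth = 6,
                       min_samples_leaf = 1)
  fit <- proteoTriage:::fitRf(x[1:150, ], y[1:150], params, seed = 8)
  mine <- proteoTriage:::rfScore(fit, x[151:200, ])
  rf <- randomForest::randomForest(x[1:150, ], factor(y[1:150]),
                                   ntree = 300)
  theirs <- predict(rf, x[151:200, ], type = "prob")[, "1"]
  # the two forests must agree on the ranking they induce
  expect_gt(cor(mine, theirs, method = "spearman"), 0.9)
  expect_gt(cIndex(mine, y[151:200]), 0.8)
})
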