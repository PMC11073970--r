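test_that("arm contrasts reproduce the canonical verdicts", {
  set.seed(1)
  mkArm <- function(med_vh, med_cc, n = 400) {
    makeClin(c(rexp(n / 2, log(2) / med_vh), rexp(n / 2, log(2) / med_cc)),
             rep(1, n), rep(c("VH", "CC"), each = n / 2))
  }
  # VH-favoring cluster (median 68.5 vs 19.4)
  ct <- armContrast(mkArm(68.5, 19.4))
  expect_identical(ct$preferred_arm, "VH")
  expect_gt(ct$margin, 0)
  expect_false(ct$neither)

  # poor under both arms (2.9 / 8.6, threshold 12)
  ct2 <- armContrast(mkArm(2.9, 8.6))
  expect_identical(ct2$preferred_arm, "CC")
  expect_true(ct2$neither)

  # identical arms: undetermined with margin 0
  tt <- rep(c(1, 2, 3, 4), 2)
  ct3 <- armContrast(makeClin(tt, rep(1, 8),
                              rep(c("VH", "CC"), each = 4)))
  expect_identical(ct3$preferred_arm, "UNDETERMINED")
  expect_identical(ct3$margin, 0)

  # single-arm cluster: undetermined
  ct4 <- armContrast(makeClin(1:5, rep(1, 5), rep("CC", 5)))
  expect_identical(ct4$preferred_arm, "UNDETERMINED")

  expect_error(
    armContrast(data.frame(os_months = numeric(), os_event = numeric(),
                           arm = character())),
    "empty cluster")
})

test_that("arm contrast is invariant to patient order", {
  set.seed(2)
  clin <- makeClin(rexp(60, 0.05), rbinom(60, 1, 0.8),
                   sample(c("VH", "CC"), 60, replace = TRUE))
  perm <- clin[sample(60), ]
  a <- armContrast(clin); b <- armContrast(perm)
  expect_identical(a$preferred_arm, b$preferred_arm)
  expect_equal(a$margin, b$margin)
  expect_equal(a$arms$VH$median, b$arms$VH$median)
})

test_that("cluster outcome summaries cover every cluster-arm cell", {
  set.seed(3)
  clin <- makeClin(rexp(80, 0.03), rbinom(80, 1, 0.9),
                   rep(c("VH", "CC"), 40),
                   crd = rexp(80, 0.05), crd_ev = rbinom(80, 1, 0.8))
  lab <- rep(c("A", "B"), each = 40)
  summ <- clusterOutcomeSummary(lab, clin)
  expect_identical(nrow(summ), 4L)
  expect_identical(sum(summ$n), 80L)
  expect_true(all(c("median_os", "s60", "median_crd") %in% colnames(summ)))
})

test_that("a single selector candidate is returned as the winner", {
  co <- simulateCohort(flatConfig(2, 120, 30, effect = 3, seed = 4))
  sel <- buildSelector(co, k = 2L, name = "PS", alphas = 0.05,
                       top_n = Inf, n_iterations = 5, seed = 4)
  expect_s4_class(sel, "SelectorSet")
  expect_identical(nrow(sel@candidates), 1L)
  expect_identical(sel@name, "PS")
  expect_true(all(selectorProteins(sel) %in% proteinIds(co)))
  expect_identical(sort(unique(clusterAssignments(sel@clustering))), 1:2)
})

test_that("an informative protein set beats a pure-noise set", {
  wins <- vapply(1:5, function(s) {
    # two planted clusters with opposite treatment benefit
    cfg <- rppaCohortConfig(n_patients = 150, n_proteins = 40,
                            cluster_props = c(0.5, 0.5),
                            signature_effect = 3, group_effect = 0,
                            median_os_months = matrix(c(60, 15, 8, 40),
                                                      2, 2, byrow = TRUE),
                            median_crd_months = matrix(20, 2, 2),
                            seed = s)
    co <- simulateCohort(cfg)
    tab <- screenPrognostic(co)
    informative <- selectPrognostic(tab, 0.05)
    if (length(informative) < 2) return(NA)
    # noise set: the least prognostic proteins
    noise <- utils::tail(tab$protein[order(tab$min_p)], 10)
    expr <- lfcMatrix(co)
    cd <- clinicalTable(co)
    score <- function(ps) {
      lab <- baseCluster(zscoreColumns(expr[, ps, drop = FALSE]), 2,
                         seed = s)
      min(vapply(1:2, function(g) {
        sel <- lab == g
        if (length(unique(cd$arm[sel])) < 2) return(0)
        logrankTest(cd$os_months[sel], cd$os_event[sel],
                    cd$arm[sel])$statistic
      }, numeric(1)))
    }
    score(informative) > score(noise)
  }, logical(1))
  expect_gte(sum(wins, na.rm = TRUE), 4L)
})

test_that("the sequential pipeline partitions the cohort deterministically",
{
  co <- simulateCohort(rppaCohortConfig(n_patients = 419, seed = 31))
  tri <- suppressMessages(runSequential(co, n_iterations = 5, seed = 31))
  lab <- finalClusters(tri)
  # partition: every patient exactly one label
  expect_identical(sort(names(lab)), sort(patientIds(co)))
  expect_true(all(lab %in% names(recommendationMap(tri))))
  expect_identical(length(selectorSets(tri)), 3L)
  # determinism
  tri2 <- suppressMessages(runSequential(co, n_iterations = 5, seed = 31))
  expect_identical(finalClusters(tri2), lab)
  expect_identical(recommendationMap(tri2), recommendationMap(tri))
  # provenance recorded for every final cluster
  expect_true(all(tri@provenance %in% c("PS1", "PS2", "PS3")))
})

test_that("a cohort favouring CC everywhere yields no VH recommendation", {
  med <- matrix(c(5, 40, 6, 50, 7, 45, 5.5, 35, 6.5, 55),
                nrow = 5, byrow = TRUE,
                dimnames = list(paste0("C", 1:5), c("VH", "CC")))
  cfg <- rppaCohortConfig(n_patients = 419, median_os_months = med,
                          median_crd_months = med, seed = 32)
  co <- simulateCohort(cfg)
  msgs <- capture_messages(tri <- runSequential(co, n_iterations = 5,
                                                seed = 32))
  expect_true(any(grepl("no PS1 group prefers VH|no final cluster is VH",
                        msgs)))
  expect_false("VH" %in% recommendationMap(tri))
})

test_that("the treatment filter drops flagged patients after PS1", {
  co <- simulateCohort(rppaCohortConfig(n_patients = 419, seed = 33))
  clin <- clinicalTable(co)
  clin$vh_plus_arac <- FALSE
  vh_ids <- clin$patient_id[clin$arm == "VH"][1:5]
  clin$vh_plus_arac[clin$patient_id %in% vh_ids] <- TRUE
  co2 <- RppaCohort(lfcMatrix(co), clin)
  tri <- suppressMessages(runSequential(co2, n_iterations = 5, seed = 33))
  expect_identical(sort(tri@dropped), sort(vh_ids))
  expect_false(any(vh_ids %in% names(finalClusters(tri))))
})
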