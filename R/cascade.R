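#' Stratified train / validation / test split
#'
#' Splits samples into development and test sets (80/20) and the development
#' set into training and validation (75/25), stratified by class label so
#' every class is represented in every partition. If a rounding accident
#' leaves a class out of a partition the draw is repeated (up to 20 times).
#'
#' @param labels class label per sample.
#' @param dev_fraction fraction in the development (train + validation) set.
#' @param train_fraction_of_dev fraction of the development set used for
#'   training.
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `validation`, `test`
#'   (disjoint, exhaustive).
#' @export
splitData <- function(labels, dev_fraction = 0.8,
                      train_fraction_of_dev = 0.75, seed = NULL) {
  stopifnot(dev_fraction > 0, dev_fraction < 1,
            train_fraction_of_dev > 0, train_fraction_of_dev < 1)
  n <- length(labels)
  if (n < 10L) stop("need at least 10 samples to split")
  labels <- as.character(labels)
  classes <- unique(labels)
  drawOnce <- function(s) withSeed(s, {
    parts <- list(train = integer(), validation = integer(),
                  test = integer())
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      n_test <- round((1 - dev_fraction) * n_c)
      n_val <- round((1 - train_fraction_of_dev) * (n_c - n_test))
      parts$test <- c(parts$test, idx[seq_len(n_test)])
      parts$validation <- c(parts$validation,
                            idx[n_test + seq_len(n_val)])
      parts$train <- c(parts$train, idx[-seq_len(n_test + n_val)])
    }
    parts
  })
  for (try in 0:19) {
    parts <- drawOnce(childSeed(if (is.null(seed)) 0L else seed, try))
    covered <- vapply(parts, function(ix)
      all(classes %in% labels[ix]), logical(1L))
    if (all(covered)) return(lapply(parts, sort))
  }
  stop("could not produce a split covering every class in every partition")
}

#' Default random-forest hyperparameter grid
#'
#' The 150-combination grid searched per cascade stage: 10 forest sizes x 5
#' depths x 3 leaf sizes. All values are overridable by passing any
#' data.frame with columns `n_estimators`, `max_depth`, `min_samples_leaf`
#' to [gridSearch()].
#'
#' @return `data.frame` with 150 rows.
#' @export
defaultHyperGrid <- function() {
  expand.grid(n_estimators = c(25L, 50L, 75L, 100L, 150L, 200L, 300L,
                               400L, 500L, 750L),
              max_depth = c(2L, 3L, 4L, 6L, 8L),
              min_samples_leaf = c(1L, 3L, 5L))
}

## Random forest via xgboost's parallel-tree mode: one boosting round of
## `n_estimators` trees, eta = 1, squared-error leaves on 0/1 labels so the
## ensemble prediction is the average in-leaf positive fraction, row
## subsampling 0.632 and sqrt(p) feature sampling per node. This keeps
## training fast and gives exact tree-path SHAP attributions via
## predict(..., predcontrib = TRUE).
fitRf <- function(x, y, params, seed = 0L) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0, 1)))
  p <- ncol(x)
  pa <- list(objective = "reg:squarederror",
             eta = 1,
             max_depth = as.integer(params$max_depth),
             min_child_weight = as.numeric(params$min_samples_leaf),
             num_parallel_tree = as.integer(params$n_estimators),
             subsample = 0.632,
             colsample_bynode = max(sqrt(p), 1) / p,
             tree_method = "hist",
             nthread = 1L,
             seed = as.integer(seed %% .Machine$integer.max))
  booster <- xgboost::xgb.train(
    params = pa,
    data = xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1L),
    nrounds = 1L, verbose = 0L)
  structure(list(booster = booster, features = colnames(x),
                 params = params), class = "rfModel")
}

rfScore <- function(model, x, contrib = FALSE) {
  miss <- setdiff(model$features, colnames(x))
  if (length(miss))
    stop("missing protein: ", paste(miss, collapse = ", "))
  xm <- as.matrix(x)[, model$features, drop = FALSE]
  out <- stats::predict(model$booster, xm, predcontrib = contrib)
  if (!contrib) pmin(pmax(as.numeric(out), 0), 1) else out
}

#' Concordance index of binary classification scores
#'
#' `(#concordant pairs + 0.5 * #tied pairs) / #permissible pairs`, where the
#' permissible pairs are all (positive, negative) pairs and a pair is
#' concordant when the positive sample's score is the larger one.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical); both classes must be
#'   present.
#' @return C-index in `[0, 1]`.
#' @export
cIndex <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  cmp <- outer(pos, neg, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

#' Validation-driven hyperparameter grid search
#'
#' Fits one random forest per grid row on the training set, scores each by
#' C-index on the validation set, and returns the best row. Ties go to the
#' smaller forest (fewest trees, then shallowest).
#'
#' @param x_train,y_train,x_val,y_val training and validation data (matrix /
#'   0-1 labels).
#' @param grid hyperparameter `data.frame`; [defaultHyperGrid()] by default.
#' @param seed RNG seed for the forest fits.
#' @return list: `best` (one-row data.frame), `results` (grid plus
#'   `val_cindex`), `n_evaluated`.
#' @export
gridSearch <- function(x_train, y_train, x_val, y_val,
                       grid = defaultHyperGrid(), seed = 0L) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyperparameter grid")
  val <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- fitRf(x_train, y_train, grid[i, ], seed = seed)
    cIndex(rfScore(fit, x_val), y_val)
  }, numeric(1L))
  results <- cbind(grid, val_cindex = val)
  ord <- order(-results$val_cindex, results$n_estimators, results$max_depth)
  list(best = grid[ord[1L], , drop = FALSE], results = results,
       n_evaluated = nrow(grid))
}

#' SHAP ranking of a stage model's proteins
#'
#' Per-feature mean absolute Shapley attribution of the model's predictions
#' over a reference data set (exact tree-path attributions; per sample the
#' attributions plus the base value reproduce the model output).
#'
#' @param model a fitted stage forest (as produced inside [trainCascade()]).
#' @param x data to attribute over (the development set in the cascade).
#' @return `data.frame` with `protein` and `mean_abs_shap`, descending.
#' @export
shapRank <- function(model, x) {
  ctr <- rfScore(model, x, contrib = TRUE)
  imp <- colMeans(abs(ctr[, model$features, drop = FALSE]))
  out <- data.frame(protein = names(imp), mean_abs_shap = unname(imp))
  out[order(-out$mean_abs_shap), , drop = FALSE]
}

#' Exhaustive few-protein subset selection
#'
#' Evaluates all 63 nonempty subsets of the top 6 SHAP-ranked proteins:
#' each subset is refit (with the stage's grid-searched hyperparameters) on
#' the training set and scored by validation C-index. Ties prefer the
#' smaller subset, then the earlier rank order.
#'
#' @param x_train,y_train,x_val,y_val stage data.
#' @param ranked_proteins proteins in SHAP rank order (the top 6 are used).
#' @param params hyperparameter row from [gridSearch()].
#' @param seed RNG seed.
#' @return list: `proteins` (winning subset, in rank order), `val_cindex`,
#'   `results` (per-subset table).
#' @export
selectSubset <- function(x_train, y_train, x_val, y_val, ranked_proteins,
                         params, seed = 0L) {
  top <- utils::head(ranked_proteins, 6L)
  if (length(top) < 6L)
    warning("fewer than 6 ranked proteins; searching subsets of ",
            length(top))
  subsets <- unlist(lapply(seq_along(top), function(k)
    utils::combn(seq_along(top), k, simplify = FALSE)), recursive = FALSE)
  val <- vapply(subsets, function(ix) {
    fit <- fitRf(x_train[, top[ix], drop = FALSE], y_train, params,
                 seed = seed)
    cIndex(rfScore(fit, x_val), y_val)
  }, numeric(1L))
  key <- vapply(subsets, function(ix)
    paste(sprintf("%02d", ix), collapse = ""), character(1L))
  ord <- order(-val, lengths(subsets), key)
  best <- subsets[[ord[1L]]]
  list(proteins = top[best], val_cindex = val[ord[1L]],
       results = data.frame(subset = vapply(subsets, function(ix)
         paste(top[ix], collapse = "+"), character(1L)),
         size = lengths(subsets), val_cindex = val))
}

#' @rdname trainCascade
#' @aliases ProteinClassifier-class
#' @exportClass ProteinClassifier
setClass("ProteinClassifier",
         representation(stages = "list", seed = "integer"))

setMethod("show", "ProteinClassifier", function(object) {
  cat("ProteinClassifier: 3-stage random-forest cascade\n")
  for (st in object@stages)
    cat(sprintf("  stage %d (%s): %d protein(s) [%s], val C = %.3f, test C = %.3f\n",
                st$stage, st$positive_class, length(st$proteins),
                paste(st$proteins, collapse = ", "),
                st$val_cindex, st$test_cindex))
  invisible(NULL)
})

#' @describeIn trainCascade list of the three fitted stage models.
#' @param x a `ProteinClassifier`.
#' @export
stageModels <- function(x) x@stages

## Stage definitions: sample filter and positive class on C1..C5 labels.
stageSpecs <- list(
  list(stage = 1L, positive_class = "C1 vs rest",
       keep = function(l) rep(TRUE, length(l)),
       pos = function(l) l == "C1"),
  list(stage = 2L, positive_class = "C2+C4 vs C3+C5",
       keep = function(l) l != "C1",
       pos = function(l) l %in% c("C2", "C4")),
  list(stage = 3L, positive_class = "C3 vs C5",
       keep = function(l) l %in% c("C3", "C5"),
       pos = function(l) l == "C3"))

#' Train the three-stage protein classifier cascade
#'
#' @description
#' Trains the therapy-recommendation cascade on expression plus final
#' cluster labels: stage 1 detects `C1` against everything else, stage 2
#' separates `C2 + C4` from `C3 + C5` on the non-`C1` subcohort, and stage 3
#' separates `C3` from `C5`. Every stage runs the same procedure: stratified
#' 80/20 development/test and 75/25 train/validation splits, a
#' hyperparameter grid search ([gridSearch()]), SHAP ranking of all input
#' proteins on the development set ([shapRank()]), and exhaustive
#' few-protein subset selection from the top 6 ([selectSubset()]). The
#' deployed stage model is the winning few-protein forest refit on the
#' training set; its test C-index is reported.
#'
#' @param expr patients x proteins matrix (all candidate proteins).
#' @param labels final cluster label per patient (`"C1"`..`"C5"`).
#' @param grid hyperparameter grid (defaults to the 150-combination
#'   [defaultHyperGrid()]).
#' @param dev_fraction,train_fraction_of_dev split fractions.
#' @param seed RNG seed; training is a deterministic function of
#'   (data, seed).
#' @return a `ProteinClassifier` object.
#' @seealso [cascadePredict()], [evaluateCascade()]
#' @export
trainCascade <- function(expr, labels, grid = defaultHyperGrid(),
                         dev_fraction = 0.8, train_fraction_of_dev = 0.75,
                         seed = 1L) {
  expr <- as.matrix(expr)
  labels <- as.character(labels)
  stopifnot(nrow(expr) == length(labels))
  stages <- lapply(stageSpecs, function(sp) {
    keep <- sp$keep(labels)
    x <- expr[keep, , drop = FALSE]
    y <- as.numeric(sp$pos(labels[keep]))
    s <- childSeed(seed, sp$stage)
    parts <- splitData(y, dev_fraction, train_fraction_of_dev, seed = s)
    xt <- x[parts$train, , drop = FALSE]; yt <- y[parts$train]
    xv <- x[parts$validation, , drop = FALSE]; yv <- y[parts$validation]
    xs <- x[parts$test, , drop = FALSE]; ys <- y[parts$test]
    gs <- gridSearch(xt, yt, xv, yv, grid = grid, seed = s)
    full <- fitRf(xt, yt, gs$best, seed = s)
    dev_idx <- c(parts$train, parts$validation)
    rank <- shapRank(full, x[dev_idx, , drop = FALSE])
    sub <- selectSubset(xt, yt, xv, yv, rank$protein, gs$best, seed = s)
    model <- fitRf(xt[, sub$proteins, drop = FALSE], yt, gs$best, seed = s)
    list(stage = sp$stage, positive_class = sp$positive_class,
         params = gs$best, proteins = sub$proteins, model = model,
         val_cindex = sub$val_cindex,
         test_cindex = cIndex(rfScore(model, xs), ys),
         grid_results = gs$results, shap = rank,
         subset_results = sub$results, split = parts)
  })
  methods::new("ProteinClassifier", stages = stages,
               seed = as.integer(seed))
}

#' Predict therapy recommendations with the cascade
#'
#' Routes each patient through the three stage models sequentially: a
#' stage-1 score of at least 0.5 recommends `VH`; otherwise a stage-2 score
#' of at least 0.5 recommends `CC`; otherwise stage 3 decides between
#' `CC_INTENSIFY` (the `C3` profile — chemotherapy with intensification,
#' e.g. transplant in first remission) and `NEITHER` (the `C5` profile).
#'
#' @param classifier a trained `ProteinClassifier`.
#' @param expr patients x proteins matrix providing every stage's selected
#'   proteins (a missing protein is an error naming it).
#' @return `data.frame` with `recommendation` and the three stage scores,
#'   one row per patient.
#' @export
cascadePredict <- function(classifier, expr) {
  stopifnot(methods::is(classifier, "ProteinClassifier"))
  expr <- as.matrix(expr)
  sc <- vapply(classifier@stages, function(st)
    rfScore(st$model, expr), numeric(nrow(expr)))
  sc <- matrix(sc, nrow = nrow(expr))
  rec <- ifelse(sc[, 1L] >= 0.5, "VH",
                ifelse(sc[, 2L] >= 0.5, "CC",
                       ifelse(sc[, 3L] >= 0.5, "CC_INTENSIFY", "NEITHER")))
  data.frame(patient_id = rownames(expr), recommendation = rec,
             stage1_score = sc[, 1L], stage2_score = sc[, 2L],
             stage3_score = sc[, 3L], row.names = NULL)
}

#' Evaluate the cascade against known cluster labels
#'
#' @description
#' Scores cascade recommendations on labelled data. The label-implied
#' therapy is `VH` for `C1`, `CC` for `C2`-`C4` (an intensified-CC
#' recommendation counts as `CC`), and `NEITHER` for `C5`. Reported metrics:
#'
#' * `correct_therapy_fraction` — recommended therapy equals the implied one;
#' * `misassigned_fraction` — direct VH/CC crossings (VH recommended where
#'   CC was implied, or vice versa);
#' * `c5_assigned_fraction` — true `C5` patients handed a VH or CC
#'   recommendation instead of `NEITHER`;
#' * per-stage sensitivity / specificity / C-index at the 0.5 threshold,
#'   each stage evaluated on the samples its training population defines;
#' * `pooled_accuracy`, `pooled_sensitivity`, `pooled_specificity` —
#'   micro-averages of the three stages' binary decisions (decisions are
#'   pooled across stages before the rates are formed);
#' * `confusion` — true cluster x recommendation table.
#'
#' @param classifier a trained `ProteinClassifier`.
#' @param expr patients x proteins matrix.
#' @param labels true cluster labels (`"C1"`..`"C5"`).
#' @return list of metrics as described.
#' @export
evaluateCascade <- function(classifier, expr, labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("missing cluster labels")
  pred <- cascadePredict(classifier, expr)
  implied <- ifelse(labels == "C1", "VH",
                    ifelse(labels == "C5", "NEITHER", "CC"))
  given <- ifelse(pred$recommendation == "CC_INTENSIFY", "CC",
                  pred$recommendation)
  crossing <- (given == "VH" & implied == "CC") |
    (given == "CC" & implied == "VH")
  scores <- as.matrix(pred[, c("stage1_score", "stage2_score",
                               "stage3_score")])
  per_stage <- lapply(stageSpecs, function(sp) {
    keep <- sp$keep(labels)
    y <- as.numeric(sp$pos(labels[keep]))
    s <- scores[keep, sp$stage]
    yhat <- as.numeric(s >= 0.5)
    list(stage = sp$stage,
         sensitivity = mean(yhat[y == 1] == 1),
         specificity = mean(yhat[y == 0] == 0),
         accuracy = mean(yhat == y),
         cindex = if (length(unique(y)) == 2L) cIndex(s, y) else NA_real_,
         n = sum(keep))
  })
  counts <- vapply(stageSpecs, function(sp) {
    keep <- sp$keep(labels)
    y <- as.numeric(sp$pos(labels[keep]))
    yhat <- as.numeric(scores[keep, sp$stage] >= 0.5)
    c(correct = sum(yhat == y), n = length(y),
      tp = sum(yhat == 1 & y == 1), pos = sum(y == 1),
      tn = sum(yhat == 0 & y == 0), neg = sum(y == 0))
  }, numeric(6L))
  list(correct_therapy_fraction = mean(given == implied),
       misassigned_fraction = mean(crossing),
       c5_assigned_fraction =
         if (any(labels == "C5"))
           mean(given[labels == "C5"] %in% c("VH", "CC")) else NA_real_,
       per_stage = per_stage,
       pooled_accuracy = sum(counts["correct", ]) / sum(counts["n", ]),
       pooled_sensitivity = sum(counts["tp", ]) / sum(counts["pos", ]),
       pooled_specificity = sum(counts["tn", ]) / sum(counts["neg", ]),
       confusion = table(true = labels,
                         recommended = pred$recommendation))
}
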