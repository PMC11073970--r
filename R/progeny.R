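#' @rdname progenyCluster
#' @aliases ProgenyClustering-class
#' @exportClass ProgenyClustering
setClass("ProgenyClustering",
         representation(chosen_k = "integer",
                        stability_scores = "numeric",
                        assignments = "integer",
                        n_iterations = "integer",
                        seed = "integer"))

setValidity("ProgenyClustering", function(object) {
  msg <- character()
  k <- object@chosen_k
  if (length(unique(object@assignments)) != k)
    msg <- c(msg, "some cluster in 1..chosen_k is empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProgenyClustering", function(object) {
  cat("ProgenyClustering: k =", object@chosen_k, "on",
      length(object@assignments), "observations\n")
  if (length(object@stability_scores) > 1L) {
    cat("  stability scores:\n")
    print(round(object@stability_scores, 4L))
  }
  cat("  cluster sizes:", paste(table(object@assignments), collapse = "/"),
      "\n")
  invisible(NULL)
})

#' @describeIn progenyCluster chosen number of clusters.
#' @export
chosenK <- function(x) x@chosen_k

#' @describeIn progenyCluster per-observation cluster labels (1..k).
#' @export
clusterAssignments <- function(x) x@assignments

#' @describeIn progenyCluster stability score per candidate k.
#' @export
stabilityScores <- function(x) x@stability_scores

#' Base clustering used inside the progeny procedure
#'
#' k-means with 10 random restarts (best within-cluster sum of squares kept);
#' a Ward agglomerative hook (`method = "ward"`) is available for users who
#' prefer hierarchical base clusterings.
#'
#' @param x numeric matrix, observations in rows.
#' @param k number of clusters, `2 <= k <= nrow(x)`.
#' @param seed RNG seed (k-means restarts are random).
#' @param method `"kmeans"` (default) or `"ward"`.
#' @return integer labels 1..k.
#' @export
baseCluster <- function(x, k, seed = NULL, method = c("kmeans", "ward")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of observations")
  if (k < 1L) stop("k must be positive")
  if (k == 1L) return(rep(1L, nrow(x)))
  if (k == nrow(x)) return(seq_len(nrow(x)))   # every point its own cluster
  if (method == "ward")
    return(as.integer(stats::cutree(stats::hclust(stats::dist(x),
                                                  method = "ward.D2"), k)))
  withSeed(seed, {
    km <- suppressWarnings(
      stats::kmeans(x, centers = k, nstart = 10L, iter.max = 50L))
    as.integer(km$cluster)
  })
}

#' Progeny resampling of a clustered data set
#'
#' For each cluster, draws `m_per_cluster` artificial "progeny" observations
#' by sampling every feature independently (with replacement) from that
#' cluster's members — preserving the cluster's feature marginals while
#' destroying within-cluster covariance. Reclustering such progeny probes how
#' much of the clustering is driven by genuine multivariate structure.
#'
#' @param x data matrix (observations x features).
#' @param labels cluster labels from [baseCluster()].
#' @param m_per_cluster progeny per cluster.
#' @param seed RNG seed.
#' @return list with `progeny` (matrix, `k * m_per_cluster` rows) and `truth`
#'   (the generating cluster of each progeny row).
#' @export
makeProgeny <- function(x, labels, m_per_cluster = 20L, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  ks <- seq_len(max(labels))
  if (any(tabulate(labels, nbins = max(labels)) == 0L))
    stop("empty cluster")
  withSeed(seed, {
    prog <- lapply(ks, function(cl) {
      mem <- x[labels == cl, , drop = FALSE]
      apply(mem, 2L, function(col)
        col[sample.int(length(col), m_per_cluster, replace = TRUE)])
    })
    list(progeny = do.call(rbind, prog),
         truth = rep(ks, each = m_per_cluster))
  })
}

## Mean co-assignment contrast: P(same recovered cluster | same truth)
## minus P(same recovered cluster | different truth).
coassignContrast <- function(found, truth) {
  same_truth <- outer(truth, truth, "==")
  same_found <- outer(found, found, "==")
  off <- !diag(length(truth))
  mean(same_found[same_truth & off]) - mean(same_found[!same_truth])
}

#' Stability score of a candidate number of clusters
#'
#' One progeny-clustering iteration clusters the data at `k`, draws progeny
#' per cluster, reclusters the progeny at `k`, and contrasts co-assignment of
#' progeny pairs from the same versus different generating clusters. The same
#' contrast computed after shuffling the progeny's generating labels serves as
#' a null reference and is subtracted. The score averages
#' (observed - null) over `n_iterations` iterations; well-supported `k` gives
#' scores near 1, structureless data near 0.
#'
#' @inheritParams baseCluster
#' @param n_iterations progeny resampling iterations.
#' @param m_per_cluster progeny per cluster and iteration.
#' @return numeric stability score.
#' @export
stabilityScore <- function(x, k, n_iterations = 50L, m_per_cluster = 20L,
                           seed = NULL, method = "kmeans") {
  x <- as.matrix(x)
  labels <- baseCluster(x, k, seed = childSeed(seed, 0L), method = method)
  iter <- vapply(seq_len(n_iterations), function(i) {
    s <- childSeed(seed, i)
    pg <- makeProgeny(x, labels, m_per_cluster, seed = s)
    found <- baseCluster(pg$progeny, k, seed = childSeed(s, 1L),
                         method = method)
    obs <- coassignContrast(found, pg$truth)
    null <- withSeed(childSeed(s, 2L),
                     coassignContrast(found, sample(pg$truth)))
    obs - null
  }, numeric(1L))
  mean(iter)
}

#' Progeny clustering with data-driven choice of k
#'
#' @description
#' Evaluates [stabilityScore()] for every candidate number of clusters and
#' returns the final [baseCluster()] assignment at the chosen k. The choice
#' accounts for an asymmetry of the stability score: *merging* well-separated
#' clusters preserves progeny co-assignment, so every k at or below the true
#' number saturates the score, while *splitting* a genuine cluster mixes its
#' progeny and the score drops sharply. Hence, when the best score indicates
#' real structure (at least `structure_cutoff`), the finest candidate whose
#' score is within `score_tol` of the maximum is chosen; when all scores are
#' low (no structure, where the score instead drifts upward with k), the
#' coarsest candidate is returned and a message notes the flat profile.
#' Passing a single candidate forces that k (the forced path used when the
#' pipeline targets a known stage structure); its stability score is then not
#' computed.
#'
#' @inheritParams stabilityScore
#' @param k_candidates integer candidates, a subset of 2..8.
#' @param structure_cutoff minimum best score for the data to count as
#'   clustered (default 0.6; pure-noise profiles stay well below it).
#' @param score_tol scores within this margin of the best are treated as
#'   ties (default 0.02, above the Monte-Carlo noise of the score at the
#'   default number of iterations).
#' @return a [ProgenyClustering-class] object.
#' @examples
#' cfg <- rppaCohortConfig(n_patients = 120, n_proteins = 40, seed = 3)
#' x <- zscoreColumns(lfcMatrix(simulateCohort(cfg)))
#' pc <- progenyCluster(x, k_candidates = 5L, seed = 3)
#' table(clusterAssignments(pc))
#' @export
progenyCluster <- function(x, k_candidates = 2:6, n_iterations = 50L,
                           m_per_cluster = 20L, seed = NULL,
                           method = "kmeans", structure_cutoff = 0.6,
                           score_tol = 0.02) {
  x <- as.matrix(x)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (!all(k_candidates %in% 2:8))
    stop("k_candidates must lie in 2..8")
  if (any(k_candidates > nrow(x))) stop("candidate k exceeds n")
  if (length(k_candidates) == 1L) {
    scores <- stats::setNames(NA_real_, as.character(k_candidates))
    best <- k_candidates
  } else {
    scores <- vapply(k_candidates, function(k)
      stabilityScore(x, k, n_iterations, m_per_cluster,
                     seed = childSeed(seed, 100L + k), method = method),
      numeric(1L))
    names(scores) <- as.character(k_candidates)
    if (max(scores) >= structure_cutoff) {
      best <- max(k_candidates[scores >= max(scores) - score_tol])
    } else {
      best <- min(k_candidates)
      message("flat stability profile (best score ",
              format(max(scores), digits = 3),
              "); falling back to the coarsest candidate k = ", best)
    }
  }
  assign <- baseCluster(x, best, seed = childSeed(seed, 0L), method = method)
  methods::new("ProgenyClustering",
               chosen_k = as.integer(best),
               stability_scores = scores,
               assignments = assign,
               n_iterations = as.integer(n_iterations),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
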