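#' @rdname buildSelector
#' @aliases SelectorSet-class
#' @exportClass SelectorSet
setClass("SelectorSet",
         representation(name = "character",
                        proteins = "character",
                        cohort_ids = "character",
                        clustering = "ProgenyClustering",
                        os_p = "numeric",
                        crd_p = "numeric",
                        outcome = "data.frame",
                        candidates = "data.frame"))

setMethod("show", "SelectorSet", function(object) {
  cat("SelectorSet", object@name, ":", length(object@proteins),
      "proteins,", length(object@cohort_ids), "patients,",
      "k =", object@clustering@chosen_k, "\n")
  cat("  OS log-rank p =", format(object@os_p, digits = 3),
      "; CRD log-rank p =", format(object@crd_p, digits = 3), "\n")
  invisible(NULL)
})

#' @describeIn buildSelector proteins of the winning selector set.
#' @export
selectorProteins <- function(x) x@proteins

#' Per-cluster per-arm outcome summary
#'
#' Kaplan-Meier summaries for every cluster-by-arm cell: patient count,
#' median overall survival (`Inf` = not reached), five-year survival
#' `S(60 mo.)`, and median remission duration among patients who achieved
#' remission.
#'
#' @param labels cluster label per patient.
#' @param clinical clinical `data.frame` aligned with `labels`.
#' @return `data.frame` with one row per cluster x arm cell.
#' @export
clusterOutcomeSummary <- function(labels, clinical) {
  stopifnot(length(labels) == nrow(clinical))
  cells <- expand.grid(cluster = sort(unique(as.character(labels))),
                       arm = c("VH", "CC"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- labels == cells$cluster[i] & clinical$arm == cells$arm[i]
    if (!any(sel))
      return(data.frame(cells[i, ], n = 0L, median_os = NA_real_,
                        s60 = NA_real_, median_crd = NA_real_))
    km <- kmFit(clinical$os_months[sel], clinical$os_event[sel])
    crd_ok <- sel & !is.na(clinical$crd_months)
    med_crd <- if (any(crd_ok))
      medianSurvival(kmFit(clinical$crd_months[crd_ok],
                           clinical$crd_event[crd_ok])) else NA_real_
    data.frame(cells[i, ], n = sum(sel), median_os = medianSurvival(km),
               s60 = survivalAt(km, 60), median_crd = med_crd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cluster, out$arm), ]
}

#' Treatment-arm contrast within one patient cluster
#'
#' Kaplan-Meier per arm, then a verdict: the preferred arm is the one with
#' the larger median OS (a never-reached median beats any finite one);
#' `UNDETERMINED` when only one arm is present or the medians tie. The
#' `neither` flag marks clusters with poor outcome under *both* therapies —
#' both arm medians finite and below `neither_threshold` months.
#'
#' @param clinical clinical rows of the cluster's patients.
#' @param neither_threshold months; both-arm medians below this flag the
#'   cluster as benefiting from neither therapy (default 12).
#' @return list: `arms` (per-arm n / median / S60), `preferred_arm`,
#'   `margin` (difference of medians, `Inf` when not reached beats finite),
#'   `best_median`, `neither`.
#' @export
armContrast <- function(clinical, neither_threshold = 12) {
  if (nrow(clinical) == 0L) stop("empty cluster")
  arms <- lapply(c(VH = "VH", CC = "CC"), function(a) {
    sel <- clinical$arm == a
    if (!any(sel)) return(list(n = 0L, median = NA_real_, s60 = NA_real_))
    km <- kmFit(clinical$os_months[sel], clinical$os_event[sel])
    list(n = sum(sel), median = medianSurvival(km), s60 = survivalAt(km, 60))
  })
  m_vh <- arms$VH$median; m_cc <- arms$CC$median
  if (is.na(m_vh) || is.na(m_cc) || m_vh == m_cc) {
    preferred <- "UNDETERMINED"
    margin <- if (!is.na(m_vh) && !is.na(m_cc)) 0 else NA_real_
  } else if (m_vh > m_cc) {
    preferred <- "VH"; margin <- m_vh - m_cc
  } else {
    preferred <- "CC"; margin <- m_cc - m_vh
  }
  best <- max(m_vh, m_cc, na.rm = TRUE)
  neither <- is.finite(m_vh) && is.finite(m_cc) &&
    m_vh < neither_threshold && m_cc < neither_threshold
  list(arms = arms, preferred_arm = preferred, margin = margin,
       best_median = best, neither = neither)
}

#' Build a protein selector set for one (sub)cohort
#'
#' Crosses the screen's two significance cutoffs with top-N truncations of
#' the ranked prognostic list to form candidate protein sets and clusters the
#' per-protein z-scored expression of each candidate with
#' [progenyCluster()]. Candidates are scored by how *therapeutically
#' discriminating* their clusters are: the primary score is the smallest
#' within-cluster VH-vs-CC log-rank chi-square across clusters (maximised, so
#' every cluster must separate the arms — a selector whose weakest cluster
#' carries no treatment contrast cannot route patients to a therapy), with
#' the overall OS and CRD log-rank p-values across clusters as tie-breaks.
#' The winner becomes the selector set.
#'
#' @param cohort an [RppaCohort] (already aligned).
#' @param screen_table output of [screenPrognostic()] on this cohort; when
#'   `NULL` it is computed here.
#' @param k target number of clusters (single value forces it; a vector lets
#'   the stability score choose).
#' @param name label for the selector (`"PS1"`, `"PS2"`, `"PS3"`, ...).
#' @param alphas screen cutoffs crossed into candidates.
#' @param top_n truncation lengths of the ranked prognostic list
#'   (`Inf` = every protein passing the cutoff, the default: truncating by
#'   p-value rank can drop an entire coherent marker block whose members sit
#'   at borderline ranks and leave the corresponding patient group invisible
#'   to the clustering).
#' @param min_cluster_size smallest admissible cluster.
#' @param n_iterations,m_per_cluster,method progeny-clustering controls.
#' @param seed RNG seed.
#' @return a `SelectorSet` object.
#' @export
buildSelector <- function(cohort, screen_table = NULL, k = 2L, name = "PS",
                          alphas = c(0.05, 0.01), top_n = Inf,
                          min_cluster_size = 10L, n_iterations = 50L,
                          m_per_cluster = 20L, method = "kmeans",
                          seed = NULL) {
  if (is.null(screen_table)) screen_table <- screenPrognostic(cohort)
  expr <- lfcMatrix(cohort)
  cd <- clinicalTable(cohort)
  cand <- list()
  for (a in alphas) {
    ranked <- selectPrognostic(screen_table, a)
    for (nn in top_n) {
      ps <- utils::head(ranked, nn)
      if (length(ps) >= 2L)
        cand[[sprintf("alpha%.2f_top%s", a, format(nn))]] <- ps
    }
  }
  cand <- cand[!duplicated(lapply(cand, paste, collapse = "|"))]
  if (length(cand) == 0L)
    stop("no candidate protein set for ", name,
         ": the screen selected fewer than 2 proteins")
  evalOne <- function(ps, s) {
    z <- zscoreColumns(expr[, ps, drop = FALSE])
    pc <- progenyCluster(z, k_candidates = k, n_iterations = n_iterations,
                         m_per_cluster = m_per_cluster, seed = s,
                         method = method)
    lab <- clusterAssignments(pc)
    if (min(table(lab)) < min_cluster_size) return(NULL)
    os_p <- logrankTest(cd$os_months, cd$os_event, lab)$p_value
    crd_ok <- !is.na(cd$crd_months)
    crd_p <- if (sum(crd_ok) >= 2L &&
                 length(unique(lab[crd_ok])) >= 2L)
      logrankTest(cd$crd_months[crd_ok], cd$crd_event[crd_ok],
                  lab[crd_ok])$p_value else NA_real_
    arm_x2 <- vapply(sort(unique(lab)), function(g) {
      sel <- lab == g
      if (length(unique(cd$arm[sel])) < 2L) return(0)
      logrankTest(cd$os_months[sel], cd$os_event[sel],
                  cd$arm[sel])$statistic
    }, numeric(1L))
    list(clustering = pc, os_p = os_p, crd_p = crd_p,
         min_arm_chisq = min(arm_x2))
  }
  fits <- lapply(seq_along(cand), function(i)
    evalOne(cand[[i]], childSeed(seed, i)))
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok))
    stop("no candidate for ", name, " yields >= 2 clusters of at least ",
         min_cluster_size, " patients")
  candTab <- data.frame(candidate = names(cand),
                        n_proteins = lengths(cand),
                        min_arm_chisq = vapply(fits, function(f)
                          if (is.null(f)) NA_real_ else f$min_arm_chisq,
                          numeric(1L)),
                        os_p = vapply(fits, function(f)
                          if (is.null(f)) NA_real_ else f$os_p, numeric(1L)),
                        crd_p = vapply(fits, function(f)
                          if (is.null(f)) NA_real_ else f$crd_p, numeric(1L)))
  ord <- order(-candTab$min_arm_chisq, candTab$os_p, candTab$crd_p,
               candTab$n_proteins)
  best <- ord[ord %in% which(ok)][1L]
  win <- fits[[best]]
  lab <- clusterAssignments(win$clustering)
  methods::new("SelectorSet",
               name = name,
               proteins = cand[[best]],
               cohort_ids = rownames(expr),
               clustering = win$clustering,
               os_p = win$os_p,
               crd_p = win$crd_p,
               outcome = clusterOutcomeSummary(lab, cd),
               candidates = candTab)
}
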