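#' @rdname runSequential
#' @aliases TriageClusters-class
#' @exportClass TriageClusters
setClass("TriageClusters",
         representation(labels = "character",
                        provenance = "character",
                        recommendations = "character",
                        selectors = "list",
                        outcome = "data.frame",
                        dropped = "character"))

setValidity("TriageClusters", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by patient id")
  if (!all(object@labels %in% names(object@recommendations)))
    msg <- c(msg, "every label needs a recommendation")
  if (!all(object@recommendations %in%
             c("VH", "CC", "NEITHER", "UNDETERMINED")))
    msg <- c(msg, "invalid recommendation value")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TriageClusters", function(object) {
  cat("TriageClusters:", length(object@labels), "patients in",
      length(object@recommendations), "clusters\n")
  tab <- table(object@labels)
  for (cl in names(object@recommendations))
    cat(sprintf("  %s (n = %3d, from %s) -> %s\n", cl, tab[[cl]],
                object@provenance[[cl]], object@recommendations[[cl]]))
  if (length(object@dropped))
    cat("  dropped by treatment filter:", length(object@dropped), "\n")
  invisible(NULL)
})

#' @describeIn runSequential final cluster label per patient (named vector).
#' @param x a `TriageClusters` object.
#' @export
finalClusters <- function(x) x@labels

#' @describeIn runSequential named map cluster -> recommended therapy.
#' @export
recommendationMap <- function(x) x@recommendations

#' @describeIn runSequential the three fitted `SelectorSet`s.
#' @export
selectorSets <- function(x) x@selectors

#' @describeIn runSequential per final-cluster per-arm outcome table.
#' @export
outcomeSummary <- function(x) x@outcome

#' Sequential protein-selector pipeline
#'
#' @description
#' Reproduces the three-stage selector construction on a cohort:
#'
#' 1. **PS1** clusters the whole cohort into three groups from its best
#'    prognostic protein set. The group preferring VH (larger median OS under
#'    VH, largest margin) is frozen as a final cluster; of the two others,
#'    the one with the poorer best-arm median feeds PS3, the remaining one
#'    PS2. When no group prefers VH, the group with the best outcome is
#'    frozen instead and a message notes that no VH-recommended cluster
#'    exists.
#' 2. **PS2** and **PS3** re-screen and re-cluster their subcohorts into two
#'    groups each, yielding five final clusters.
#' 3. Final labels `C1..C5` and therapy recommendations are assigned from
#'    each final cluster's [armContrast()]: at most one cluster — the worst
#'    of those with both arm medians under `neither_threshold` — is labelled
#'    `C5`/`NEITHER`; the VH-preferring cluster with the largest margin is
#'    `C1`/`VH`; the rest are `C2`-`C4`/`CC`, ordered by provenance then
#'    median OS. Cluster naming is therefore outcome-driven while the PS
#'    provenance of every cluster is recorded.
#'
#' Between PS1 and the later stages an optional treatment filter sharpens the
#' arm contrast: when the clinical table carries a logical `vh_plus_arac`
#' column, VH patients who also received cytarabine are dropped; when it
#' carries `arac_only`, CC patients are restricted to those treated with
#' cytarabine alone.
#'
#' @param cohort an [RppaCohort] containing both arms.
#' @param ps1_k number of PS1 clusters (the design targets 3).
#' @param alphas,top_n,min_cluster_size,n_iterations,m_per_cluster,method
#'   passed to [buildSelector()].
#' @param neither_threshold months; see [armContrast()].
#' @param poor_threshold months; a PS1 group whose best arm median falls
#'   below this is logged as the poor-outcome branch (the branch choice
#'   itself uses the relative ordering, which is well-defined even when both
#'   or neither group crosses the threshold).
#' @param min_subcohort smallest subcohort a later stage may run on.
#' @param treatment_filter apply the arm-sharpening filter when the clinical
#'   columns are present.
#' @param seed RNG seed; the full run is deterministic given (cohort, seed).
#' @return a `TriageClusters` object.
#' @examples
#' \donttest{
#' cohort <- simulateCohort(rppaCohortConfig(seed = 11))
#' tri <- runSequential(cohort, n_iterations = 10, seed = 11)
#' recommendationMap(tri)
#' }
#' @export
runSequential <- function(cohort, ps1_k = 3L,
                          alphas = c(0.05, 0.01), top_n = Inf,
                          neither_threshold = 12, poor_threshold = 20,
                          min_cluster_size = 10L, min_subcohort = 30L,
                          n_iterations = 50L, m_per_cluster = 20L,
                          method = "kmeans", treatment_filter = TRUE,
                          seed = NULL) {
  if (ps1_k != 3L)
    stop("the sequential design requires ps1_k = 3 (one frozen branch and ",
         "two subcohorts)")
  cd <- clinicalTable(cohort)
  if (length(unique(cd$arm)) < 2L) stop("cohort must contain both arms")

  ps1 <- buildSelector(cohort, k = ps1_k, name = "PS1", alphas = alphas,
                       top_n = top_n, min_cluster_size = min_cluster_size,
                       n_iterations = n_iterations,
                       m_per_cluster = m_per_cluster, method = method,
                       seed = childSeed(seed, 1L))
  ps1_lab <- stats::setNames(clusterAssignments(ps1@clustering),
                             ps1@cohort_ids)

  ## Treatment filter after PS1 (PS1 itself is not refit).
  dropped <- character()
  if (treatment_filter) {
    drop <- rep(FALSE, nrow(cd))
    if (!is.null(cd$vh_plus_arac))
      drop <- drop | (cd$arm == "VH" & cd$vh_plus_arac %in% TRUE)
    if (!is.null(cd$arac_only))
      drop <- drop | (cd$arm == "CC" & !(cd$arac_only %in% TRUE))
    if (any(drop)) {
      dropped <- cd$patient_id[drop]
      message("treatment filter removed ", length(dropped), " patient(s)")
      cohort <- cohort[, !drop]
      cd <- clinicalTable(cohort)
      ps1_lab <- ps1_lab[cd$patient_id]
    }
  }

  ## Classify the PS1 branches by arm contrast.
  contr1 <- lapply(seq_len(ps1_k), function(g)
    armContrast(cd[ps1_lab == g, , drop = FALSE], neither_threshold))
  vh_pref <- vapply(contr1, function(ct)
    ct$preferred_arm == "VH", logical(1L))
  margins <- vapply(contr1, function(ct)
    ifelse(is.na(ct$margin), -Inf, ct$margin), numeric(1L))
  best_med <- vapply(contr1, function(ct) ct$best_median, numeric(1L))
  if (any(vh_pref)) {
    frozen <- which(vh_pref)[which.max(margins[vh_pref])]
  } else {
    frozen <- which.max(best_med)
    message("no PS1 group prefers VH; freezing the best-outcome group ",
            "without a VH recommendation")
  }
  rest <- setdiff(seq_len(ps1_k), frozen)
  ps3_branch <- rest[which.min(best_med[rest])]
  ps2_branch <- setdiff(rest, ps3_branch)
  if (best_med[ps3_branch] >= poor_threshold)
    message("poor-outcome branch has best-arm median ",
            format(best_med[ps3_branch], digits = 3),
            " mo., above the nominal poor threshold of ", poor_threshold)

  subSelector <- function(branch, name, s) {
    ids <- names(ps1_lab)[ps1_lab == branch]
    if (length(ids) < min_subcohort)
      stop("stage ", name, " has only ", length(ids),
           " patients (minimum ", min_subcohort, ")")
    sub <- cohort[, ids]
    buildSelector(sub, k = 2L, name = name, alphas = alphas, top_n = top_n,
                  min_cluster_size = min_cluster_size,
                  n_iterations = n_iterations,
                  m_per_cluster = m_per_cluster, method = method, seed = s)
  }
  ps2 <- subSelector(ps2_branch, "PS2", childSeed(seed, 2L))
  ps3 <- subSelector(ps3_branch, "PS3", childSeed(seed, 3L))

  ## Assemble raw final clusters with provenance.
  raw <- character(nrow(cd)); names(raw) <- cd$patient_id
  raw[names(ps1_lab)[ps1_lab == frozen]] <- "PS1.frozen"
  for (sel in list(ps2, ps3)) {
    lab <- clusterAssignments(sel@clustering)
    raw[sel@cohort_ids] <- paste0(sel@name, ".", lab)
  }

  ## Outcome-driven naming: C5 = worst both-arm-poor cluster, C1 = strongest
  ## VH cluster, the rest C2..C4 by provenance then median OS.
  parts <- sort(unique(raw))
  contrF <- lapply(parts, function(p)
    armContrast(cd[raw == p, , drop = FALSE], neither_threshold))
  names(contrF) <- parts
  bestF <- vapply(contrF, function(ct) ct$best_median, numeric(1L))
  marginF <- vapply(contrF, function(ct)
    ifelse(is.na(ct$margin), -Inf, ct$margin), numeric(1L))
  vhF <- vapply(contrF, function(ct) ct$preferred_arm == "VH", logical(1L))

  ## NEITHER: examine only the cluster with the worst arm-pooled median OS
  ## (pooled medians are far less noisy than per-arm ones, so the ranking is
  ## stable) and flag it when both arms are poor on either endpoint (the
  ## clusters are judged on OS and CRD curves alike).
  pooledF <- vapply(parts, function(p)
    medianSurvival(kmFit(cd$os_months[raw == p], cd$os_event[raw == p])),
    numeric(1L))
  worst <- parts[which.min(pooledF)]
  crd_neither <- {
    sel <- raw == worst & !is.na(cd$crd_months)
    if (sum(sel) >= 10L && length(unique(cd$arm[sel])) == 2L)
      armContrast(data.frame(os_months = cd$crd_months[sel],
                             os_event = cd$crd_event[sel],
                             arm = cd$arm[sel]),
                  neither_threshold)$neither
    else FALSE
  }
  neither_part <- if (contrF[[worst]]$neither || crd_neither)
    worst else character()
  vh_parts <- setdiff(parts[vhF], neither_part)
  c1_part <- if (length(vh_parts))
    vh_parts[which.max(marginF[vh_parts])] else character()
  if (!length(c1_part)) message("no final cluster is VH-recommended")
  mid <- setdiff(parts, c(c1_part, neither_part))
  stage_rank <- match(substr(mid, 1L, 3L), c("PS1", "PS2", "PS3"))
  mid <- mid[order(stage_rank, -bestF[mid])]
  ordered <- c(c1_part, mid, neither_part)
  new_names <- paste0("C", seq_along(ordered))
  rec <- ifelse(ordered %in% neither_part, "NEITHER",
                ifelse(vhF[ordered], "VH",
                       ifelse(vapply(contrF[ordered], function(ct)
                         ct$preferred_arm == "CC", logical(1L)),
                         "CC", "UNDETERMINED")))
  ## An undetermined contrast outside the NEITHER slot defaults to CC, the
  ## majority therapy, with a message.
  if (any(rec == "UNDETERMINED")) {
    message("arm contrast undetermined for ",
            sum(rec == "UNDETERMINED"), " cluster(s); defaulting to CC")
    rec[rec == "UNDETERMINED"] <- "CC"
  }
  labels <- stats::setNames(new_names[match(raw, ordered)], names(raw))
  prov <- stats::setNames(sub("\\..*$", "", ordered), new_names)
  methods::new("TriageClusters",
               labels = labels,
               provenance = prov,
               recommendations = stats::setNames(rec, new_names),
               selectors = list(PS1 = ps1, PS2 = ps2, PS3 = ps3),
               outcome = clusterOutcomeSummary(labels, cd),
               dropped = dropped)
}
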