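#' RppaCohort: an RPPA expression matrix joined to clinical outcomes
#'
#' @description
#' `RppaCohort` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' central container of the package. The single assay, `"lfc"`, holds protein
#' expression as log2 fold-change versus the normal-bone-marrow CD34+ reference
#' (proteins in rows, patients in columns, the Bioconductor orientation).
#' Clinical outcomes live in `colData`: overall survival (`os_months`,
#' `os_event`), complete remission duration (`crd_months`, `crd_event`; `NA`
#' for patients never in remission) and the treatment arm (`arm`, `"VH"` =
#' venetoclax + hypomethylating agent, `"CC"` = conventional chemotherapy).
#' Cohorts produced by [simulateCohort()] additionally carry the planted
#' `true_cluster` label.
#'
#' @param expression numeric matrix, patients in rows and proteins in columns
#'   (the natural orientation of a clinical join; it is transposed internally).
#'   Row and column names are required and must be unique.
#' @param clinical `data.frame` with columns `patient_id`, `os_months`,
#'   `os_event`, `arm`, and optionally `crd_months`, `crd_event` plus arbitrary
#'   covariate columns. Rows are matched to `rownames(expression)` by
#'   `patient_id` and may come in any order.
#'
#' @return An `RppaCohort` object.
#'
#' @examples
#' cohort <- simulateCohort(rppaCohortConfig(n_patients = 60, n_proteins = 40,
#'                                           seed = 1))
#' cohort
#' dim(lfcMatrix(cohort))
#' head(clinicalTable(cohort))
#'
#' @aliases RppaCohort-class
#' @export
RppaCohort <- function(expression, clinical) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("'expression' must be a numeric matrix (patients x proteins)")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("'expression' needs patient row names and protein column names")
  clinical <- checkClinical(clinical)
  ord <- match(rownames(expression), clinical$patient_id)
  if (anyNA(ord))
    stop("clinical table is missing patients: ",
         paste(utils::head(setdiff(rownames(expression),
                                   clinical$patient_id), 5L), collapse = ", "))
  clinical <- clinical[ord, , drop = FALSE]
  cd <- S4Vectors::DataFrame(clinical, row.names = clinical$patient_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lfc = t(expression)), colData = cd)
  methods::new("RppaCohort", se)
}

setClass("RppaCohort", contains = "SummarizedExperiment")

setValidity("RppaCohort", function(object) {
  msg <- character()
  if (!"lfc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'lfc' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient_id", "os_months", "os_event", "arm")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(cd$patient_id))
      msg <- c(msg, "duplicate patient ids")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate protein ids")
    if (any(cd$os_months < 0, na.rm = TRUE))
      msg <- c(msg, "negative os_months")
    if (!all(cd$arm %in% c("VH", "CC")))
      msg <- c(msg, "arm must be 'VH' or 'CC'")
    if (!all(cd$os_event %in% c(0, 1)))
      msg <- c(msg, "os_event must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

## Validate + type a raw clinical data.frame (shared by RppaCohort() and
## readClinical()).
checkClinical <- function(clinical) {
  if (!is.data.frame(clinical)) stop("'clinical' must be a data.frame")
  need <- c("patient_id", "os_months", "os_event", "arm")
  miss <- setdiff(need, colnames(clinical))
  if (length(miss))
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  clinical$patient_id <- as.character(clinical$patient_id)
  if (anyDuplicated(clinical$patient_id)) stop("duplicate patient id")
  clinical$os_months <- as.numeric(clinical$os_months)
  clinical$os_event <- as.numeric(clinical$os_event)
  if (any(!is.finite(clinical$os_months)) || any(clinical$os_months < 0))
    stop("os_months must be finite and nonnegative")
  if (!all(clinical$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  clinical$arm <- as.character(clinical$arm)
  bad <- setdiff(unique(clinical$arm), c("VH", "CC"))
  if (length(bad))
    stop("unknown treatment arm: ", paste(bad, collapse = ", "))
  if (!is.null(clinical$crd_months)) {
    clinical$crd_months <- as.numeric(clinical$crd_months)
    if (any(clinical$crd_months < 0, na.rm = TRUE))
      stop("crd_months must be nonnegative")
    if (!all(clinical$crd_event %in% c(0, 1) | is.na(clinical$crd_event)))
      stop("crd_event must be 0/1 or NA")
  }
  clinical
}

#' @describeIn RppaCohort patients x proteins LFC matrix (transposed assay).
#' @param x,object an `RppaCohort`.
#' @export
lfcMatrix <- function(x) {
  stopifnot(methods::is(x, "RppaCohort"))
  t(SummarizedExperiment::assay(x, "lfc"))
}

#' @describeIn RppaCohort clinical table as a plain `data.frame`.
#' @export
clinicalTable <- function(x) {
  stopifnot(methods::is(x, "RppaCohort"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn RppaCohort patient identifiers.
#' @export
patientIds <- function(x) colnames(x)

#' @describeIn RppaCohort protein identifiers.
#' @export
proteinIds <- function(x) rownames(x)

#' @describeIn RppaCohort treatment arm per patient (`"VH"`/`"CC"`).
#' @export
treatmentArm <- function(x) SummarizedExperiment::colData(x)$arm

#' @describeIn RppaCohort planted cluster labels (`NULL` for real cohorts).
#' @export
trueCluster <- function(x) SummarizedExperiment::colData(x)$true_cluster

setMethod("show", "RppaCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("RppaCohort:", ncol(object), "patients x", nrow(object), "proteins\n")
  cat("  arms: VH =", sum(cd$arm == "VH"), "/ CC =", sum(cd$arm == "CC"), "\n")
  cat("  OS events:", sum(cd$os_event), "; CRD available:",
      if (is.null(cd$crd_months)) 0L else sum(!is.na(cd$crd_months)), "\n")
  if (!is.null(cd$true_cluster))
    cat("  planted clusters:",
        paste(names(table(cd$true_cluster)), table(cd$true_cluster),
              sep = ":", collapse = " "), "\n")
  invisible(NULL)
})
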