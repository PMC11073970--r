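#' Read an RPPA expression matrix
#'
#' Parses a delimited text file with a header row of protein ids and a first
#' column of patient ids into a patients x proteins numeric matrix of LFC
#' values. The delimiter is taken from the extension: `.csv` is
#' comma-separated, anything else (`.tsv`, `.txt`) tab-separated. The decimal
#' mark is `.`.
#'
#' @param path file to read.
#' @return numeric matrix, patients in rows, proteins in columns.
#' @seealso [writeExpression()], [alignCohort()]
#' @export
readExpression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed expression file: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate patient id in ", path)
  prot <- colnames(df)[-1L]
  if (anyDuplicated(prot)) stop("duplicate protein id in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2L, as.numeric))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric value at patient '%s', protein '%s'",
                   ids[bad[1L, 1L]], prot[bad[1L, 2L]]))
    mat <- apply(mat, 2L, as.numeric)
  }
  dimnames(mat) <- list(ids, prot)
  mat
}

#' Write an RPPA expression matrix
#'
#' Inverse of [readExpression()]: writes the patients x proteins matrix with a
#' `patient_id` first column; delimiter chosen from the extension as in
#' [readExpression()].
#'
#' @param x patients x proteins numeric matrix with dimnames.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(patient_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a clinical outcome table
#'
#' The clinical CSV contract: columns `patient_id`, `os_months`, `os_event`
#' (0/1), `crd_months`/`crd_event` (may be empty for patients never in
#' remission), `arm` (`VH` or `CC`), plus any extra covariate columns.
#' Validation rejects negative times, non-0/1 event flags, duplicate patients
#' and arms outside \{VH, CC\}.
#'
#' @param path CSV file.
#' @return typed `data.frame`.
#' @export
readClinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty clinical file: ", path)
  checkClinical(df)
}

#' @rdname readClinical
#' @param x clinical `data.frame` to write.
#' @export
writeClinical <- function(x, path) {
  checkClinical(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align an expression matrix and a clinical table into an RppaCohort
#'
#' Restricts both inputs to the intersection of their patient ids, in the
#' expression matrix's order, and returns the joined [RppaCohort]. The number
#' of dropped ids is reported with a message; an empty intersection is an
#' error. The operation is idempotent.
#'
#' @param expression patients x proteins matrix (see [readExpression()]).
#' @param clinical clinical `data.frame` (see [readClinical()]).
#' @return an [RppaCohort] on the common patients.
#' @export
alignCohort <- function(expression, clinical) {
  clinical <- checkClinical(clinical)
  common <- intersect(rownames(expression), clinical$patient_id)
  if (length(common) == 0L)
    stop("no patients in common between expression and clinical inputs")
  dropped <- (nrow(expression) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0L)
    message("alignCohort: dropped ", dropped,
            " patient record(s) absent from one of the inputs")
  keep <- rownames(expression)[rownames(expression) %in% common]
  RppaCohort(expression[keep, , drop = FALSE],
             clinical[match(keep, clinical$patient_id), , drop = FALSE])
}
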