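#' Quantile split of a protein's expression
#'
#' Cuts a continuous expression vector into `n_groups` quantile groups
#' (2 = median split, 3 = tertiles, 4 = quartiles, 5 = quintiles,
#' 6 = sextiles). Boundaries are the `k / n_groups` sample quantiles; values
#' tied with a boundary all fall into the lower group, which makes the split
#' deterministic and independent of input order.
#'
#' @param values numeric vector.
#' @param n_groups integer in 2..6.
#' @return integer labels `0 .. n_groups - 1`; errors with "degenerate
#'   protein" when the values cannot support `n_groups` nonempty groups.
#' @export
quantileSplit <- function(values, n_groups) {
  n_groups <- as.integer(n_groups)
  if (!n_groups %in% 2:6) stop("n_groups must be one of 2, 3, 4, 5, 6")
  if (any(!is.finite(values))) stop("degenerate protein: non-finite values")
  if (length(unique(values)) < n_groups)
    stop("degenerate protein: fewer distinct values than groups")
  cuts <- stats::quantile(values, probs = seq_len(n_groups - 1L) / n_groups,
                          names = FALSE)
  labels <- rowSums(outer(values, cuts, ">"))
  if (length(unique(labels)) < n_groups)
    stop("degenerate protein: empty quantile group")
  as.integer(labels)
}

quantileSchemes <- c(p_median = 2L, p_tertile = 3L, p_quartile = 4L,
                     p_quintile = 5L, p_sextile = 6L)

#' Quantile-sweep log-rank screen of one protein
#'
#' For each of the five quantile schemes, splits the cohort on the protein's
#' expression and compares overall survival across the groups with a log-rank
#' test; records the five p-values and their minimum. A protein that cannot
#' be split under some scheme (too few distinct values) gets `NA` for that
#' scheme; a protein degenerate under every scheme is flagged excluded.
#'
#' @param values one protein's expression across the cohort.
#' @param times,events overall-survival follow-up, aligned with `values`.
#' @return named list: `p_values` (length 5), `min_p`, `excluded`.
#' @export
screenProtein <- function(values, times, events) {
  stopifnot(length(values) == length(times))
  p <- vapply(quantileSchemes, function(k) {
    g <- tryCatch(quantileSplit(values, k), error = function(e) NULL)
    if (is.null(g)) return(NA_real_)
    logrankTest(times, events, g)$p_value
  }, numeric(1L))
  min_p <- if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
  list(p_values = p, min_p = min_p, excluded = all(is.na(p)))
}

#' Quantile-sweep prognostic screen of a cohort
#'
#' Applies [screenProtein()] to every protein (independently; there is no
#' cross-protein state) and assembles the p-value table with per-scheme
#' columns, `min_p`, and the two selection flags at the p < 0.05 and p < 0.01
#' cutoffs. Selection uses raw per-protein p-values, as in the screening
#' design this implements; [bhAdjust()] is available for users who prefer an
#' FDR-controlled list. Proteins with missing expression values are excluded
#' (not imputed) with a warning.
#'
#' @param cohort an [RppaCohort].
#' @param endpoint `"os"` (the screening endpoint) or `"crd"`.
#' @return `data.frame` with columns `protein`, `p_median`, `p_tertile`,
#'   `p_quartile`, `p_quintile`, `p_sextile`, `min_p`, `prognostic_05`,
#'   `prognostic_01`, `excluded`.
#' @export
screenPrognostic <- function(cohort, endpoint = c("os", "crd")) {
  endpoint <- match.arg(endpoint)
  expr <- lfcMatrix(cohort)
  cd <- clinicalTable(cohort)
  if (endpoint == "os") {
    times <- cd$os_months; events <- cd$os_event
  } else {
    keep <- !is.na(cd$crd_months)
    expr <- expr[keep, , drop = FALSE]
    times <- cd$crd_months[keep]; events <- cd$crd_event[keep]
  }
  has_na <- colSums(is.na(expr)) > 0L
  if (any(has_na))
    warning(sum(has_na), " protein(s) with missing values excluded from the ",
            "screen")
  rows <- lapply(colnames(expr), function(pr) {
    if (has_na[[pr]])
      return(c(stats::setNames(rep(NA_real_, 5L), names(quantileSchemes)),
               min_p = NA_real_))
    s <- screenProtein(expr[, pr], times, events)
    c(s$p_values, min_p = s$min_p)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(protein = colnames(expr), tab)
  tab$prognostic_05 <- !is.na(tab$min_p) & tab$min_p < 0.05
  tab$prognostic_01 <- !is.na(tab$min_p) & tab$min_p < 0.01
  tab$excluded <- is.na(tab$min_p)
  rownames(tab) <- NULL
  tab
}

#' Select prognostic proteins at a significance cutoff
#'
#' Proteins whose minimum p-value across the five quantile schemes falls below
#' `alpha`, sorted by `min_p` ascending; the `alpha = 0.01` list is always
#' nested inside the `alpha = 0.05` list.
#'
#' @param table output of [screenPrognostic()].
#' @param alpha significance cutoff (the screen's two canonical values are
#'   0.05 and 0.01).
#' @return character vector of protein ids.
#' @export
selectPrognostic <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("protein", "min_p") %in%
                                        colnames(table)))
  hit <- table[!is.na(table$min_p) & table$min_p < alpha, , drop = FALSE]
  hit$protein[order(hit$min_p)]
}
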