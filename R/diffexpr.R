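#' One-vs-rest differential expression of a cluster
#'
#' Per protein, a two-sided Wilcoxon rank-sum test of the target cluster
#' against the pooled remaining patients, Benjamini-Hochberg adjusted across
#' proteins, with the effect defined as mean LFC in the cluster minus mean
#' LFC in the rest (the expression values are already log2 fold-changes, so
#' this difference is itself an LFC). Reported rows must pass both gates:
#' adjusted p below `alpha` and absolute effect at least `lfc_threshold`.
#' With `comparison = "per-cluster"` the target is instead tested against
#' each other cluster separately and a protein must pass against all of them
#' (worst-case p, smallest-magnitude effect; an exploratory variant).
#'
#' @param expr patients x proteins LFC matrix.
#' @param clusters cluster label per patient.
#' @param target the cluster to profile.
#' @param alpha FDR cutoff (default 0.05).
#' @param lfc_threshold minimum absolute mean-LFC difference (default 0.5).
#' @param comparison `"pooled"` (default) or `"per-cluster"`.
#' @return `data.frame` of passing rows (`protein`, `effect`, `p_raw`,
#'   `p_fdr`, `direction`), ordered by `p_fdr`; the full per-protein table is
#'   attached as `attr(, "full")`.
#' @export
deOneVsRest <- function(expr, clusters, target, alpha = 0.05,
                        lfc_threshold = 0.5,
                        comparison = c("pooled", "per-cluster")) {
  comparison <- match.arg(comparison)
  expr <- as.matrix(expr)
  clusters <- as.character(clusters)
  stopifnot(nrow(expr) == length(clusters))
  in_t <- clusters == target
  if (sum(in_t) < 3L || sum(!in_t) < 3L)
    stop("target cluster and its complement each need at least 3 patients")
  others <- setdiff(unique(clusters), target)
  testOne <- function(v) {
    if (comparison == "pooled") {
      p <- stats::wilcox.test(v[in_t], v[!in_t], exact = FALSE)$p.value
      eff <- mean(v[in_t]) - mean(v[!in_t])
    } else {
      per <- vapply(others, function(cl) {
        sel <- clusters == cl
        c(stats::wilcox.test(v[in_t], v[sel], exact = FALSE)$p.value,
          mean(v[in_t]) - mean(v[sel]))
      }, numeric(2L))
      p <- max(per[1L, ])
      eff <- unname(per[2L, which.min(abs(per[2L, ]))])
      if (length(unique(sign(per[2L, ]))) > 1L) eff <- 0
    }
    c(p = unname(p), effect = eff)
  }
  res <- t(apply(expr, 2L, testOne))
  full <- data.frame(protein = colnames(expr), effect = res[, "effect"],
                     p_raw = res[, "p"], p_fdr = bhAdjust(res[, "p"]),
                     row.names = NULL)
  full$direction <- ifelse(full$effect > 0, "UP", "DOWN")
  hits <- full[full$p_fdr < alpha & abs(full$effect) >= lfc_threshold, ,
               drop = FALSE]
  hits <- hits[order(hits$p_fdr, -abs(hits$effect)), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "full") <- full
  hits
}

#' Pairwise Pearson correlation of proteins
#'
#' Pearson correlation of every protein pair with the two-sided t-based
#' p-value; pairs whose coefficient exceeds `r_threshold` are flagged as top
#' correlations. Zero-variance proteins yield `NA` pairs with a warning.
#'
#' @param expr patients x proteins LFC matrix.
#' @param proteins columns to correlate (all by default).
#' @param r_threshold flag threshold on the coefficient (default 0.60).
#' @return list: `matrix` (full symmetric correlation matrix) and `pairs`
#'   (long table with `protein_a`, `protein_b`, `r`, `p_value`, `top_pair`,
#'   upper triangle only).
#' @export
correlateProteins <- function(expr, proteins = colnames(expr),
                              r_threshold = 0.60) {
  x <- as.matrix(expr)[, proteins, drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 patients")
  if (ncol(x) < 2L) stop("need at least 2 proteins")
  novar <- apply(x, 2L, stats::sd) == 0
  if (any(novar)) {
    warning("zero-variance protein(s): ",
            paste(colnames(x)[novar], collapse = ", "),
            "; their correlations are NA")
    x[, novar] <- NA_real_
  }
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  n <- nrow(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(protein_a = colnames(x)[ut[, 1L]],
                      protein_b = colnames(x)[ut[, 2L]],
                      r = r[ut], p_value = p[ut])
  pairs$top_pair <- !is.na(pairs$r) & pairs$r > r_threshold
  list(matrix = r, pairs = pairs[order(-abs(pairs$r)), , drop = FALSE])
}
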