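# Shared fixtures and independent oracles used across the test files.

## Independent brute-force product-limit estimator: a plain loop over
## distinct event times, no survfit involved.
bruteKM <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(times >= ts[i])
    d_i <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

## Brute-force C-index by explicit pair enumeration.
bruteCIndex <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  conc <- 0; ties <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) ties <- ties + 1
  }
  (conc + 0.5 * ties) / (length(pos) * length(neg))
}

## Minimal clinical table builder.
makeClin <- function(os, ev, arm, crd = NULL, crd_ev = NULL,
                     ids = sprintf("P%03d", seq_along(os))) {
  data.frame(patient_id = ids, os_months = os, os_event = ev,
             crd_months = if (is.null(crd)) NA_real_ else crd,
             crd_event = if (is.null(crd_ev)) NA_real_ else crd_ev,
             arm = arm, stringsAsFactors = FALSE)
}

## Small expression matrix with named dims.
makeExpr <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("P%03d", seq_len(n)),
                         sprintf("PR%03d", seq_len(p))))
}

## Tiny flat-structure generator config (k clusters, equal arms, no group
## blocks) used by clustering tests.
flatConfig <- function(k, n, p, effect, seed, noise = 1) {
  rppaCohortConfig(n_patients = n, n_proteins = p,
                   cluster_props = rep(1 / k, k),
                   signature_effect = effect, group_effect = 0,
                   noise_sd = noise,
                   median_os_months = matrix(20, k, 2),
                   median_crd_months = matrix(20, k, 2),
                   seed = seed)
}
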